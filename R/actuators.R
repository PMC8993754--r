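# Boundary force actuators. Each actuator turns the current (deformed)
# boundary geometry into per-vertex traction vectors - force per unit
# boundary length - which are then edge-lumped into nodal loads. Because
# they are re-evaluated on the deformed boundary at every step, the source
# terms are advected with the flow and shrink with the contours they pull
# on (the self-arrest mechanism).
#
# Sign conventions (each closed loop in its own counter-clockwise frame,
# normal away from the enclosed region): positive magnitudes are
# contractile/inward for line_tension, normal_pressure and shear_pair, and
# outward growth for neg_surface_tension.

#' Create a boundary actuator
#'
#' @param kind one of `"line_tension"`, `"normal_pressure"`, `"shear_pair"`,
#'   `"tension_gradient"`, `"extensional_shear"`, `"neg_surface_tension"`.
#' @param label target boundary/chain label (must exist in the mesh at run
#'   time; a missing label is a configuration error).
#' @param ... kind-specific magnitude parameters:
#'   \describe{
#'     \item{line_tension}{`T` (tension).}
#'     \item{normal_pressure}{`P` (pressure).}
#'     \item{shear_pair / extensional_shear}{`F` (line force), `asymmetry`
#'       (scales the second half, default 1), `normal_T` (optional
#'       line-tension term adding the normal component the pure shear model
#'       deliberately omits, default 0).}
#'     \item{tension_gradient}{`strength`, `direction` (2-vector).}
#'     \item{neg_surface_tension}{`gamma`, `m` (exponent, 1 or 2), `clamp`
#'       (no growth in concavities, default TRUE).}
#'   }
#' @return an object of class `actuator`.
#' @export
actuator <- function(kind, label, ...) {
  kind <- match.arg(kind, c("line_tension", "normal_pressure", "shear_pair",
                            "tension_gradient", "extensional_shear",
                            "neg_surface_tension"))
  pars <- list(...)
  defaults <- switch(kind,
    line_tension = list(T = 1),
    normal_pressure = list(P = 1),
    shear_pair = list(F = 1, asymmetry = 1, sense = "contract", normal_T = 0),
    extensional_shear = list(F = 1, asymmetry = 1, sense = "extend",
                             normal_T = 0),
    tension_gradient = list(strength = 1, direction = c(0, 1)),
    neg_surface_tension = list(gamma = 1, m = 1, clamp = TRUE))
  unknown <- setdiff(names(pars), names(defaults))
  if (length(unknown))
    stop("actuator(", kind, "): unknown parameter(s) ",
         paste(unknown, collapse = ", "))
  pars <- utils::modifyList(defaults, pars)
  if (kind == "neg_surface_tension" && !(pars$m %in% c(1, 2)))
    stop("neg_surface_tension: exponent m must be 1 or 2")
  structure(c(list(kind = kind, label = label), pars), class = "actuator")
}

#' @export
print.actuator <- function(x, ...) {
  p <- x[setdiff(names(x), c("kind", "label"))]
  cat(sprintf("actuator %s on '%s': %s\n", x$kind, x$label,
              paste(names(p), vapply(p, function(v) paste(format(v),
                    collapse = ","), ""), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Laplace (purse-string) traction of a constant line tension
#'
#' A tension `T` along a curved contour pulls inward with the Laplace
#' pressure `T * kappa`: traction `T * kappa * (-n)` per vertex. On a
#' shrinking circular hole the magnitude grows as `1/R` while the perimeter
#' shrinks as `R`, keeping the total force constant. Straight segments
#' (`kappa = 0`) feel nothing.
#'
#' @param curv a `curvature_field`.
#' @param T tension (force units).
#' @return nrow(curv) x 2 traction matrix.
#' @export
line_tension_traction <- function(curv, T) {
  cbind(-T * curv$kappa * curv$nx, -T * curv$kappa * curv$ny)
}

#' Constant normal pressure traction
#'
#' Curvature-independent inward traction `P * (-n)`; the total force scales
#' with the perimeter and therefore decays as the contour shrinks. At
#' corner vertices the vertex normal is the (chord-weighted) average of the
#' adjacent edge normals, i.e. the half-angle bisector for equal edge
#' lengths.
#'
#' @param curv a `curvature_field`.
#' @param P pressure (force per unit length).
#' @return nrow(curv) x 2 traction matrix.
#' @export
normal_pressure_traction <- function(curv, P) {
  cbind(-P * curv$nx, -P * curv$ny)
}

#' Antagonistic shear-pair traction
#'
#' The tangential line force of a constant stress gradient along a straight
#' pulling segment: constant shear along one half of the target polyline
#' and the opposite value along the other half (split at the arclength
#' midpoint), oriented head-on (`contract`) or tail-to-tail (`extend`).
#' `asymmetry` scales the second (high-arclength) half.
#'
#' @param curv a `curvature_field` of a single-part chain with >= 4
#'   vertices.
#' @param F line-force magnitude.
#' @param asymmetry ratio applied to the second half.
#' @param sense `"contract"` or `"extend"`.
#' @return nrow(curv) x 2 traction matrix.
#' @export
shear_pair_traction <- function(curv, F, asymmetry = 1, sense = "contract") {
  sense <- match.arg(sense, c("contract", "extend"))
  if (length(unique(curv$part)) != 1L)
    stop("shear_pair: target label must be a single contiguous chain")
  if (nrow(curv) < 4L)
    stop("shear_pair: target chain has fewer than 4 vertices")
  s_mid <- (curv$s[1L] + curv$s[nrow(curv)]) / 2
  sgn <- ifelse(curv$s < s_mid, 1, -asymmetry)
  at_mid <- abs(curv$s - s_mid) < 1e-12
  sgn[at_mid] <- (1 - asymmetry) / 2
  if (sense == "extend") sgn <- -sgn
  cbind(F * sgn * curv$tx, F * sgn * curv$ty)
}

#' Tangential tension-gradient traction
#'
#' Constant-magnitude tangential traction signed so that it points toward
#' the given direction (e.g. toward the neural tube for the dorsal-ward
#' gradient of tension, or along the body axis for ventral/dorsal pulls).
#' Vertices whose tangent is perpendicular to `direction` feel nothing.
#'
#' @param curv a `curvature_field`.
#' @param strength traction magnitude.
#' @param direction 2-vector; only its direction matters.
#' @return nrow(curv) x 2 traction matrix.
#' @export
tension_gradient_traction <- function(curv, strength, direction) {
  d <- direction / sqrt(sum(direction^2))
  sgn <- sign(curv$tx * d[1] + curv$ty * d[2])
  cbind(strength * sgn * curv$tx, strength * sgn * curv$ty)
}

#' Negative-surface-tension (growth) traction
#'
#' Outward normal growth stress `gamma * kappa^m * (+n)` modelling the
#' extensional work of cells stacked in a curved ridge; with `m = 2` the
#' feedback is quadratic in curvature (more curved regions grow faster and
#' push along a more curved normal). By default clamped to zero where the
#' contour is concave (`kappa <= 0`): growth only where convex.
#'
#' @param curv a `curvature_field` on the external contour.
#' @param gamma growth-stress coefficient (stress times length^m).
#' @param m curvature exponent, 1 or 2.
#' @param clamp clamp concave regions to zero (default) or keep the signed
#'   odd extension `gamma * sign(kappa) * |kappa|^m`.
#' @return nrow(curv) x 2 traction matrix.
#' @export
neg_surface_tension_traction <- function(curv, gamma, m, clamp = TRUE) {
  if (!(m %in% c(1, 2))) stop("neg_surface_tension: m must be 1 or 2")
  k <- curv$kappa
  mag <- if (clamp) gamma * pmax(k, 0)^m else gamma * sign(k) * abs(k)^m
  # no growth at the terminal vertices of an open chain: they sit at
  # label junctions (corners), where the curvature is not defined
  if ("terminal" %in% names(curv)) mag[curv$terminal] <- 0
  cbind(mag * curv$nx, mag * curv$ny)
}

#' Evaluate an actuator's tractions on the current boundary
#'
#' @param act an `actuator`.
#' @param curv the `curvature_field` of its target label (current mesh).
#' @return nrow(curv) x 2 traction matrix.
#' @export
actuator_tractions <- function(act, curv) {
  switch(act$kind,
    line_tension = line_tension_traction(curv, act$T),
    normal_pressure = normal_pressure_traction(curv, act$P),
    shear_pair = ,
    extensional_shear = {
      tr <- shear_pair_traction(curv, act$F, act$asymmetry, act$sense)
      if (act$normal_T != 0)
        tr <- tr + line_tension_traction(curv, act$normal_T)
      tr
    },
    tension_gradient = tension_gradient_traction(curv, act$strength,
                                                 act$direction),
    neg_surface_tension = neg_surface_tension_traction(curv, act$gamma,
                                                       act$m, act$clamp))
}

# Total nodal loads of a list of actuators on the current mesh; curvature
# fields are computed once per distinct target label.
actuator_loads <- function(mesh, actuators) {
  F <- numeric(2L * nrow(mesh$vertices))
  if (length(actuators) == 0L) return(F)
  labs <- unique(vapply(actuators, `[[`, "", "label"))
  curvs <- lapply(labs, function(lb) boundary_curvature(mesh, lb))
  names(curvs) <- labs
  for (act in actuators) {
    cv <- curvs[[act$label]]
    F <- F + traction_loads(mesh, cv, actuator_tractions(act, cv))
  }
  F
}
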