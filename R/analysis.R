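# Trace analysis: closure-law fitting (linear wound-healing vs exponential
# self-arrest), shape metrics for regions and contours, and paired regime
# comparison.

#' Fit linear and exponential closure laws to a shrinking-length trace
#'
#' Fits both a linear law `L = L0 + slope t` (constant total force, as for
#' a purse-string at constant tension) and an exponential self-arrest law
#' `L = L0 exp(-t / tau)` (force proportional to the shrinking source,
#' `dL/dt` proportional to `-L`). The exponential parameters come from
#' least squares on `log L` (the log-linear plot), refined by nonlinear
#' least squares on the original scale; both models are scored by AIC
#' computed from the residual sum of squares on the original `L` scale
#' (`n log(RSS/n) + 2k`, `k = 2` each) and the lower AIC is selected, ties
#' going to linear. An initial-transient burn-in fraction is discarded
#' before fitting.
#'
#' @param trace data.frame with columns `time` and `value`, or a numeric
#'   vector of times (then `value` must be given).
#' @param value observable values if `trace` is a time vector.
#' @param burn_in fraction of points discarded from the start (default
#'   0.2).
#' @return a `closure_trace`: list with `time`, `value` (post burn-in),
#'   `models` (`linear`: slope, intercept, rss, aic; `exponential`: L0,
#'   tau, rss, aic, r_squared_log) and `selected` (`"linear"` or
#'   `"exponential"`).
#' @export
fit_closure_law <- function(trace, value = NULL, burn_in = 0.2) {
  if (is.data.frame(trace)) {
    tt <- trace$time; vv <- trace$value
  } else {
    tt <- trace; vv <- value
  }
  stopifnot(length(tt) == length(vv), burn_in >= 0, burn_in < 1)
  if (any(diff(tt) <= 0)) stop("fit_closure_law: time must strictly increase")
  drop_n <- floor(burn_in * length(tt))
  if (drop_n > 0L) { tt <- tt[-seq_len(drop_n)]; vv <- vv[-seq_len(drop_n)] }
  if (length(tt) < 10L)
    stop("fit_closure_law: need at least 10 points after burn-in")
  if (any(vv <= 0))
    stop("fit_closure_law: values must be strictly positive")

  n <- length(tt)
  lin <- stats::lm(vv ~ tt)
  rss_lin <- sum(stats::residuals(lin)^2)
  linear <- list(slope = unname(stats::coef(lin)[2]),
                 intercept = unname(stats::coef(lin)[1]),
                 rss = rss_lin, aic = n * log(rss_lin / n) + 4)

  lg <- stats::lm(log(vv) ~ tt)
  sl <- unname(stats::coef(lg)[2])
  r2_log <- suppressWarnings(summary(lg)$r.squared)
  exponential <- NULL
  if (sl < 0) {
    tau <- -1 / sl
    L0 <- exp(unname(stats::coef(lg)[1]))
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(vv ~ L0 * exp(-tt / tau),
                          start = list(L0 = L0, tau = tau),
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      if (co[["tau"]] > 0) { L0 <- co[["L0"]]; tau <- co[["tau"]] }
    }
    rss_exp <- sum((vv - L0 * exp(-tt / tau))^2)
    exponential <- list(L0 = L0, tau = tau, rss = rss_exp,
                        aic = n * log(rss_exp / n) + 4,
                        r_squared_log = r2_log)
  }
  selected <- if (is.null(exponential) || linear$aic <= exponential$aic)
    "linear" else "exponential"
  structure(list(time = tt, value = vv, burn_in = burn_in,
                 models = list(linear = linear, exponential = exponential),
                 selected = selected),
            class = "closure_trace")
}

#' @export
print.closure_trace <- function(x, ...) {
  cat("closure_trace:", length(x$time), "points, selected law:",
      x$selected, "\n")
  cat(sprintf("  linear: slope %.5g (AIC %.4g)\n",
              x$models$linear$slope, x$models$linear$aic))
  if (!is.null(x$models$exponential))
    cat(sprintf("  exponential: tau %.5g (AIC %.4g, log-linear R2 %.4f)\n",
                x$models$exponential$tau, x$models$exponential$aic,
                x$models$exponential$r_squared_log))
  invisible(x)
}

# Area, centroid and central second moments of a simple polygon
# (Green's-theorem formulas; orientation-independent outputs).
polygon_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  k <- nrow(xy)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12       # integral of y^2
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12       # integral of x^2
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  s <- abs(A)
  sgn <- sign(A)
  list(area = s, cx = cx, cy = cy,
       sxx = sgn * iyy / s - cx^2, syy = sgn * ixx / s - cy^2,
       sxy = sgn * ixy / s - cx * cy)
}

aspect_from_moments <- function(sxx, syy, sxy) {
  M <- matrix(c(sxx, sxy, sxy, syy), 2)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), .Machine$double.eps))
}

#' Shape metrics of a material region or closed contour
#'
#' For an integer `region`, metrics are computed over the triangles with
#' that material tag (area, boundary perimeter of the sub-triangulation,
#' area centroid, principal-axis aspect ratio). For a character label, the
#' polygon enclosed by the named chain(s) is used (e.g.
#' `c("ear_crenel", "ear_base")` closes the placode outline). The aspect
#' ratio is `sqrt(lambda_max / lambda_min)` of the central second-moment
#' matrix (2 for a 2:1 ellipse); `isoperimetric` is `4 pi A / P^2` (1 for
#' a circle).
#'
#' @param mesh a `trimesh`.
#' @param region integer material tag, a character vector of chain labels
#'   forming a closed outline, or a k x 2 polygon matrix (e.g. from
#'   [placode_outline()]).
#' @return list: `area`, `perimeter`, `centroid`, `aspect_ratio`,
#'   `isoperimetric`.
#' @export
shape_metrics <- function(mesh, region) {
  if (is.matrix(region) || is.character(region)) {
    poly <- if (is.matrix(region)) region else region_polygon(mesh, region)
    mom <- polygon_moments(poly)
    per <- polygon_perimeter(poly)
  } else {
    sel <- mesh$tags == as.integer(region)
    if (!any(sel)) stop("shape_metrics: empty region ", region)
    tr <- mesh$triangles[sel, , drop = FALSE]
    v <- mesh$vertices
    mom <- region_triangle_moments(v, tr)
    e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    single <- names(which(table(key) == 1L))
    bsel <- match(single, key)
    per <- sum(sqrt(rowSums((v[e[bsel, 2], , drop = FALSE] -
                               v[e[bsel, 1], , drop = FALSE])^2)))
  }
  list(area = mom$area, perimeter = per, centroid = c(mom$cx, mom$cy),
       aspect_ratio = aspect_from_moments(mom$sxx, mom$syy, mom$sxy),
       isoperimetric = 4 * pi * mom$area / per^2)
}

# Exact first/second moments over a set of triangles.
region_triangle_moments <- function(v, tr) {
  x1 <- v[tr[, 1], 1]; y1 <- v[tr[, 1], 2]
  x2 <- v[tr[, 2], 1]; y2 <- v[tr[, 2], 2]
  x3 <- v[tr[, 3], 1]; y3 <- v[tr[, 3], 2]
  A <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  S <- sum(A)
  cx <- sum(A * (x1 + x2 + x3) / 3) / S
  cy <- sum(A * (y1 + y2 + y3) / 3) / S
  ix2 <- sum(A / 6 * (x1^2 + x2^2 + x3^2 + x1 * x2 + x1 * x3 + x2 * x3))
  iy2 <- sum(A / 6 * (y1^2 + y2^2 + y3^2 + y1 * y2 + y1 * y3 + y2 * y3))
  ixy <- sum(A / 12 * (x1 * (2 * y1 + y2 + y3) + x2 * (y1 + 2 * y2 + y3) +
                         x3 * (y1 + y2 + 2 * y3)))
  list(area = S, cx = cx, cy = cy,
       sxx = ix2 / S - cx^2, syy = iy2 / S - cy^2, sxy = ixy / S - cx * cy)
}

#' Maximum deflection of a chain from its own chord
#'
#' Depth of an invagination (or bulge): the largest perpendicular distance
#' of the chain vertices from the chord through the chain's current
#' endpoints, measured toward the domain interior (the chain is traversed
#' with the domain on its left, so the interior normal is the chord
#' direction rotated by +90 degrees). Measuring against the current chord
#' makes the depth insensitive to bulk translation or rotation of the
#' edge (e.g. neck flexure carrying the whole mouth along).
#'
#' @param mesh a `trimesh`.
#' @param label chain label (single part).
#' @param origin,direction optional explicit chord (a point and a unit
#'   normal); defaults to the current endpoints chord and its interior
#'   normal.
#' @return max projection (>= 0, clamped at zero).
#' @export
chord_deflection <- function(mesh, label, origin = NULL, direction = NULL) {
  ch <- mesh_chain(mesh, label)
  xy <- mesh$vertices[unlist(ch$parts), , drop = FALSE]
  if (is.null(origin) || is.null(direction)) {
    p0 <- xy[1, ]; p1 <- xy[nrow(xy), ]
    dir <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    nrm <- c(-dir[2], dir[1])            # +90 deg: toward the interior
    origin <- p0; direction <- nrm
  }
  d <- direction / sqrt(sum(direction^2))
  max(0, max((xy[, 1] - origin[1]) * d[1] + (xy[, 2] - origin[2]) * d[2]))
}

#' Paired comparison of two simulation runs
#'
#' Interpolates a shared observable of two runs onto a common time grid
#' and reports the end-state delta; used for the ordinal regime claims
#' (e.g. quadratic-growth tip extension vs linear, flexure-hindered mouth
#' invagination vs control).
#'
#' @param runA,runB `sim_result` objects with the observable recorded.
#' @param observable trace column name.
#' @param n_grid points of the common time grid.
#' @return list: `observable`, `time` (grid), `A`, `B` (interpolated
#'   curves), `final_A`, `final_B`, `delta_final` (A - B), `larger`
#'   (`"A"`/`"B"`/`"tie"`).
#' @export
compare_regimes <- function(runA, runB, observable, n_grid = 50L) {
  for (r in list(runA, runB))
    if (!observable %in% names(r$trace))
      stop("compare_regimes: observable '", observable, "' not in trace")
  tmax <- min(max(runA$trace$time), max(runB$trace$time))
  grid <- seq(0, tmax, length.out = n_grid)
  fa <- stats::approx(runA$trace$time, runA$trace[[observable]], xout = grid,
                      rule = 2)$y
  fb <- stats::approx(runB$trace$time, runB$trace[[observable]], xout = grid,
                      rule = 2)$y
  finA <- runA$trace[[observable]][nrow(runA$trace)]
  finB <- runB$trace[[observable]][nrow(runB$trace)]
  delta <- finA - finB
  list(observable = observable, time = grid, A = fa, B = fb,
       final_A = finA, final_B = finB, delta_final = delta,
       larger = if (delta > 0) "A" else if (delta < 0) "B" else "tie")
}
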