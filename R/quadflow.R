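# Closed-form quadrupolar potential-flow model of placode winding.
# Two vertical source lines at x = a and x = c pull head-on along the
# segment [-b, b] in y with magnitudes alpha and beta; the stream function
# is a sum of four logarithmic terms and the velocity is its curl. The
# contour is advected passively in this frozen field - deliberately not
# self-consistent (that is what the finite-element actuators add).

#' Quadrupolar flow parameters
#'
#' @param a,c x-positions of the two pulling source lines (`a != c`).
#' @param b half-length of the pulling segment along y (> 0).
#' @param alpha,beta source magnitudes; `alpha = beta` is the symmetric
#'   quadrupole, unequal values encode the head-flexure asymmetry.
#' @return object of class `quadflow_params`.
#' @export
quadflow_params <- function(a = -1, c = 1, b = 1, alpha = 1, beta = 1) {
  stopifnot(is.finite(a), is.finite(c), a != c, b > 0,
            is.finite(alpha), is.finite(beta))
  structure(list(a = a, c = c, b = b, alpha = alpha, beta = beta),
            class = "quadflow_params")
}

#' @export
print.quadflow_params <- function(x, ...) {
  cat(sprintf("quadflow: sources x = %g, %g; segment |y| <= %g; ",
              x$a, x$c, x$b))
  cat(sprintf("alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

# Squared distances to the four logarithmic singularities.
quad_d2 <- function(x, y, p) {
  list(d1 = (x - p$a)^2 + (y - p$b)^2, d2 = (x - p$a)^2 + (y + p$b)^2,
       d3 = (x - p$c)^2 + (y - p$b)^2, d4 = (x - p$c)^2 + (y + p$b)^2)
}

#' Default exclusion radius around the flow singularities
#' @param params a `quadflow_params`.
#' @return radius (model length).
#' @export
quad_exclusion_radius <- function(params) 1e-3 * abs(params$c - params$a)

quad_check_regular <- function(x, y, p, r_excl = quad_exclusion_radius(p)) {
  d2 <- quad_d2(x, y, p)
  if (any(pmin(d2$d1, d2$d2, d2$d3, d2$d4) < r_excl^2))
    stop("quadflow: evaluation inside the exclusion radius of a singularity")
  d2
}

#' Stream function of the quadrupolar flow
#'
#' `Psi = alpha ln((x-a)^2+(y-b)^2) - alpha ln((x-a)^2+(y+b)^2)
#'        - beta ln((x-c)^2+(y-b)^2) + beta ln((x-c)^2+(y+b)^2)`;
#' odd in y, so the x-axis is a streamline.
#'
#' @param x,y coordinates (vectorised).
#' @param params a `quadflow_params`.
#' @return stream-function values.
#' @export
quad_psi <- function(x, y, params) {
  d2 <- quad_check_regular(x, y, params)
  params$alpha * log(d2$d1) - params$alpha * log(d2$d2) -
    params$beta * log(d2$d3) + params$beta * log(d2$d4)
}

#' Velocity of the quadrupolar flow
#'
#' `(u, v) = (dPsi/dy, -dPsi/dx)` from the hand-derived analytic
#' derivatives of the four log terms; exactly divergence-free.
#'
#' @param x,y coordinates (vectorised).
#' @param params a `quadflow_params`.
#' @return n x 2 matrix of velocities.
#' @export
quad_velocity <- function(x, y, params) {
  p <- params
  d2 <- quad_check_regular(x, y, p)
  u <- 2 * p$alpha * ((y - p$b) / d2$d1 - (y + p$b) / d2$d2) -
    2 * p$beta * ((y - p$b) / d2$d3 - (y + p$b) / d2$d4)
  v <- -(2 * p$alpha * ((x - p$a) / d2$d1 - (x - p$a) / d2$d2) -
           2 * p$beta * ((x - p$c) / d2$d3 - (x - p$c) / d2$d4))
  cbind(u, v, deparse.level = 0)
}

#' Finite-difference harmonicity check of the stream function
#'
#' Evaluates the five-point Laplacian of `Psi` on a grid that excludes
#' disks around the four singular points; away from the point-like sources
#' `Psi` is harmonic, so the maximum should vanish at second order in the
#' grid spacing.
#'
#' @param params a `quadflow_params`.
#' @param xlim,ylim grid extents.
#' @param n grid points per side.
#' @param r_excl exclusion radius around the singularities (default
#'   `1e-3 |c - a|`; a grid point inside it violates the precondition).
#' @return max |Laplacian(Psi)| over the admissible grid, with attribute
#'   `h` (the spacing used).
#' @export
quad_check_harmonic <- function(params, xlim = c(-3, 3), ylim = c(-3, 3),
                                n = 61L,
                                r_excl = quad_exclusion_radius(params)) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  hx <- xs[2] - xs[1]; hy <- ys[2] - ys[1]
  g <- expand.grid(x = xs, y = ys)
  p <- params
  sing <- rbind(c(p$a, p$b), c(p$a, -p$b), c(p$c, p$b), c(p$c, -p$b))
  # the 5-point stencil must clear the singularities: margin of one spacing
  dmin <- apply(sing, 1, function(sp) sqrt((g$x - sp[1])^2 + (g$y - sp[2])^2))
  ok <- matrix(apply(dmin, 1, min) > (r_excl + max(hx, hy)), n, n)
  psi_g <- matrix(quad_psi_unchecked(g$x, g$y, p), n, n)
  core <- 2:(n - 1L)
  lap <- (psi_g[core - 1L, core] + psi_g[core + 1L, core] -
            2 * psi_g[core, core]) / hx^2 +
    (psi_g[core, core - 1L] + psi_g[core, core + 1L] -
       2 * psi_g[core, core]) / hy^2
  okc <- ok[core - 1L, core] & ok[core + 1L, core] & ok[core, core - 1L] &
    ok[core, core + 1L] & ok[core, core]
  if (!any(okc)) stop("quad_check_harmonic: no admissible grid points")
  structure(max(abs(lap[okc])), h = max(hx, hy))
}

# psi without the singularity guard (grid evaluation masks afterwards).
quad_psi_unchecked <- function(x, y, p) {
  d2 <- quad_d2(x, y, p)
  out <- p$alpha * log(d2$d1) - p$alpha * log(d2$d2) -
    p$beta * log(d2$d3) + p$beta * log(d2$d4)
  out[!is.finite(out)] <- 0
  out
}

#' Advect a passive contour in the frozen quadrupolar flow
#'
#' Classical 4th-order Runge-Kutta integration of marker points in the
#' analytic velocity field (the field is *not* updated as the contour
#' deforms). A marker entering the exclusion radius of a singularity halts
#' the integration with its index.
#'
#' @param contour k x 2 matrix of marker points.
#' @param params a `quadflow_params`.
#' @param dt time step.
#' @param n_steps number of steps.
#' @return list of k x 2 matrices, length `n_steps + 1` (including the
#'   initial contour).
#' @export
quad_advect_contour <- function(contour, params, dt, n_steps) {
  contour <- as.matrix(contour)
  k <- nrow(contour)
  p <- params
  r_excl <- quad_exclusion_radius(p)
  # the right-hand side skips the singularity guard (log terms stay finite
  # off the exact singular points); marker positions are checked per
  # recorded step below so the halt can name the offending marker
  rhs <- function(t, state, parms) {
    xy <- matrix(state, ncol = 2)
    d2 <- quad_d2(xy[, 1], xy[, 2], p)
    u <- 2 * p$alpha * ((xy[, 2] - p$b) / d2$d1 - (xy[, 2] + p$b) / d2$d2) -
      2 * p$beta * ((xy[, 2] - p$b) / d2$d3 - (xy[, 2] + p$b) / d2$d4)
    v <- -(2 * p$alpha * ((xy[, 1] - p$a) / d2$d1 -
                            (xy[, 1] - p$a) / d2$d2) -
             2 * p$beta * ((xy[, 1] - p$c) / d2$d3 -
                             (xy[, 1] - p$c) / d2$d4))
    list(c(u, v))
  }
  times <- seq(0, n_steps * dt, by = dt)
  sol <- deSolve::rk4(y = as.numeric(contour), times = times, func = rhs,
                      parms = NULL)
  out <- vector("list", n_steps + 1L)
  sing <- rbind(c(p$a, p$b), c(p$a, -p$b), c(p$c, p$b), c(p$c, -p$b))
  for (i in seq_len(n_steps + 1L)) {
    xy <- matrix(sol[i, -1L], ncol = 2)
    d2 <- vapply(seq_len(4L), function(s)
      (xy[, 1] - sing[s, 1])^2 + (xy[, 2] - sing[s, 2])^2, numeric(k))
    bad <- which(apply(matrix(d2, nrow = k), 1, min) < r_excl^2)
    if (length(bad) > 0L)
      stop("quad_advect_contour: marker ", bad[1L],
           " entered the singular exclusion zone at step ", i - 1L)
    out[[i]] <- xy
  }
  out
}

#' Stagnation (saddle) point of the flow on the symmetry axis
#'
#' For `alpha, beta > 0` exactly one stagnation point lies on `y = 0`
#' between the two source lines; found by root bracketing of the axial
#' velocity.
#'
#' @param params a `quadflow_params` with positive magnitudes.
#' @return x-coordinate of the saddle point.
#' @export
quad_saddle_x <- function(params) {
  p <- params
  stopifnot(p$alpha > 0, p$beta > 0)
  lo <- min(p$a, p$c); hi <- max(p$a, p$c)
  eps <- 1e-9 * (hi - lo)
  f <- function(x) quad_velocity(x, 0, p)[, 1]
  stats::uniroot(f, c(lo + eps, hi - eps), tol = 1e-12)$root
}
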