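# Quasi-static viscous plane problem: [sigma] = [H][d/dt eps], div sigma = 0
# in the bulk with prescribed boundary tractions/velocities, discretised
# with linear (P1) triangles and solved by direct sparse factorisation.
# The unknown is the velocity (displacement-rate) field; the mesh is then
# advanced explicitly in a Lagrangian fashion.

#' Viscous material model (Hooke-analog)
#'
#' The constitutive law relates stress to strain *rate* through a viscosity
#' matrix formally identical to a plane-stress Hooke tensor built from a
#' stiffness-analog `E_star` and a Poisson-analog `nu_star`. `softness` is a
#' per-region multiplier on `E_star` (tag -> factor in `[0, 1]`), used to
#' soften placode tissue.
#'
#' @param E_star stiffness-analog, > 0 (model stress units; default 2, the
#'   value used for the simulations over a body dimension of 0.4).
#' @param nu_star Poisson-analog in (-1, 0.5); default 0.45,
#'   near-incompressible but non-singular.
#' @param softness named numeric vector mapping region tags to factors.
#' @return object of class `material_model`.
#' @export
material_model <- function(E_star = 2, nu_star = 0.45, softness = c(`1` = 1)) {
  stopifnot(E_star > 0, nu_star > -1, nu_star < 0.5,
            all(softness >= 0), all(softness <= 1))
  structure(list(E_star = E_star, nu_star = nu_star, softness = softness),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("material_model: E* = %g, nu* = %g", x$E_star, x$nu_star))
  if (length(x$softness) > 1L)
    cat(";", paste(sprintf("tag %s: f=%g", names(x$softness), x$softness),
                   collapse = ", "))
  cat("\n")
  invisible(x)
}

# Plane-stress-analog viscosity matrix entries scaled per triangle.
h_entries <- function(material, mesh) {
  f <- material$softness[as.character(mesh$tags)]
  f[is.na(f)] <- 1
  E <- material$E_star * f
  nu <- material$nu_star
  co <- E / (1 - nu^2)
  list(d11 = co, d12 = co * nu, d33 = co * (1 - nu) / 2)
}

# Global 2n x 2n stiffness-analog matrix (dofs: u_1, v_1, u_2, v_2, ...).
assemble_viscous_matrix <- function(mesh, material) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  x <- matrix(v[tr, 1], ncol = 3); y <- matrix(v[tr, 2], ncol = 3)
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  A <- (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]) / 2   # signed, positive
  d <- h_entries(material, mesh)
  # degenerate softness f = 0 regions would make the system singular; such
  # placodes are excluded from the mesh at build time, enforce that here
  if (any(d$d11 <= 0))
    stop("assemble: zero-stiffness region present in the mesh; use f = 0 ",
         "exclusion at build time instead")
  ii <- jj <- xx <- vector("list", 36L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    kuu <- (d$d11 * b[, i] * b[, j] + d$d33 * cc[, i] * cc[, j]) / (4 * A)
    kuv <- (d$d12 * b[, i] * cc[, j] + d$d33 * cc[, i] * b[, j]) / (4 * A)
    kvu <- (d$d12 * cc[, i] * b[, j] + d$d33 * b[, i] * cc[, j]) / (4 * A)
    kvv <- (d$d11 * cc[, i] * cc[, j] + d$d33 * b[, i] * b[, j]) / (4 * A)
    du_i <- 2L * tr[, i] - 1L; dv_i <- 2L * tr[, i]
    du_j <- 2L * tr[, j] - 1L; dv_j <- 2L * tr[, j]
    ii[[k + 1L]] <- du_i; jj[[k + 1L]] <- du_j; xx[[k + 1L]] <- kuu
    ii[[k + 2L]] <- du_i; jj[[k + 2L]] <- dv_j; xx[[k + 2L]] <- kuv
    ii[[k + 3L]] <- dv_i; jj[[k + 3L]] <- du_j; xx[[k + 3L]] <- kvu
    ii[[k + 4L]] <- dv_i; jj[[k + 4L]] <- dv_j; xx[[k + 4L]] <- kvv
    k <- k + 4L
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2L * n, 2L * n))
}

# Edge-lumped nodal loads from per-vertex tractions along a curvature-field
# selection: each chain edge of length le contributes le/2 times the
# endpoint traction to each endpoint. trac: matrix nrow(curv) x 2.
traction_loads <- function(mesh, curv, trac) {
  n <- nrow(mesh$vertices)
  F <- numeric(2L * n)
  for (ip in unique(curv$part)) {
    sel <- which(curv$part == ip)
    vv <- curv$vertex[sel]
    P <- cbind(curv$x[sel], curv$y[sel])
    k <- length(vv)
    a <- seq_len(k - 1L); bidx <- a + 1L
    if (isTRUE(attr(curv, "closed"))) { a <- c(a, k); bidx <- c(bidx, 1L) }
    le <- sqrt(rowSums((P[bidx, , drop = FALSE] - P[a, , drop = FALSE])^2))
    for (side in list(cbind(a, le), cbind(bidx, le))) {
      iv <- vv[side[, 1]]
      w <- side[, 2] / 2
      F[2L * iv - 1L] <- F[2L * iv - 1L] + w * trac[sel[side[, 1]], 1]
      F[2L * iv] <- F[2L * iv] + w * trac[sel[side[, 1]], 2]
    }
  }
  F
}

# Loads from a traction function evaluated per boundary edge with the exact
# (domain-outward) edge normal: t(xm, ym, nx, ny) -> c(tx, ty) or an
# m x 2 matrix. Constant-per-edge tractions integrate exactly, which is
# what the patch test requires.
edge_traction_loads <- function(mesh, traction_fun, labels = NULL) {
  bd <- mesh$boundary
  if (!is.null(labels)) bd <- bd[bd$label %in% labels, , drop = FALSE]
  v <- mesh$vertices
  p1 <- v[bd$v1, , drop = FALSE]; p2 <- v[bd$v2, , drop = FALSE]
  ev <- p2 - p1
  le <- sqrt(rowSums(ev^2))
  sgn <- ifelse(bd$loop == 1L, 1, -1)   # outward normal flips on hole loops
  nxny <- cbind(ev[, 2], -ev[, 1]) / le * sgn
  mid <- (p1 + p2) / 2
  tt <- traction_fun(mid[, 1], mid[, 2], nxny[, 1], nxny[, 2])
  tt <- matrix(tt, ncol = 2)
  F <- numeric(2L * nrow(v))
  for (vcol in list(bd$v1, bd$v2)) {
    F[2L * vcol - 1L] <- F[2L * vcol - 1L] + le / 2 * tt[, 1]
    F[2L * vcol] <- F[2L * vcol] + le / 2 * tt[, 2]
  }
  F
}

# Consistent P1 nodal loads for a body-force density f(x, y) -> n x 2
# (one-point quadrature at centroids).
body_force_loads <- function(mesh, force_fun) {
  v <- mesh$vertices; tr <- mesh$triangles
  cent <- (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
             v[tr[, 3], , drop = FALSE]) / 3
  A <- triangle_areas(mesh)
  ff <- matrix(force_fun(cent[, 1], cent[, 2]), ncol = 2)
  F <- numeric(2L * nrow(v))
  for (i in 1:3) {
    F[2L * tr[, i] - 1L] <- F[2L * tr[, i] - 1L] + A / 3 * ff[, 1]
    F[2L * tr[, i]] <- F[2L * tr[, i]] + A / 3 * ff[, 2]
  }
  F
}

#' Solve the quasi-static viscous problem for the velocity field
#'
#' Assembles the P1 discretisation of `div sigma = 0` with the given nodal
#' loads / boundary tractions and Dirichlet constraints and solves it by
#' direct sparse factorisation. Rigid-body modes must be removed either by
#' the constraints or, for self-equilibrated loads, by the null-space
#' filter (Lagrange multipliers on mean translation and rotation).
#'
#' @param mesh a `trimesh`.
#' @param material a `material_model`.
#' @param loads numeric vector of nodal forces, length `2 n` (interleaved
#'   `u1, v1, u2, v2, ...`); may be omitted if `tractions` given.
#' @param tractions either a function `f(x, y, nx, ny)` evaluated per
#'   boundary edge (exact edge normal, domain-outward), or `NULL`.
#' @param body_force optional function `f(x, y)` of a body-force density.
#' @param dirichlet list with any of: `labels` (chains pinned), `vertices`
#'   (extra vertex ids), `values` (`NULL` for zero, or a function
#'   `f(xy)` returning an n_fixed x 2 matrix of prescribed velocities).
#' @param nullspace use the rigid-mode filter instead of Dirichlet pins.
#' @return `velocity_field`: an n x 2 matrix with attribute `residual`
#'   (relative algebraic residual on the free dofs).
#' @export
solve_velocity <- function(mesh, material, loads = NULL, tractions = NULL,
                           body_force = NULL, dirichlet = NULL,
                           nullspace = FALSE) {
  n <- nrow(mesh$vertices)
  K <- assemble_viscous_matrix(mesh, material)
  F <- numeric(2L * n)
  if (!is.null(loads)) F <- F + loads
  if (!is.null(tractions)) F <- F + edge_traction_loads(mesh, tractions)
  if (!is.null(body_force)) F <- F + body_force_loads(mesh, body_force)

  fixed_v <- integer(0); fixed_val <- NULL
  if (!is.null(dirichlet)) {
    for (lb in dirichlet$labels)
      fixed_v <- c(fixed_v, unlist(mesh_chain(mesh, lb)$parts))
    fixed_v <- sort(unique(c(fixed_v, dirichlet$vertices)))
    if (is.function(dirichlet$values)) {
      fixed_val <- dirichlet$values(mesh$vertices[fixed_v, , drop = FALSE])
    } else if (!is.null(dirichlet$values)) {
      fixed_val <- matrix(dirichlet$values, length(fixed_v), 2)
    } else {
      fixed_val <- matrix(0, length(fixed_v), 2)
    }
  }

  u <- numeric(2L * n)
  if (length(fixed_v) == 0L && !nullspace)
    stop("solve_velocity: singular system - unconstrained rigid-body modes ",
         "(null-space dimension 3); pin a boundary or set nullspace = TRUE")

  if (nullspace && length(fixed_v) == 0L) {
    xy <- mesh$vertices
    C <- Matrix::sparseMatrix(
      i = c(rep(1L, n), rep(2L, n), rep(3L, n), rep(3L, n)),
      j = c(2L * seq_len(n) - 1L, 2L * seq_len(n),
            2L * seq_len(n) - 1L, 2L * seq_len(n)),
      x = c(rep(1, n), rep(1, n), -xy[, 2], xy[, 1]),
      dims = c(3L, 2L * n))
    KKT <- rbind(cbind(K, Matrix::t(C)),
                 cbind(C, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               dims = c(3L, 3L))))
    sol <- Matrix::solve(KKT, c(F, 0, 0, 0))
    u <- as.numeric(sol[seq_len(2L * n)])
    free <- seq_len(2L * n)
  } else {
    fdof <- c(rbind(2L * fixed_v - 1L, 2L * fixed_v))
    u[2L * fixed_v - 1L] <- fixed_val[, 1]
    u[2L * fixed_v] <- fixed_val[, 2]
    free <- setdiff(seq_len(2L * n), fdof)
    rhs <- F[free] - as.numeric(K[free, fdof, drop = FALSE] %*% u[fdof])
    u[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs))
  }
  r <- as.numeric(K %*% u - F)[free]
  res <- sqrt(sum(r^2)) / max(sqrt(sum(F^2)), 1e-300)
  vel <- matrix(u, ncol = 2, byrow = TRUE)
  structure(vel, residual = res, class = c("velocity_field", "matrix", "array"))
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- sqrt(rowSums(unclass(x)^2))
  cat(sprintf("velocity_field: %d vertices, max speed %.4g, residual %.2e\n",
              nrow(x), max(sp), attr(x, "residual")))
  invisible(x)
}

#' CFL-limited time step
#'
#' @param mesh a `trimesh`.
#' @param velocity a `velocity_field`.
#' @param cfl Courant factor (fraction of the shortest edge a vertex may
#'   travel per step).
#' @param dt_max upper bound (also returned for a quiescent field).
#' @return time step (model time).
#' @export
cfl_dt <- function(mesh, velocity, cfl = 0.2, dt_max = Inf) {
  vmax <- max(sqrt(rowSums(unclass(velocity)^2)))
  if (vmax <= 0) return(dt_max)
  min(cfl * min_edge_length(mesh) / vmax, dt_max)
}

#' Advance the mesh one explicit Lagrangian step
#'
#' Moves every vertex by `velocity * dt` and re-checks element orientation.
#' An inverted element raises a condition of class `morphosim_inversion`;
#' the caller (the time loop) halves `dt` or remeshes.
#'
#' @param mesh a `trimesh`.
#' @param velocity a `velocity_field` (n x 2).
#' @param dt time step, > 0.
#' @return the advected `trimesh` (same connectivity and labels).
#' @export
advance_mesh <- function(mesh, velocity, dt) {
  stopifnot(dt > 0)
  out <- mesh
  out$vertices <- mesh$vertices + dt * unclass(velocity)
  a <- triangle_areas(out)
  if (any(a <= 0))
    stop(structure(class = c("morphosim_inversion", "error", "condition"),
                   list(message = paste0("advance_mesh: ", sum(a <= 0),
                                         " element(s) inverted at dt = ", dt),
                        call = sys.call(-1))))
  out
}
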