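test_that("patch test: uniform strain rate is reproduced to machine precision", {
  m <- build_rectangle_structured(2, 1, 8, 4)
  mat <- default_material()
  E <- mat$E_star; nu <- mat$nu_star; co <- E / (1 - nu^2)
  sxx <- co * 0.1; syy <- co * nu * 0.1     # consistent with eps_xx = 0.1
  exact <- function(xy) cbind(0.1 * xy[, 1], 0 * xy[, 2])
  vel <- solve_velocity(
    m, mat,
    tractions = function(x, y, nx, ny) cbind(sxx * nx, syy * ny),
    dirichlet = list(labels = "left", values = exact))
  expect_lt(max(abs(unclass(vel) - exact(m$vertices))), 1e-12)
  expect_lt(attr(vel, "residual"), 1e-10)
})

test_that("zero tractions give an exactly zero velocity field", {
  vel <- solve_velocity(build_rectangle_structured(1, 1, 4, 4),
                        default_material(),
                        dirichlet = list(labels = "left"))
  expect_true(all(unclass(vel) == 0))
})

test_that("annulus under hole pressure matches the axisymmetric oracle", {
  a <- 0.3; b <- 1.0; p <- 1
  m <- build_annulus(b, a, 0.05)
  mat <- default_material()
  cv <- boundary_curvature(m, "hole")
  loads <- morphosim:::traction_loads(m, cv, normal_pressure_traction(cv, p))
  vel <- solve_velocity(m, mat, loads = loads,
                        dirichlet = list(labels = "outer"))
  # plane-stress Lame solution u = A r + B / r with sigma_rr(a) = p, u(b) = 0
  E <- mat$E_star; nu <- mat$nu_star; co <- E / (1 - nu^2)
  A <- p / (co * ((1 + nu) + (1 - nu) * b^2 / a^2))
  u_a <- A * (a - b^2 / a)
  hv <- cv$vertex
  r <- sqrt(rowSums(m$vertices[hv, ]^2))
  vr <- rowSums(unclass(vel)[hv, ] * m$vertices[hv, ] / r)
  expect_equal(mean(vr), u_a, tolerance = 0.02)
  expect_lt(stats::sd(vr) / abs(mean(vr)), 0.01)   # angular uniformity
})

test_that("manufactured solution converges at second order", {
  mat <- default_material()
  errs <- c(); hs <- c()
  for (nx in c(8, 16, 32)) {
    m <- build_rectangle_structured(1, 1, nx, nx)
    vel <- solve_velocity(m, mat, dirichlet = list(
      labels = c("left", "right", "top", "bottom"),
      values = manufactured_exact))
    errs <- c(errs, nodal_rms(m, vel, manufactured_exact))
    hs <- c(hs, 1 / nx)
  }
  order <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
  expect_gte(order, 1.9)
})

test_that("unconstrained systems fail loudly, the null-space filter works", {
  m <- build_rectangle_structured(1, 1, 4, 4)
  expect_error(solve_velocity(m, default_material()), "null-space dimension 3")
  vel <- solve_velocity(m, default_material(), nullspace = TRUE)
  expect_lt(max(abs(vel)), 1e-10)
})

test_that("mirror-symmetric problems give mirror-antisymmetric velocities", {
  nx <- 8; ny <- 4
  m <- build_rectangle_structured(2, 1, nx, ny)
  mat <- default_material()
  vel <- solve_velocity(
    m, mat,
    tractions = function(x, y, nxv, nyv) cbind(0 * x, -0.5 * (y > 0.5)),
    dirichlet = list(labels = c("left", "right")))
  # structured grid: mirror of grid vertex (i, j) is (nx + 2 - i, j)
  v <- m$vertices
  mirror <- match(paste(round(2 - v[, 1], 12), round(v[, 2], 12)),
                  paste(round(v[, 1], 12), round(v[, 2], 12)))
  u <- unclass(vel)
  expect_lt(max(abs(u[, 1] + u[mirror, 1])), 1e-10)
  expect_lt(max(abs(u[, 2] - u[mirror, 2])), 1e-10)
})

test_that("explicit Lagrangian stepping moves, preserves and rejects", {
  m <- build_rectangle_structured(1, 1, 4, 4)
  n <- nrow(m$vertices)
  vf <- function(mat) structure(mat, class = c("velocity_field", "matrix",
                                               "array"))
  # zero velocity: identical coordinates
  m0 <- advance_mesh(m, vf(matrix(0, n, 2)), 0.1)
  expect_identical(m0$vertices, m$vertices)
  # uniform translation is exact
  m1 <- advance_mesh(m, vf(cbind(rep(1, n), rep(0, n))), 0.1)
  expect_equal(m1$vertices[, 1], m$vertices[, 1] + 0.1, tolerance = 1e-15)
  # rigid rotation at small dt: area drift is O(dt^2)
  om <- cbind(-m$vertices[, 2], m$vertices[, 1])
  m2 <- advance_mesh(m, vf(om), 1e-3)
  expect_lt(abs(mesh_area(m2) - mesh_area(m)) / mesh_area(m), 1e-5)
  # inversion is rejected as a typed condition
  vbad <- matrix(0, n, 2)
  vbad[m$triangles[1, 1], ] <- c(10, 10)
  expect_error(advance_mesh(m, vf(vbad), 1), class = "morphosim_inversion")
})

test_that("quiescent runs terminate immediately with an unchanged mesh", {
  m <- small_annulus()
  res <- simulate_morphogenesis(m, default_material(), actuators = list(),
                                constraints = list(fix = "outer"),
                                stop = list(max_steps = 10L,
                                            quiescence_tol = 1e-12))
  expect_identical(res$stopped_by, "quiescence")
  expect_identical(res$mesh$vertices, m$vertices)
})

test_that("a contracting shear pair self-arrests (speed decays)", {
  res <- run_scenario_cached("crenel_ear")
  vmax <- res$trace$vmax[-1]
  n <- length(vmax)
  early <- stats::median(vmax[seq_len(ceiling(n / 3))])
  late <- stats::median(vmax[(n - ceiling(n / 3)):n])
  expect_lt(late, early)
  # and the late trace is non-increasing up to small remesh jitter
  sm <- stats::runmed(vmax, 5)
  expect_true(all(diff(sm[-seq_len(ceiling(n / 5))]) < 0.02 * early))
})
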