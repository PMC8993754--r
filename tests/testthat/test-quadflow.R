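p_sym <- quadflow_params(a = -1, c = 1, b = 1, alpha = 1, beta = 1)
p_asym <- quadflow_params(a = -1, c = 1, b = 1, alpha = 1, beta = 0.6)

test_that("the stream function obeys its exact symmetries", {
  # odd in y: identically zero on the axis
  expect_identical(quad_psi(c(-2, 0.3, 4), c(0, 0, 0), p_asym), rep(0, 3))
  # alpha = beta: zero on the mirror plane x = (a + c) / 2
  expect_equal(quad_psi(c(0, 0), c(0.7, -1.9), p_sym), c(0, 0),
               tolerance = 1e-14)
  # zero sources: zero everywhere
  p0 <- quadflow_params(a = -1, c = 1, b = 1, alpha = 0, beta = 0)
  expect_identical(quad_psi(0.3, 0.9, p0), 0)
  # evaluation at a singularity is a domain error
  expect_error(quad_psi(-1, 1, p_sym), "singularity")
})

test_that("analytic velocity matches finite differences of psi", {
  set.seed(7)
  for (i in 1:20) {
    x <- stats::runif(1, -2.5, 2.5); y <- stats::runif(1, -2.5, 2.5)
    if (min((x - c(-1, -1, 1, 1))^2 + (y - c(1, -1, 1, -1))^2) < 0.04) next
    v <- quad_velocity(x, y, p_asym)
    h <- 1e-5
    u_fd <- (quad_psi(x, y + h, p_asym) - quad_psi(x, y - h, p_asym)) / (2 * h)
    v_fd <- -(quad_psi(x + h, y, p_asym) - quad_psi(x - h, y, p_asym)) / (2 * h)
    expect_equal(v[1, 1], u_fd, tolerance = 1e-6)
    expect_equal(v[1, 2], v_fd, tolerance = 1e-6)
    # divergence-free by construction
    div <- (quad_velocity(x + h, y, p_asym)[1] -
              quad_velocity(x - h, y, p_asym)[1]) / (2 * h) +
      (quad_velocity(x, y + h, p_asym)[2] -
         quad_velocity(x, y - h, p_asym)[2]) / (2 * h)
    expect_lt(abs(div), 1e-6)
  }
  # v vanishes identically on the axis
  expect_equal(quad_velocity(c(-2, 0.5, 3), c(0, 0, 0), p_asym)[, 2],
               rep(0, 3), tolerance = 1e-15)
})

test_that("psi is harmonic away from sources, at second order", {
  # nested grids on a window clear of the sources
  win <- list(xlim = c(1.8, 3), ylim = c(-0.5, 0.5), r_excl = 0.3)
  l_coarse <- do.call(quad_check_harmonic, c(list(p_asym, n = 41L), win))
  l_fine <- do.call(quad_check_harmonic, c(list(p_asym, n = 81L), win))
  expect_gt(l_coarse / l_fine, 3)    # ~4 for a second-order stencil
  # a grid overlapping a singularity violates the precondition
  expect_error(quad_check_harmonic(p_asym, xlim = c(0.9, 1.1),
                                   ylim = c(0.9, 1.1), n = 11L,
                                   r_excl = 0.5), "no admissible")
  # zero sources: exactly zero Laplacian
  p0 <- quadflow_params(alpha = 0, beta = 0)
  expect_equal(as.numeric(quad_check_harmonic(p0, r_excl = 0.5)), 0)
})

test_that("the flow has exactly one stagnation point between the sources", {
  expect_equal(quad_saddle_x(p_sym), 0, tolerance = 1e-9)
  xs <- quad_saddle_x(p_asym)
  expect_true(xs > -1 && xs < 1)
  # uniqueness: the axial velocity changes sign exactly once
  grid <- seq(-0.98, 0.98, length.out = 400)
  u <- quad_velocity(grid, rep(0, 400), p_asym)[, 1]
  expect_equal(sum(diff(sign(u)) != 0), 1L)
})

test_that("passive contour advection respects the flow's invariants", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  cont <- cbind(0.3 * cos(th) + 0.2, 0.3 * sin(th) + 1.8)
  seqs <- quad_advect_contour(cont, p_asym, dt = 0.002, n_steps = 200)
  # closed contour: enclosed area conserved (incompressible flow)
  a0 <- abs(polygon_area(seqs[[1]])); a1 <- abs(polygon_area(seqs[[201]]))
  expect_lt(abs(a1 - a0) / a0, 0.001)
  # markers stay on their streamline: psi constant along trajectories
  ps <- vapply(seqs, function(xy) quad_psi(xy[1, 1], xy[1, 2], p_asym),
               numeric(1))
  expect_lt(max(abs(ps - ps[1])), 1e-8 * max(1, abs(ps[1])))
  # a contour on the axis stays on the axis
  axis_pts <- cbind(seq(-0.5, 0.5, 0.1), 0)
  out <- quad_advect_contour(axis_pts, p_sym, 0.01, 50)
  expect_equal(max(abs(out[[51]][, 2])), 0, tolerance = 1e-14)
  # alpha = beta: a mirror-symmetric contour stays mirror-symmetric;
  # marker k at angle theta_k pairs with the marker at pi - theta_k
  cont2 <- cbind(0.4 * cos(th), 0.4 * sin(th) + 1.6)
  fin <- quad_advect_contour(cont2, p_sym, 0.002, 100)[[101]]
  k <- seq_len(nrow(fin)) - 1L
  mirror <- ((50L - k) %% 100L) + 1L
  expect_equal(fin[mirror, 1], -fin[, 1], tolerance = 1e-9)
  expect_equal(fin[mirror, 2], fin[, 2], tolerance = 1e-9)
  # a marker inside the exclusion zone halts with its index
  expect_error(quad_advect_contour(rbind(c(-1.001, 1.0)), p_sym, 0.01, 10),
               "marker 1")
})

test_that("parameter validation rejects degenerate quadrupoles", {
  expect_error(quadflow_params(a = 1, c = 1), "a != c")
  expect_error(quadflow_params(b = 0), "b > 0")
})
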