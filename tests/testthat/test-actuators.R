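circle_curv <- function(R, n = 64) {
  m <- build_annulus(3 * R, R, min(0.049 * R / 0.05, R / 2))
  boundary_curvature(m, "hole")
}

test_that("line tension produces the Laplace traction T/R toward the centre", {
  cv <- circle_curv(0.5)
  tr <- line_tension_traction(cv, 1)
  mag <- sqrt(rowSums(tr^2))
  expect_equal(mean(mag), 2.0, tolerance = 0.02)
  # pointing toward the hole centre (origin)
  inward <- -(cbind(cv$x, cv$y)) / sqrt(cv$x^2 + cv$y^2)
  expect_gt(min(rowSums(tr * inward) / mag), 0.999)
  # zero tension and straight targets give exactly nothing
  expect_true(all(line_tension_traction(cv, 0) == 0))
  mb <- small_body()
  cvs <- boundary_curvature(mb, "ventral")
  inner <- !cvs$terminal      # chain ends sit at rectangle corners
  expect_true(all(line_tension_traction(cvs, 1)[inner, ] == 0))
})

test_that("line-tension tractions on a closed loop are self-equilibrated", {
  cv <- circle_curv(0.5)
  tr <- line_tension_traction(cv, 1)
  ds <- c(diff(cv$s), sqrt((cv$x[1] - cv$x[nrow(cv)])^2 +
                             (cv$y[1] - cv$y[nrow(cv)])^2))
  net <- colSums(tr * ds)
  expect_lt(sqrt(sum(net^2)) / sum(sqrt(rowSums(tr^2)) * ds), 1e-6)
})

test_that("normal pressure is curvature-independent with decaying total force", {
  cv <- circle_curv(0.5)
  tr <- normal_pressure_traction(cv, 1)
  expect_equal(sqrt(rowSums(tr^2)), rep(1, nrow(cv)), tolerance = 1e-12)
  # total force = P * perimeter, so it shrinks with the circle
  for (R in c(0.5, 0.25)) {
    cvR <- circle_curv(R)
    ds <- c(diff(cvR$s), sqrt((cvR$x[1] - cvR$x[nrow(cvR)])^2 +
                                (cvR$y[1] - cvR$y[nrow(cvR)])^2))
    expect_equal(sum(sqrt(rowSums(normal_pressure_traction(cvR, 1)^2)) * ds),
                 2 * pi * R, tolerance = 0.01)
  }
})

test_that("pressure at a square corner acts along the half-angle bisector", {
  m <- build_rectangle_structured(1, 1, 4, 4)
  cv <- boundary_curvature(m, "all-external")
  tr <- normal_pressure_traction(cv, 1)
  corner <- which(cv$x == 0 & cv$y == 0)
  # inward bisector at the (0, 0) corner is (1, 1) / sqrt(2)
  expect_equal(unname(tr[corner, ]), c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("shear pairs act head-on, split at the arclength midpoint", {
  m <- small_body()
  cv <- boundary_curvature(m, "ear_base")
  tr <- shear_pair_traction(cv, 1)
  s_mid <- (cv$s[1] + cv$s[nrow(cv)]) / 2
  left <- cv$s < s_mid - 1e-12; right <- cv$s > s_mid + 1e-12
  expect_true(all(tr[left, 1] > 0.999))    # +x, toward the midpoint
  expect_true(all(tr[right, 1] < -0.999))  # -x, toward the midpoint
  expect_true(all(shear_pair_traction(cv, 0) == 0))
  # swapping contract <-> extend negates exactly
  expect_identical(shear_pair_traction(cv, 1, sense = "extend"), -tr)
  # asymmetry scales the second half only; net force becomes nonzero
  tra <- shear_pair_traction(cv, 1, asymmetry = 0.5)
  expect_equal(max(abs(tra[right, 1])), 0.5, tolerance = 1e-12)
  # net force via the edge-lumped loads: zero for the symmetric pair,
  # nonzero under asymmetry
  loads_sym <- morphosim:::traction_loads(m, cv, tr)
  loads_asym <- morphosim:::traction_loads(m, cv, tra)
  expect_lt(abs(sum(loads_sym[seq(1, length(loads_sym), 2)])), 1e-12)
  expect_gt(abs(sum(loads_asym[seq(1, length(loads_asym), 2)])), 0.01)
  expect_error(shear_pair_traction(cv[1:3, ], 1), "fewer than 4")
})

test_that("tension gradients point toward the requested direction", {
  m <- small_body()
  cv <- boundary_curvature(m, "neck")    # vertical segment
  tr <- tension_gradient_traction(cv, 1, c(0, 1))
  expect_true(all(tr[!cv$terminal, 2] > 0.999))
  expect_true(all(tension_gradient_traction(cv, 0, c(0, 1)) == 0))
})

test_that("a tangential gradient advects the placode centroid dorsally", {
  m <- build_body(2, 1, list(list(position = 1, width = 0.3, depth = 0.2)),
                  0, 0.1)
  mat <- material_model(2, 0.45, softness = attr(m, "softness"))
  cy0 <- shape_metrics(m, placode_outline(m))$centroid[2]
  res <- simulate_morphogenesis(
    m, mat,
    actuators = list(actuator("tension_gradient", "ear_crenel",
                              strength = 0.3, direction = c(0, 1))),
    constraints = list(fix = "neck"),
    stop = list(max_steps = 8L),
    observables = list(cy = function(ms)
      shape_metrics(ms, placode_outline(ms))$centroid[2]))
  expect_gt(res$trace$cy[nrow(res$trace)], cy0)
})

test_that("negative surface tension grows convex contours outward", {
  cv <- circle_curv(0.5)
  # clamp convention: growth only where convex (kappa > 0), zero in
  # concavities, unless the unclamped signed form is requested
  mixed <- data.frame(kappa = c(2, -1, 0, 3), nx = c(1, 1, 1, 1),
                      ny = c(0, 0, 0, 0), terminal = FALSE)
  expect_equal(neg_surface_tension_traction(mixed, 1, 1)[, 1],
               c(2, 0, 0, 3))
  expect_equal(neg_surface_tension_traction(mixed, 1, 1,
                                            clamp = FALSE)[, 1],
               c(2, -1, 0, 3))
  # magnitudes kappa^m on a circle
  tr1 <- neg_surface_tension_traction(cv, 1, 1, clamp = FALSE)
  tr2 <- neg_surface_tension_traction(cv, 1, 2, clamp = FALSE)
  expect_equal(mean(sqrt(rowSums(tr1^2))), 2, tolerance = 0.02)
  expect_equal(mean(sqrt(rowSums(tr2^2))), 4, tolerance = 0.04)
  # m = 2 on circles R and R/2: tip tractions in ratio 1:4
  cvh <- circle_curv(0.25)
  trh <- neg_surface_tension_traction(cvh, 1, 2, clamp = FALSE)
  expect_equal(mean(sqrt(rowSums(trh^2))) / mean(sqrt(rowSums(tr2^2))), 4,
               tolerance = 0.05)
  # flat segments feel nothing under either exponent
  mb <- small_body()
  cvs <- boundary_curvature(mb, "ventral")
  expect_true(all(neg_surface_tension_traction(cvs, 1, 1) == 0))
  expect_true(all(neg_surface_tension_traction(cvs, 1, 2) == 0))
  # (corner terminals are excluded from growth by convention)
  expect_error(neg_surface_tension_traction(cv, 1, 3), "m must be 1 or 2")
})

test_that("actuators referencing missing labels are configuration errors", {
  m <- small_annulus()
  act <- actuator("line_tension", "nonexistent", T = 1)
  expect_error(
    simulate_morphogenesis(m, default_material(), actuators = list(act),
                           constraints = list(fix = "outer"),
                           stop = list(max_steps = 2L)),
    "config error")
})
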