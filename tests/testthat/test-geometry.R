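test_that("annulus mesh reproduces circle perimeter and area", {
  m <- build_annulus(1.0, 0.3, 0.05)
  expect_equal(chain_length(m, "hole"), 2 * pi * 0.3, tolerance = 0.01)
  expect_equal(mesh_area(m), pi * (1 - 0.09), tolerance = 0.01)
  expect_gte(length(m$chains$hole$parts[[1]]), 16L)
  expect_true(all(triangle_areas(m) > 0))
})

test_that("degenerate annulus parameters are rejected", {
  expect_error(build_annulus(1.0, 0.999, 0.05), "too thin")
  expect_error(build_annulus(1.0, 0, 0.05), "hole_radius")
  expect_error(build_annulus(1.0, 0.3, 0.4), "edge_length")
})

test_that("body outline matches the independent polygon-perimeter oracle", {
  # internal placode: the outline is the plain rectangle
  m <- build_body(2, 1, list(list(position = 1, width = 0.3, depth = 0.2)),
                  0, 0.05)
  oracle_rect <- polygon_perimeter(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
  expect_equal(polygon_perimeter(m$vertices[m$loops[[1]], ]), oracle_rect,
               tolerance = 1e-12)
  # hairpin chain: two walls of the depth plus the base width
  expect_equal(chain_length(m, "ear_crenel"), 0.3 + 2 * 0.2,
               tolerance = 1e-12)
  expect_equal(chain_length(m, "ear_base"), 0.3, tolerance = 1e-12)
  # absent tissue (f = 0): open notch adds two wall depths to the outline
  m0 <- build_body(2, 1,
                   list(list(position = 1, width = 0.3, depth = 0.2, f = 0)),
                   0, 0.05)
  notch_outline <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1.15, 1),
                         c(1.15, 0.8), c(0.85, 0.8), c(0.85, 1), c(0, 1))
  expect_equal(polygon_perimeter(m0$vertices[m0$loops[[1]], ]),
               polygon_perimeter(notch_outline), tolerance = 1e-12)
  expect_equal(mesh_area(m0), 2 - 0.3 * 0.2, tolerance = 0.01)
})

test_that("plain rectangle body has four labels and the right area", {
  m <- build_body(2.0, 1.0, list(), 0, 0.05)
  expect_setequal(names(m$chains), c("ventral", "neck", "dorsal", "mouth"))
  expect_equal(mesh_area(m), 2.0, tolerance = 0.01)
})

test_that("placode material tags, softness and trapeze shape are set", {
  m <- build_body(2, 1, list(list(position = 1, width = 0.3, depth = 0.2,
                                  f = 0.25)), 0, 0.05)
  expect_equal(sum(triangle_areas(m)[m$tags == 2L]), 0.06, tolerance = 0.02)
  expect_equal(unname(attr(m, "softness")["2"]), 0.25)
  tz <- build_body(2, 1, list(list(position = 1, width = 0.3, depth = 0.2,
                                   shape = "trapeze")), 0, 0.05)
  # trapeze: top width w, bottom width w/2
  expect_equal(abs(polygon_area(placode_outline(tz))),
               0.2 * (0.3 + 0.15) / 2, tolerance = 1e-10)
})

test_that("overlapping or out-of-footprint placodes are rejected", {
  expect_error(build_body(2, 1, list(
    list(position = 1.0, width = 0.4, depth = 0.2),
    list(position = 1.3, width = 0.4, depth = 0.2)), 0, 0.05), "overlap")
  expect_error(build_body(2, 1, list(
    list(position = 0.1, width = 0.4, depth = 0.2)), 0, 0.05), "footprint")
})

test_that("corner smoothing arcs carry curvature 1/r", {
  m <- build_body(1.2, 1.0, list(), 0.1, 0.04)
  cv <- boundary_curvature(m, "mouth")
  expect_equal(max(cv$kappa), 1 / 0.1, tolerance = 0.1)
})

test_that("discrete curvature matches analytic values", {
  # circle R = 0.5 at 64 points
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  mesh_like <- list()  # curvature is geometric: test through an annulus hole
  m <- build_annulus(1.5, 0.5, 0.049)
  cv <- boundary_curvature(m, "hole")
  expect_true(all(abs(cv$kappa - 2.0) / 2.0 < 0.02))
  # normals and tangents are orthonormal
  expect_true(all(abs(cv$nx^2 + cv$ny^2 - 1) < 1e-12))
  expect_true(all(abs(cv$nx * cv$tx + cv$ny * cv$ty) < 1e-12))
  # straight segment: exactly zero away from the corner terminals
  mb <- build_body(2, 1, list(), 0, 0.1)
  cvv <- boundary_curvature(mb, "ventral")
  expect_true(all(cvv$kappa[!cvv$terminal] == 0))
})

test_that("ellipse curvature at the apex matches a/b^2", {
  # ellipse boundary evaluated through the circumcircle stencil directly
  a <- 1; b <- 0.5
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  P <- cbind(a * cos(th), b * sin(th))
  n <- nrow(P)
  Pm <- P[c(n, 1:(n - 1)), ]; Pp <- P[c(2:n, 1), ]
  e1 <- P - Pm; e2 <- Pp - P
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  l3 <- sqrt(rowSums((Pp - Pm)^2))
  kap <- 2 * (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / (l1 * l2 * l3)
  expect_equal(kap[1], a / b^2, tolerance = 0.03)   # vertex at (a, 0)
})

test_that("Gauss-Bonnet holds on closed convex loops", {
  m <- build_annulus(1, 0.3, 0.05)
  for (lb in c("outer", "hole")) {
    cv <- boundary_curvature(m, lb)
    ds <- c(diff(cv$s), sqrt((cv$x[1] - cv$x[nrow(cv)])^2 +
                               (cv$y[1] - cv$y[nrow(cv)])^2))
    expect_equal(sum(cv$kappa * ds), 2 * pi, tolerance = 0.02)
  }
})

test_that("remeshing is a no-op on a healthy mesh and repairs slivers", {
  m <- small_annulus()
  expect_identical(remesh_if_needed(m, 0.2), m)
  # squash an interior vertex onto a neighbour to create a sliver
  interior <- setdiff(seq_len(nrow(m$vertices)), unique(unlist(m$loops)))
  v <- intersect(interior, as.vector(m$triangles))[1]
  row <- which(apply(m$triangles == v, 1, any))[1]
  other <- setdiff(m$triangles[row, ], v)[1]
  bad <- m
  bad$vertices[v, ] <- m$vertices[other, ] +
    1e-4 * (m$vertices[v, ] - m$vertices[other, ])
  expect_lt(min(triangle_quality(bad)), 0.2)
  fixed <- remesh_if_needed(bad, 0.2)
  expect_gte(min(triangle_quality(fixed)), 0.2)
  # boundary vertices preserved exactly, area preserved tightly
  expect_identical(fixed$vertices[fixed$loops[[1]], ],
                   bad$vertices[bad$loops[[1]], ])
  expect_equal(mesh_area(fixed), mesh_area(bad), tolerance = 0.005)
})

test_that("a self-intersecting boundary halts with the segment pair", {
  bowtie <- rbind(c(0, 0), c(2, 0), c(0, 1.3), c(2, 1.6))
  expect_error(
    morphosim:::mesh_domain(list(list(xy = bowtie,
                                      labels = rep("b", 4))), 0.2),
    "self-intersection|positive")
})
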