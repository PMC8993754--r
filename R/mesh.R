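#' Triangulated 2D domain with labeled boundary chains
#'
#' A `trimesh` is the evolving Lagrangian reference configuration of the
#' tissue: vertices, positively oriented triangles, a labeled boundary edge
#' set, ordered label chains (boundary sub-chains and interior feature lines
#' such as the dorso-ventral segment under a placode), per-triangle material
#' region tags, and the target edge length used to build it.
#'
#' @param vertices n x 2 numeric matrix.
#' @param triangles m x 3 integer matrix, counter-clockwise.
#' @param boundary data.frame with columns `v1`, `v2` (vertex indices,
#'   directed along the loop) and `label`.
#' @param chains named list; each element `list(parts, closed, loop, kind)`
#'   where `parts` is a list of ordered vertex paths (a label interrupted by
#'   a placode contributes several parts), `kind` is `"boundary"` or
#'   `"interior"` and `loop` the owning loop index (NA for interior chains).
#' @param loops list of integer vertex cycles (loop 1 is the external
#'   contour, counter-clockwise by enclosed area; holes likewise stored
#'   with positive enclosed area).
#' @param tags integer vector, one material region tag per triangle.
#' @param regions list describing how tags are recovered after a remesh:
#'   each element `list(tag, chain_labels)` names the closed chain sequence
#'   bounding that region.
#' @param h target edge length (model units).
#' @param validate run the validity checks.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, triangles, boundary, chains, loops,
                    tags = NULL, regions = list(), h = NA_real_,
                    validate = TRUE) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(triangles) <- "integer"
  triangles <- unname(as.matrix(triangles))
  if (is.null(tags)) tags <- rep(1L, nrow(triangles))
  m <- structure(
    list(vertices = vertices, triangles = triangles, boundary = boundary,
         chains = chains, loops = loops, tags = as.integer(tags),
         regions = regions, h = h),
    class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

#' @export
print.trimesh <- function(x, ...) {
  q <- triangle_quality(x)
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles,", nrow(x$boundary), "boundary edges\n")
  cat("  labels:", paste(names(x$chains), collapse = ", "), "\n")
  cat(sprintf("  area %.5g, min quality %.3f, h = %.4g\n",
              mesh_area(x), min(q), x$h))
  invisible(x)
}

# Validity: positive orientation, boundary edge/one-triangle property,
# label partition, chain consistency.
validate_trimesh <- function(m) {
  a <- triangle_areas(m)
  if (any(a <= 0)) stop("trimesh: ", sum(a <= 0), " non-positively oriented triangle(s)")
  ec <- edge_counts(m)
  b1 <- pmin(m$boundary$v1, m$boundary$v2)
  b2 <- pmax(m$boundary$v1, m$boundary$v2)
  key <- paste(b1, b2)
  cnt <- ec$count[match(key, ec$key)]
  if (anyNA(cnt) || any(cnt != 1L))
    stop("trimesh: boundary edges must belong to exactly one triangle")
  mesh_b <- ec$key[ec$count == 1L]
  if (length(setdiff(mesh_b, key)) > 0L)
    stop("trimesh: unlabeled boundary edges present")
  if (anyDuplicated(key)) stop("trimesh: boundary edge labeled more than once")
  if (length(m$tags) != nrow(m$triangles))
    stop("trimesh: one region tag per triangle required")
  for (nm in names(m$chains)) {
    ch <- m$chains[[nm]]
    if (any(lengths(ch$parts) < 2L))
      stop("trimesh: chain '", nm, "' has a degenerate part")
  }
  invisible(TRUE)
}

# Undirected edge multiplicity table of the triangulation.
edge_counts <- function(m) {
  tr <- m$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tb <- table(key)
  list(key = names(tb), count = as.integer(tb))
}

#' Signed areas of all triangles
#' @param m a `trimesh`.
#' @return numeric vector of length `n_triangles`.
#' @export
triangle_areas <- function(m) {
  v <- m$vertices; tr <- m$triangles
  x1 <- v[tr[, 1], 1]; y1 <- v[tr[, 1], 2]
  x2 <- v[tr[, 2], 1]; y2 <- v[tr[, 2], 2]
  x3 <- v[tr[, 3], 1]; y3 <- v[tr[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Total mesh area
#' @param m a `trimesh`.
#' @return scalar area.
#' @export
mesh_area <- function(m) sum(triangle_areas(m))

#' Radius-ratio triangle quality
#'
#' Quality 2 r_in / r_circ per triangle: 1 for equilateral, 0 degenerate.
#'
#' @param m a `trimesh`.
#' @return numeric vector in (0, 1].
#' @export
triangle_quality <- function(m) {
  v <- m$vertices; tr <- m$triangles
  a <- sqrt(rowSums((v[tr[, 2], ] - v[tr[, 3], ])^2))
  b <- sqrt(rowSums((v[tr[, 1], ] - v[tr[, 3], ])^2))
  cc <- sqrt(rowSums((v[tr[, 1], ] - v[tr[, 2], ])^2))
  A <- abs(triangle_areas(m))
  s <- (a + b + cc) / 2
  r_in <- A / s
  r_circ <- a * b * cc / (4 * A)
  2 * r_in / r_circ
}

# Shortest triangle edge in the mesh (CFL length scale).
min_edge_length <- function(m) {
  v <- m$vertices; tr <- m$triangles
  min(sqrt(rowSums((v[tr[, 2], ] - v[tr[, 3], ])^2)),
      sqrt(rowSums((v[tr[, 1], ] - v[tr[, 3], ])^2)),
      sqrt(rowSums((v[tr[, 1], ] - v[tr[, 2], ])^2)))
}

#' Ordered coordinates of a labeled chain
#' @param m a `trimesh`.
#' @param label chain label.
#' @param part which part of the chain (labels interrupted by a placode
#'   have several parts).
#' @return k x 2 matrix of vertex coordinates in chain order.
#' @export
chain_xy <- function(m, label, part = 1L) {
  ch <- mesh_chain(m, label)
  m$vertices[ch$parts[[part]], , drop = FALSE]
}

# Chain lookup with a configuration error on a missing label.
mesh_chain <- function(m, label) {
  ch <- m$chains[[label]]
  if (is.null(ch))
    stop("morphosim config error: no boundary/chain label '", label,
         "' in mesh (have: ", paste(names(m$chains), collapse = ", "), ")",
         call. = FALSE)
  ch
}

#' Length of a labeled chain polyline
#' @param m a `trimesh`.
#' @param label chain label.
#' @return total arclength over all parts (closing edge included for a
#'   closed chain).
#' @export
chain_length <- function(m, label) {
  ch <- mesh_chain(m, label)
  sum(vapply(ch$parts, function(p) {
    xy <- m$vertices[p, , drop = FALSE]
    len <- polyline_length(xy)
    if (isTRUE(ch$closed))
      len <- len + sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
    len
  }, numeric(1)))
}

#' Structured union-jack rectangle mesh
#'
#' Deterministic, mirror-symmetric structured mesh of `[0, L] x [0, H]`
#' (four triangles per grid cell around cell centres) used for verification
#' problems (patch test, manufactured solutions, symmetry checks). Boundary
#' labels: `"left"`, `"right"`, `"bottom"`, `"top"`.
#'
#' @param L,H rectangle dimensions.
#' @param nx,ny number of cells per side.
#' @return a `trimesh`.
#' @export
build_rectangle_structured <- function(L, H, nx, ny) {
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(0, H, length.out = ny + 1L)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i            # grid vertex id
  ctr0 <- (nx + 1L) * (ny + 1L)
  cid <- function(i, j) ctr0 + (j - 1L) * nx + i            # cell centre id
  cx <- as.matrix(expand.grid(x = (xs[-1] + xs[-(nx + 1L)]) / 2,
                              y = (ys[-1] + ys[-(ny + 1L)]) / 2))
  v <- rbind(g, cx)
  ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
  sw <- nid(ii, jj); se <- nid(ii + 1L, jj)
  ne <- nid(ii + 1L, jj + 1L); nw <- nid(ii, jj + 1L)
  cc <- cid(ii, jj)
  tr <- rbind(cbind(sw, se, cc), cbind(se, ne, cc),
              cbind(ne, nw, cc), cbind(nw, sw, cc))
  bot <- nid(seq_len(nx + 1L), 1L)
  rgt <- nid(nx + 1L, seq_len(ny + 1L))
  top <- nid(rev(seq_len(nx + 1L)), ny + 1L)
  lft <- nid(1L, rev(seq_len(ny + 1L)))
  loop <- c(bot, rgt[-1L], top[-1L], lft[-1L])
  loop <- loop[-length(loop)]
  lab <- c(rep("bottom", nx), rep("right", ny), rep("top", nx), rep("left", ny))
  boundary <- data.frame(v1 = loop, v2 = c(loop[-1L], loop[1L]), label = lab,
                         loop = 1L)
  chains <- list(
    bottom = list(parts = list(bot), closed = FALSE, loop = 1L, kind = "boundary"),
    right  = list(parts = list(rgt), closed = FALSE, loop = 1L, kind = "boundary"),
    top    = list(parts = list(top), closed = FALSE, loop = 1L, kind = "boundary"),
    left   = list(parts = list(lft), closed = FALSE, loop = 1L, kind = "boundary"))
  trimesh(v, tr, boundary, chains, loops = list(loop),
          h = max(L / nx, H / ny))
}
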