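# Low-level planar geometry helpers shared by the meshing and curvature code.
# All coordinates are dimensionless model units; polygons are plain k x 2
# matrices without a repeated closing vertex.

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy k x 2 matrix of vertices, not closed.
#' @return Signed area (model length squared).
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#'
#' @param xy k x 2 matrix of vertices, not closed.
#' @return Total edge length.
#' @export
polygon_perimeter <- function(xy) {
  d <- xy[c(seq_len(nrow(xy))[-1], 1), , drop = FALSE] - xy
  sum(sqrt(rowSums(d^2)))
}

# Length of an open polyline.
polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}

# z-component of the cross product of 2D vectors (vectorised).
cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

# Minimum distance from each point to a set of segments.
# pts: n x 2, seg_a/seg_b: m x 2 segment endpoints. Returns length-n vector.
# Chunked so the n x m temporaries stay modest.
point_segment_dist <- function(pts, seg_a, seg_b) {
  n <- nrow(pts)
  if (n == 0L) return(numeric(0))
  m <- nrow(seg_a)
  out <- rep(Inf, n)
  ex <- seg_b[, 1] - seg_a[, 1]
  ey <- seg_b[, 2] - seg_a[, 2]
  el2 <- pmax(ex^2 + ey^2, .Machine$double.eps)
  chunk <- max(1L, floor(2e6 / m))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    px <- pts[lo:hi, 1]; py <- pts[lo:hi, 2]
    dx <- outer(px, seg_a[, 1], "-")
    dy <- outer(py, seg_a[, 2], "-")
    tt <- sweep(sweep(dx, 2, ex, "*") + sweep(dy, 2, ey, "*"), 2, el2, "/")
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    qx <- dx - sweep(tt, 2, ex, "*")
    qy <- dy - sweep(tt, 2, ey, "*")
    out[lo:hi] <- sqrt(apply(qx^2 + qy^2, 1, min))
  }
  out
}

# Do segments (a1,a2) and (b1,b2) properly intersect (shared endpoints do
# not count)? Vectorised over the first family against one segment at a time
# is avoided: full pairwise test used by the self-intersection check.
segments_intersect_pairs <- function(p, q) {
  # p, q: m x 4 matrices (x1,y1,x2,y2) of equal row count; returns logical m.
  d1 <- cross2(q[, 3] - q[, 1], q[, 4] - q[, 2], p[, 1] - q[, 1], p[, 2] - q[, 2])
  d2 <- cross2(q[, 3] - q[, 1], q[, 4] - q[, 2], p[, 3] - q[, 1], p[, 4] - q[, 2])
  d3 <- cross2(p[, 3] - p[, 1], p[, 4] - p[, 2], q[, 1] - p[, 1], q[, 2] - p[, 2])
  d4 <- cross2(p[, 3] - p[, 1], p[, 4] - p[, 2], q[, 3] - p[, 1], q[, 4] - p[, 2])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# First properly-intersecting pair of boundary segments, or NULL.
# segs: m x 4 matrix (x1, y1, x2, y2).
find_self_intersection <- function(segs) {
  m <- nrow(segs)
  if (m < 4) return(NULL)
  idx <- utils::combn(m, 2)
  i <- idx[1, ]; j <- idx[2, ]
  hit <- segments_intersect_pairs(segs[i, , drop = FALSE], segs[j, , drop = FALSE])
  if (!any(hit)) return(NULL)
  k <- which(hit)[1]
  c(i[k], j[k])
}

# Points strictly inside a polygon-with-holes domain.
# outer: k x 2 CCW; holes: list of k x 2 (any orientation).
points_in_domain <- function(pts, outer, holes = list()) {
  if (nrow(pts) == 0L) return(logical(0))
  inside <- mgcv::in.out(rbind(as.matrix(outer), outer[1, , drop = FALSE]),
                         as.matrix(pts))
  for (h in holes) {
    inh <- mgcv::in.out(rbind(as.matrix(h), h[1, , drop = FALSE]),
                        as.matrix(pts))
    inside <- inside & !inh
  }
  inside
}

# Subdivide each edge of a polyline/polygon into pieces no longer than h.
# xy: k x 2; labels: length k (closed) or k-1 (open) edge labels.
# Returns list(xy, labels) with labels per refined edge.
subdivide_path <- function(xy, labels, h, closed = TRUE) {
  k <- nrow(xy)
  nseg <- if (closed) k else k - 1L
  stopifnot(length(labels) == nseg)
  px <- list(); lab <- character(0)
  for (i in seq_len(nseg)) {
    a <- xy[i, ]
    b <- xy[if (i == k) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nn <- max(1L, ceiling(len / h - 1e-9))
    tt <- seq(0, 1, length.out = nn + 1L)[-(nn + 1L)]
    px[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    lab <- c(lab, rep(labels[i], nn))
  }
  pts <- do.call(rbind, px)
  if (!closed) pts <- rbind(pts, xy[k, , drop = FALSE])
  list(xy = pts, labels = lab)
}

# Sample a circular arc from angle th0 to th1 (going th0 -> th1 as given)
# with chord length about h; returns the arc without its final point when
# drop_last, so arcs can be concatenated into a path.
arc_points <- function(center, r, th0, th1, h, drop_last = TRUE) {
  n <- max(2L, ceiling(abs(th1 - th0) * r / h))
  th <- seq(th0, th1, length.out = n + 1L)
  if (drop_last) th <- th[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
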