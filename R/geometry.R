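#' Annular wound domain
#'
#' Disc with a central circular hole, the reference configuration for the
#' purse-string wound-closure problem. Boundary labels: `"hole"` (inner
#' loop) and `"outer"`.
#'
#' @param outer_radius,hole_radius radii, `0 < hole_radius < outer_radius`.
#' @param target_edge_length mesh resolution `h`; must resolve the hole
#'   (`h < hole_radius`) and the annular gap.
#' @return a `trimesh`.
#' @export
build_annulus <- function(outer_radius, hole_radius, target_edge_length) {
  h <- target_edge_length
  if (!(hole_radius > 0 && hole_radius < outer_radius))
    stop("build_annulus: need 0 < hole_radius < outer_radius")
  if (h >= hole_radius)
    stop("build_annulus: target_edge_length must be smaller than hole_radius")
  if (outer_radius - hole_radius < 2 * h)
    stop("build_annulus: annulus too thin to mesh at this edge length")
  circ <- function(r) {
    n <- max(16L, ceiling(2 * pi * r / h))
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(r * cos(th), r * sin(th))
  }
  out_xy <- circ(outer_radius)
  hole_xy <- circ(hole_radius)
  mesh_domain(
    loops = list(list(xy = out_xy, labels = rep("outer", nrow(out_xy))),
                 list(xy = hole_xy, labels = rep("hole", nrow(hole_xy)))),
    h = h, subdivide = FALSE)
}

#' Body-rectangle domain with crenel placodes
#'
#' Lateral projection of the post-neurulation embryonic body: a rectangle
#' `[0, L] x [0, H]` with the mouth at `x = 0`, the neck at `x = L`, the
#' dorsal side at `y = H` and the ventral side at `y = 0`. Placodes are
#' hairpin-shaped tissue domains hanging from the dorsal line into the
#' body (the crenels inherited from the radial cleavage lines). Each
#' contributes an interior chain `"ear_crenel"` (the hairpin contour:
#' left wall, bottom, right wall), an interior chain `"ear_base"` (the
#' dorso-ventral line segment under the notch, i.e. the hairpin bottom,
#' where the contraction acts), and a distinct material tag so the
#' placode tissue can be softened. A placode with `f = 0` is excluded
#' from the mesh entirely: the hairpin becomes an open notch cut into the
#' dorsal boundary (`"ear_crenel"` walls and `"ear_base"` bottom are then
#' boundary labels).
#'
#' @param length,height rectangle dimensions `L`, `H`.
#' @param placodes list of notch specs `list(position, width, depth,
#'   shape = c("crenel", "trapeze"), f = 1)`; `position` is the notch
#'   centre along the dorsal line, `depth` how far it descends into the
#'   body, `f` the softness factor stored with the mesh (`0.01` models
#'   "very soft", `0` absent tissue).
#' @param corner_smoothing_radius radius of the circular arcs replacing
#'   the two sharp head (left) corners; 0 keeps them sharp.
#' @param target_edge_length mesh resolution.
#' @return a `trimesh`; placode `i > 1` uses suffixed labels
#'   (`"ear_crenel2"`, ...).
#' @export
build_body <- function(length, height, placodes = list(),
                       corner_smoothing_radius = 0, target_edge_length = 0.05) {
  L <- length; H <- height; h <- target_edge_length
  r <- corner_smoothing_radius
  stopifnot(L > 0, H > 0, h > 0, r >= 0)
  if (r > 0 && (r >= H / 2 || r >= L / 2))
    stop("build_body: smoothing radius too large for the rectangle")
  placodes <- lapply(placodes, normalize_placode, L = L, H = H, r = r)
  check_placode_overlap(placodes)

  suff <- function(i) if (i == 1L) "" else as.character(i)
  pl_ord <- order(-vapply(placodes, `[[`, numeric(1), "position"))
  xy <- NULL; lab <- character(0)
  add <- function(p, l) { xy <<- rbind(xy, p); lab <<- c(lab, rep(l, nrow(p))) }

  # outline, counter-clockwise; ventral from (x_start, 0) to (L, 0)
  add(cbind(if (r > 0) r else 0, 0), "ventral")
  add(cbind(L, 0), "neck")              # neck: (L,0) -> (L,H)
  add(cbind(L, H), "dorsal")            # dorsal right -> left
  for (k in pl_ord) {
    p <- placodes[[k]]
    x0 <- p$position - p$width / 2; x1 <- p$position + p$width / 2
    bw <- if (p$shape == "trapeze") p$width / 2 else p$width
    bx0 <- p$position - bw / 2; bx1 <- p$position + bw / 2
    yb <- H - p$depth
    if (p$f == 0) {
      # open notch cut into the dorsal boundary
      add(cbind(x1, H), paste0("ear_crenel", suff(k)))    # right wall down
      add(cbind(bx1, yb), paste0("ear_base", suff(k)))    # bottom leftward
      add(cbind(bx0, yb), paste0("ear_crenel", suff(k)))  # left wall up
      add(cbind(x0, H), "dorsal")
    } else {
      # conforming outline vertices at the hairpin feet
      add(cbind(x1, H), "dorsal")
      add(cbind(x0, H), "dorsal")
    }
  }
  if (r > 0) {
    # head corner arcs; both arcs belong to the mouth (head) label, so
    # "dorsal" stays the straight top span
    a1 <- arc_points(c(r, H - r), r, pi / 2, pi, h)
    a2 <- arc_points(c(r, r), r, pi, 3 * pi / 2, h)
    add(a1, "mouth")                    # top arc from (r, H) to (0, H - r)
    add(cbind(0, H - r), "mouth")
    add(a2, "mouth")                    # bottom arc down to (r, 0)
  } else {
    add(cbind(0, H), "mouth")           # mouth: (0,H) -> (0,0)
  }
  loops <- list(list(xy = xy, labels = lab))

  chains <- list(); regions <- list(); softness <- c(`1` = 1)
  for (k in seq_along(placodes)) {
    p <- placodes[[k]]
    if (p$f == 0) next
    x0 <- p$position - p$width / 2; x1 <- p$position + p$width / 2
    bw <- if (p$shape == "trapeze") p$width / 2 else p$width
    bx0 <- p$position - bw / 2; bx1 <- p$position + bw / 2
    yb <- H - p$depth
    chains[[paste0("ear_crenel", suff(k))]] <-
      cbind(c(x0, bx0, bx1, x1), c(H, yb, yb, H))
    chains[[paste0("ear_base", suff(k))]] <- cbind(c(bx0, bx1), c(yb, yb))
    # region polygon: hairpin contour auto-closed along the dorsal chord
    regions[[length(regions) + 1L]] <-
      list(tag = k + 1L, chain_labels = paste0("ear_crenel", suff(k)))
    softness[as.character(k + 1L)] <- p$f
  }
  msh <- mesh_domain(loops, h, interior_chains = chains, regions = regions)
  attr(msh, "softness") <- softness
  msh
}

normalize_placode <- function(p, L, H, r) {
  stopifnot(is.list(p), !is.null(p$position), !is.null(p$width),
            !is.null(p$depth))
  p$shape <- match.arg(if (is.null(p$shape)) "crenel" else p$shape,
                       c("crenel", "trapeze"))
  if (is.null(p$f)) p$f <- 1
  stopifnot(p$width > 0, p$depth > 0, p$depth < H, p$f >= 0, p$f <= 1)
  x0 <- p$position - p$width / 2; x1 <- p$position + p$width / 2
  if (x0 <= r || x1 >= L)
    stop("build_body: placode lies outside the rectangle footprint")
  p
}

check_placode_overlap <- function(placodes) {
  if (length(placodes) < 2L) return(invisible(TRUE))
  iv <- t(vapply(placodes, function(p)
    c(p$position - p$width / 2, p$position + p$width / 2), numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("build_body: overlapping placodes")
  invisible(TRUE)
}

#' Discrete curvature, normal and tangent along a boundary chain
#'
#' Signed curvature at each vertex of the selected chain from the
#' circumscribed circle through three consecutive vertices, signed by the
#' cross product of the adjacent edge vectors. Each closed loop is treated
#' in its own counter-clockwise orientation, so a convex loop (circle) has
#' `kappa = 1/R > 0` everywhere and the normal points away from the
#' enclosed region. Open boundary chains borrow their stencil neighbours
#' from the owning loop; truly open (interior) chains fall back to a
#' one-sided stencil at their endpoints, flagged in the `endpoint` column.
#'
#' @param mesh a `trimesh`.
#' @param label a chain label, or `"all-external"` for the whole external
#'   contour.
#' @return a `curvature_field`: data.frame with columns `vertex`, `x`, `y`,
#'   `s` (arclength), `kappa`, `nx`, `ny`, `tx`, `ty`, `endpoint`.
#' @export
boundary_curvature <- function(mesh, label) {
  if (identical(label, "all-external")) {
    parts <- list(mesh$loops[[1L]])
    closed <- TRUE; loop <- 1L
  } else {
    ch <- mesh_chain(mesh, label)
    parts <- ch$parts
    closed <- isTRUE(ch$closed)
    loop <- ch$loop
  }
  out <- lapply(seq_along(parts), function(ip) {
    cf <- curvature_part(mesh, parts[[ip]], closed, loop, label)
    cf$part <- ip
    cf
  })
  cf <- do.call(rbind, out)
  structure(cf, label = label, closed = closed,
            class = c("curvature_field", "data.frame"))
}

# Curvature data for one ordered vertex path.
curvature_part <- function(mesh, idx, closed, loop, label) {
  ghost <- NULL
  if (!closed && !is.na(loop)) {
    cyc <- mesh$loops[[loop]]
    k <- length(cyc)
    i1 <- match(idx[1L], cyc); i2 <- match(idx[length(idx)], cyc)
    ghost <- c(cyc[((i1 - 2L) %% k) + 1L], cyc[(i2 %% k) + 1L])
  }
  if (length(idx) < 3L)
    stop("boundary_curvature: chain '", label, "' has fewer than 3 vertices")
  P <- mesh$vertices[idx, , drop = FALSE]
  n <- nrow(P)
  if (closed) {
    Pm <- P[c(n, 1:(n - 1L)), , drop = FALSE]
    Pp <- P[c(2:n, 1L), , drop = FALSE]
    endpoint <- rep(FALSE, n)
  } else if (!is.null(ghost)) {
    Pm <- rbind(mesh$vertices[ghost[1L], ], P[1:(n - 1L), , drop = FALSE])
    Pp <- rbind(P[2:n, , drop = FALSE], mesh$vertices[ghost[2L], ])
    endpoint <- rep(FALSE, n)
  } else {
    # one-sided stencils at open-chain endpoints
    Pm <- rbind(P[1L, , drop = FALSE], P[1:(n - 1L), , drop = FALSE])
    Pp <- rbind(P[2:n, , drop = FALSE], P[n, , drop = FALSE])
    endpoint <- c(TRUE, rep(FALSE, n - 2L), TRUE)
  }
  e1 <- P - Pm; e2 <- Pp - P
  tv <- Pp - Pm
  tl <- sqrt(rowSums(tv^2))
  tx <- tv[, 1] / tl; ty <- tv[, 2] / tl
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  l3 <- sqrt(rowSums((Pp - Pm)^2))
  kappa <- 2 * cross2(e1[, 1], e1[, 2], e2[, 1], e2[, 2]) /
    pmax(l1 * l2 * l3, .Machine$double.xmin)
  if (!closed && is.null(ghost) && n >= 3L) {
    kappa[1L] <- 2 * cross2(P[2, 1] - P[1, 1], P[2, 2] - P[1, 2],
                            P[3, 1] - P[2, 1], P[3, 2] - P[2, 2]) /
      max(dist3(P[1, ], P[2, ], P[3, ]), .Machine$double.xmin)
    kappa[n] <- 2 * cross2(P[n - 1, 1] - P[n - 2, 1], P[n - 1, 2] - P[n - 2, 2],
                           P[n, 1] - P[n - 1, 1], P[n, 2] - P[n - 1, 2]) /
      max(dist3(P[n - 2, ], P[n - 1, ], P[n, ]), .Machine$double.xmin)
  }
  s <- c(0, cumsum(sqrt(rowSums((P[-1, , drop = FALSE] -
                                   P[-n, , drop = FALSE])^2))))
  terminal <- if (closed) rep(FALSE, n) else c(TRUE, rep(FALSE, n - 2L), TRUE)
  data.frame(vertex = idx, x = P[, 1], y = P[, 2], s = s,
             kappa = kappa, nx = ty, ny = -tx, tx = tx, ty = ty,
             endpoint = endpoint, terminal = terminal)
}

dist3 <- function(a, b, c) {
  sqrt(sum((b - a)^2)) * sqrt(sum((c - b)^2)) * sqrt(sum((c - a)^2))
}

#' Quality-triggered global remesh
#'
#' If any triangle's radius-ratio quality falls below `min_quality`, the
#' current boundary polygon (and any interior feature chains) is
#' re-triangulated. Boundary and chain vertex positions are preserved
#' exactly; only free interior vertices are regenerated. Region tags are
#' re-assigned by point location inside the (material) region polygons. A
#' self-intersecting boundary halts with the offending segment pair.
#'
#' @param mesh a `trimesh`.
#' @param min_quality quality threshold in (0, 1).
#' @return the input mesh (untouched) or a freshly triangulated one.
#' @export
remesh_if_needed <- function(mesh, min_quality = 0.2) {
  stopifnot(min_quality > 0, min_quality < 1)
  if (min(triangle_quality(mesh)) >= min_quality) return(mesh)
  loops <- lapply(seq_along(mesh$loops), function(i) {
    cyc <- mesh$loops[[i]]
    lab <- directed_edge_labels(mesh, cyc)
    list(xy = mesh$vertices[cyc, , drop = FALSE], labels = lab)
  })
  # holes may have shrunk below positive-orientation tolerance checks; all
  # loops were built CCW and advect continuously, orientation persists
  chains <- list()
  for (nm in names(mesh$chains)) {
    ch <- mesh$chains[[nm]]
    if (identical(ch$kind, "interior"))
      chains[[nm]] <- mesh$vertices[ch$parts[[1L]], , drop = FALSE]
  }
  out <- mesh_domain(loops, mesh$h, interior_chains = chains,
                     regions = mesh$regions, subdivide = FALSE,
                     smooth_passes = 2L)
  attr(out, "softness") <- attr(mesh, "softness")
  out
}

#' Outline polygon of a placode (ear territory)
#'
#' The closed polygon bounding a placode domain in the current
#' configuration: the hairpin contour (plus its bottom) closed by the
#' chord between its two dorsal endpoints. Works for both interior
#' placodes (`f > 0`) and open notches (`f = 0`).
#'
#' @param mesh a `trimesh` built by [build_body()].
#' @param index placode number (1 = unsuffixed labels).
#' @return k x 2 polygon matrix (not closed).
#' @export
placode_outline <- function(mesh, index = 1L) {
  suff <- if (index == 1L) "" else as.character(index)
  lbc <- paste0("ear_crenel", suff)
  lbb <- paste0("ear_base", suff)
  ch <- mesh_chain(mesh, lbc)
  if (identical(ch$kind, "interior"))
    return(mesh$vertices[ch$parts[[1L]], , drop = FALSE])
  # open notch: contiguous run of crenel/base labels along the outer loop
  cyc <- mesh$loops[[1L]]
  lab <- directed_edge_labels(mesh, cyc)
  lr <- label_runs(cyc, ifelse(lab %in% c(lbc, lbb), "sel", "other"), "sel")
  if (length(lr$parts) != 1L)
    stop("placode_outline: notch contour is not contiguous")
  mesh$vertices[lr$parts[[1L]], , drop = FALSE]
}

# Labels of directed loop edges (v_i -> v_{i+1}) from the boundary table.
directed_edge_labels <- function(mesh, cyc) {
  key <- paste(mesh$boundary$v1, mesh$boundary$v2)
  want <- paste(cyc, c(cyc[-1L], cyc[1L]))
  lab <- mesh$boundary$label[match(want, key)]
  if (anyNA(lab)) stop("remesh: loop edge without a boundary label")
  lab
}
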