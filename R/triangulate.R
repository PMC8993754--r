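# Constrained-polygon meshing on top of an unconstrained Delaunay kernel
# (interp::tri.mesh). Boundary loops and interior feature chains are sampled
# at the target edge length; interior seed points come from a deterministic
# hexagonal lattice kept a guard band (0.7 h) away from every constrained
# segment, so each constrained segment has an empty diametral circle and is
# therefore guaranteed to appear as a Delaunay edge (Gabriel condition).
# Triangles are then culled by centroid location and every constrained edge
# is verified; a missing edge triggers flip-based recovery and, failing
# that, seed thinning and a fallback kernel.

DEDUP_DIGITS <- 9L

coord_key <- function(xy) paste(round(xy[, 1], DEDUP_DIGITS),
                                round(xy[, 2], DEDUP_DIGITS))

# Mesh a polygon-with-holes domain.
#
# loops: list of list(xy = k x 2 (positive/CCW enclosed area), labels =
#   character k, one per edge i -> i+1); loops[[1]] is the external contour,
#   the rest are holes.
# interior_chains: named list of k x 2 polylines meshed conformingly inside
#   the domain (e.g. the D-V base segment under a placode).
# regions: list of list(tag, chain_labels) closed chain sequences defining
#   material regions; triangles default to tag 1.
# subdivide: refine input edges to length <= h (FALSE when remeshing, where
#   input vertices are material points that must be preserved exactly).
mesh_domain <- function(loops, h, interior_chains = list(),
                        regions = list(), subdivide = TRUE,
                        smooth_passes = 2L) {
  stopifnot(h > 0)
  for (i in seq_along(loops)) {
    if (polygon_area(loops[[i]]$xy) <= 0)
      stop("mesh_domain: loop ", i, " must have positive (CCW) enclosed area")
  }
  # -- sample constrained paths ------------------------------------------
  sub_loops <- lapply(loops, function(lp) {
    if (subdivide) subdivide_path(lp$xy, lp$labels, h, closed = TRUE)
    else list(xy = lp$xy, labels = lp$labels)
  })
  sub_chains <- lapply(interior_chains, function(xy) {
    if (subdivide)
      subdivide_path(xy, rep("c", nrow(xy) - 1L), h, closed = FALSE)$xy
    else xy
  })
  outer_xy <- sub_loops[[1]]$xy
  hole_xy <- lapply(sub_loops[-1], `[[`, "xy")

  con_pts <- rbind(do.call(rbind, lapply(sub_loops, `[[`, "xy")),
                   if (length(sub_chains)) do.call(rbind, sub_chains))
  key <- coord_key(con_pts)
  uid <- match(key, unique(key))
  pts <- con_pts[!duplicated(key), , drop = FALSE]

  # per-loop vertex index paths (into pts)
  off <- 0L
  loop_paths <- vector("list", length(sub_loops))
  loop_elabs <- vector("list", length(sub_loops))
  for (i in seq_along(sub_loops)) {
    k <- nrow(sub_loops[[i]]$xy)
    loop_paths[[i]] <- uid[off + seq_len(k)]
    loop_elabs[[i]] <- sub_loops[[i]]$labels
    off <- off + k
  }
  chain_paths <- list()
  for (nm in names(sub_chains)) {
    k <- nrow(sub_chains[[nm]])
    chain_paths[[nm]] <- uid[off + seq_len(k)]
    off <- off + k
  }

  # constrained segments (index pairs into pts)
  seg <- NULL
  for (i in seq_along(loop_paths)) {
    p <- loop_paths[[i]]
    seg <- rbind(seg, cbind(p, c(p[-1L], p[1L])))
  }
  for (p in chain_paths) seg <- rbind(seg, cbind(p[-length(p)], p[-1L]))

  self_intersection_guard(pts, seg)

  # -- interior seeds (deterministic hex lattice) ------------------------
  bb <- apply(outer_xy, 2, range)
  dy <- h * sqrt(3) / 2
  cx <- mean(bb[, 1]); cy <- mean(bb[, 2])
  ny <- ceiling((bb[2, 2] - bb[1, 2]) / (2 * dy)) + 1L
  nx <- ceiling((bb[2, 1] - bb[1, 1]) / (2 * h)) + 1L
  rows <- cy + dy * seq(-ny, ny)
  seeds <- do.call(rbind, lapply(seq_along(rows), function(j) {
    xoff <- if (j %% 2L == 0L) h / 2 else 0
    cbind(cx + xoff + h * seq(-nx, nx), rows[j])
  }))
  keep <- points_in_domain(seeds, outer_xy, hole_xy)
  seeds <- seeds[keep, , drop = FALSE]
  if (nrow(seeds) > 0L) {
    d <- point_segment_dist(seeds, pts[seg[, 1], , drop = FALSE],
                            pts[seg[, 2], , drop = FALSE])
    seeds <- seeds[d >= 0.7 * h, , drop = FALSE]
  }

  # -- Delaunay + constrained-edge recovery + cull -----------------------
  for (attempt in 1:4) {
    allp <- rbind(pts, seeds)
    tri <- delaunay_triangles(allp, kernel = if (attempt >= 3L) "deldir"
                              else "interp")
    tri <- tryCatch(recover_edges(allp, tri, seg), error = function(e) tri)
    cent <- (allp[tri[, 1], , drop = FALSE] + allp[tri[, 2], , drop = FALSE] +
               allp[tri[, 3], , drop = FALSE]) / 3
    tri <- tri[points_in_domain(cent, outer_xy, hole_xy), , drop = FALSE]
    tri <- tryCatch(fix_degenerate_triangles(allp, tri),
                    error = function(e) tri)
    # every loop segment must have exactly one kept triangle, every
    # interior-chain segment exactly two
    ek <- c(paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2])),
            paste(pmin(tri[, 2], tri[, 3]), pmax(tri[, 2], tri[, 3])),
            paste(pmin(tri[, 1], tri[, 3]), pmax(tri[, 1], tri[, 3])))
    nloop <- sum(lengths(loop_paths))
    want <- paste(pmin(seg[, 1], seg[, 2]), pmax(seg[, 1], seg[, 2]))
    cnt <- as.integer(table(ek)[want])
    cnt[is.na(cnt)] <- 0L
    need <- rep(c(1L, 2L), c(nloop, nrow(seg) - nloop))
    missing <- which(cnt != need)
    if (length(missing) == 0L) break
    if (attempt == 4L)
      stop("mesh_domain: could not recover ", length(missing),
           " constrained edge(s)")
    # drop interior seeds crowding the missing segments and retry
    bad_a <- pts[seg[missing, 1], , drop = FALSE]
    bad_b <- pts[seg[missing, 2], , drop = FALSE]
    if (nrow(seeds) > 0L) {
      d <- point_segment_dist(seeds, bad_a, bad_b)
      seeds <- seeds[d >= 1.2 * h, , drop = FALSE]
    }
  }

  # -- smoothing of free interior vertices -------------------------------
  ncon <- nrow(pts)
  if (smooth_passes > 0L && nrow(seeds) > 0L) {
    allp <- laplacian_smooth(allp, tri, fixed = seq_len(ncon),
                             passes = smooth_passes)
  }

  # -- assemble the trimesh ----------------------------------------------
  areas <- cross2(allp[tri[, 2], 1] - allp[tri[, 1], 1],
                  allp[tri[, 2], 2] - allp[tri[, 1], 2],
                  allp[tri[, 3], 1] - allp[tri[, 1], 1],
                  allp[tri[, 3], 2] - allp[tri[, 1], 2]) / 2
  flip <- areas < 0
  if (any(flip)) tri[flip, ] <- tri[flip, c(1, 3, 2)]

  boundary <- NULL
  chains <- list()
  for (i in seq_along(loop_paths)) {
    p <- loop_paths[[i]]
    lab <- loop_elabs[[i]]
    boundary <- rbind(boundary,
                      data.frame(v1 = p, v2 = c(p[-1L], p[1L]), label = lab,
                                 loop = i))
    for (ul in unique(lab)) {
      lr <- label_runs(p, lab, ul)
      chains[[ul]] <- list(parts = lr$parts, closed = lr$closed,
                           loop = i, kind = "boundary")
    }
  }
  for (nm in names(chain_paths)) {
    chains[[nm]] <- list(parts = list(chain_paths[[nm]]), closed = FALSE,
                         loop = NA_integer_, kind = "interior")
  }

  msh <- trimesh(allp, tri, boundary, chains,
                 loops = loop_paths, h = h, validate = FALSE)
  msh$tags <- classify_regions(msh, regions)
  msh$regions <- regions
  validate_trimesh(msh)
  msh
}

# Force every constrained segment into the triangulation by local edge
# flips. The guard band makes constrained segments Delaunay edges in exact
# arithmetic, but the kernel jitters near-cocircular inputs (sampled
# circles, deformed boundaries), which can leave a constrained segment
# crossed by one or a few triangulation edges; flipping those recovers it.
recover_edges <- function(pts, tri, seg, max_flips = 500L) {
  want1 <- pmin(seg[, 1], seg[, 2]); want2 <- pmax(seg[, 1], seg[, 2])
  for (flip_count in seq_len(max_flips)) {
    ek <- c(paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2])),
            paste(pmin(tri[, 2], tri[, 3]), pmax(tri[, 2], tri[, 3])),
            paste(pmin(tri[, 1], tri[, 3]), pmax(tri[, 1], tri[, 3])))
    missing <- which(!(paste(want1, want2) %in% ek))
    if (length(missing) == 0L) return(tri)
    pq <- seg[missing[1L], ]
    P <- pts[pq[1L], ]; Q <- pts[pq[2L], ]
    # triangulation edges properly crossing segment P-Q
    ea <- c(tri[, 1], tri[, 2], tri[, 1])
    eb <- c(tri[, 2], tri[, 3], tri[, 3])
    cand <- which(ea != pq[1L] & ea != pq[2L] & eb != pq[1L] & eb != pq[2L])
    A <- pts[ea[cand], , drop = FALSE]; B <- pts[eb[cand], , drop = FALSE]
    hit <- segments_intersect_pairs(
      cbind(A, B), matrix(c(P, Q), nrow = length(cand), ncol = 4,
                          byrow = TRUE))
    cross_e <- unique(cbind(pmin(ea[cand[hit]], eb[cand[hit]]),
                            pmax(ea[cand[hit]], eb[cand[hit]])))
    if (nrow(cross_e) == 0L)
      stop("recover_edges: constrained segment blocked but not crossed")
    flipped <- FALSE
    for (ce in seq_len(nrow(cross_e))) {
      a <- cross_e[ce, 1L]; b <- cross_e[ce, 2L]
      rows <- which(rowSums(tri == a | tri == b) == 2L)
      if (length(rows) != 2L) next
      opp <- vapply(rows, function(r) setdiff(tri[r, ], c(a, b)), integer(1))
      # flip a-b -> opp[1]-opp[2]; valid only if the quad is strictly convex
      if (!segments_intersect_pairs(
        matrix(c(pts[opp[1L], ], pts[opp[2L], ]), 1, 4),
        matrix(c(pts[a, ], pts[b, ]), 1, 4))) next
      tri[rows[1L], ] <- c(a, opp[1L], opp[2L])
      tri[rows[2L], ] <- c(b, opp[1L], opp[2L])
      flipped <- TRUE
      break
    }
    if (!flipped)
      stop("recover_edges: no flippable edge for a constrained segment")
  }
  stop("recover_edges: flip budget exhausted")
}

# Repair zero-area slivers formed by (nearly) collinear boundary points
# (an artifact of the kernel jitter along straight boundary runs): flip
# the sliver's long chord edge with its neighbouring triangle, splitting
# the neighbour at the sliver's middle vertex.
fix_degenerate_triangles <- function(pts, tri, rel_tol = 1e-12) {
  scale2 <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))^2
  tol <- rel_tol * scale2
  for (pass in 1:1000) {
    ar <- cross2(pts[tri[, 2], 1] - pts[tri[, 1], 1],
                 pts[tri[, 2], 2] - pts[tri[, 1], 2],
                 pts[tri[, 3], 1] - pts[tri[, 1], 1],
                 pts[tri[, 3], 2] - pts[tri[, 1], 2]) / 2
    bad <- which(abs(ar) <= tol)
    if (length(bad) == 0L) return(tri)
    # prefer a sliver that can be dropped safely (no neighbour across its
    # chord) or flipped against a sound neighbour; stacked collinear
    # slivers resolve once their outermost member is handled
    acted <- FALSE
    fallback <- NULL
    for (t1 in bad) {
      vv <- tri[t1, ]
      el <- c(sum((pts[vv[2], ] - pts[vv[3], ])^2),
              sum((pts[vv[1], ] - pts[vv[3], ])^2),
              sum((pts[vv[1], ] - pts[vv[2], ])^2))
      mid <- vv[which.max(el)]            # vertex opposite the chord
      ac <- setdiff(vv, mid)
      rows <- which(rowSums(tri == ac[1] | tri == ac[2]) == 2L)
      nb <- setdiff(rows, t1)
      if (length(nb) == 0L) {             # hull-fill sliver: drop
        tri <- tri[-t1, , drop = FALSE]
        acted <- TRUE
        break
      }
      if (abs(ar[nb[1L]]) > tol) {        # sound neighbour: flip the chord
        d <- setdiff(tri[nb[1L], ], ac)
        tri[t1, ] <- c(ac[1], mid, d)
        tri[nb[1L], ] <- c(ac[2], mid, d)
        acted <- TRUE
        break
      }
      if (is.null(fallback)) fallback <- t1
    }
    if (!acted) {
      if (is.null(fallback))
        stop("fix_degenerate_triangles: unresolvable sliver cluster")
      tri <- tri[-fallback, , drop = FALSE]
    }
  }
  stop("fix_degenerate_triangles: did not converge")
}

# Maximal runs of a label along a loop (edge i is p[i] -> p[i+1], cyclic).
# A label covering the whole loop yields one closed part; otherwise each
# run becomes an open vertex path including both run endpoints.
label_runs <- function(p, lab, ul) {
  k <- length(p)
  sel <- lab == ul
  if (all(sel)) return(list(parts = list(p), closed = TRUE))
  starts <- which(sel & !c(sel[k], sel[-k]))
  parts <- lapply(starts, function(st) {
    len <- 1L
    while (sel[((st + len - 1L) %% k) + 1L]) len <- len + 1L
    idx <- ((st - 1L + 0:len) %% k) + 1L
    p[idx]
  })
  list(parts = parts, closed = FALSE)
}

# Delaunay of a point set; returns m x 3 indices into the input order.
# The s-hull kernel mishandles exactly co-circular configurations (our
# sampled circles): its internal jitter-and-retry can return a
# triangulation that does not even cover the convex hull. A deterministic
# sub-guard-band jitter (golden-angle pattern, ~1e-9 of the domain size)
# is applied to the coordinates handed to the kernel only; the caller
# keeps the exact coordinates, and flip-based edge recovery repairs any
# residual near-degenerate choices. The RNG state is pinned and restored
# so meshing stays a pure function of its input.
delaunay_triangles <- function(pts, kernel = c("interp", "deldir")) {
  kernel <- match.arg(kernel)
  keep <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(keep)) assign(".Random.seed", keep, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(20101L)
  n <- nrow(pts)
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-12)
  ang <- (seq_len(n) * 2.399963229728653) %% (2 * pi)   # golden angle
  eps <- 1e-7 * scale
  px <- pts[, 1] + eps * cos(ang)
  py <- pts[, 2] + eps * sin(ang)
  if (kernel == "deldir") {
    tl <- deldir::triang.list(deldir::deldir(px, py, suppressMsge = TRUE))
    return(t(vapply(tl, function(t3) as.integer(t3$ptNum), integer(3))))
  }
  tm <- suppressWarnings(interp::tri.mesh(px, py, duplicate = "error"))
  tr <- interp::triangles(tm)
  cbind(tr[, "node1"], tr[, "node2"], tr[, "node3"])
}

# A few passes of Laplacian smoothing on free vertices, reverted per pass if
# any triangle would invert.
laplacian_smooth <- function(v, tri, fixed, passes = 2L) {
  n <- nrow(v)
  free <- setdiff(seq_len(n), fixed)
  if (length(free) == 0L) return(v)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  for (p in seq_len(passes)) {
    sx <- rowsum(v[e[, 2], 1], e[, 1], reorder = TRUE)
    sy <- rowsum(v[e[, 2], 2], e[, 1], reorder = TRUE)
    cnt <- rowsum(rep(1, nrow(e)), e[, 1], reorder = TRUE)
    ids <- as.integer(rownames(sx))
    newv <- v
    pos <- match(free, ids)
    ok <- !is.na(pos)
    newv[free[ok], 1] <- sx[pos[ok]] / cnt[pos[ok]]
    newv[free[ok], 2] <- sy[pos[ok]] / cnt[pos[ok]]
    a <- cross2(newv[tri[, 2], 1] - newv[tri[, 1], 1],
                newv[tri[, 2], 2] - newv[tri[, 1], 2],
                newv[tri[, 3], 1] - newv[tri[, 1], 1],
                newv[tri[, 3], 2] - newv[tri[, 1], 2])
    if (all(abs(a) > 0)) v <- newv else break
  }
  v
}

# Halt with the offending segment pair if the constrained boundary
# self-intersects.
self_intersection_guard <- function(pts, seg) {
  segs <- cbind(pts[seg[, 1], 1], pts[seg[, 1], 2],
                pts[seg[, 2], 1], pts[seg[, 2], 2])
  bad <- find_self_intersection(segs)
  if (!is.null(bad))
    stop(structure(
      class = c("morphosim_halt", "error", "condition"),
      list(message = paste0("boundary self-intersection between segments ",
                            bad[1], " and ", bad[2]),
           call = NULL, segments = bad)))
  invisible(TRUE)
}

# Assign material tags by locating triangle centroids inside region polygons.
classify_regions <- function(msh, regions) {
  tags <- rep(1L, nrow(msh$triangles))
  if (length(regions) == 0L) return(tags)
  v <- msh$vertices; tr <- msh$triangles
  cent <- (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
             v[tr[, 3], , drop = FALSE]) / 3
  for (rg in regions) {
    poly <- region_polygon(msh, rg$chain_labels)
    inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), cent)
    tags[inside] <- as.integer(rg$tag)
  }
  tags
}

# Closed polygon from a sequence of chain labels (deduplicating the shared
# junction vertices).
region_polygon <- function(msh, chain_labels) {
  idx <- integer(0)
  for (lb in chain_labels) {
    ch <- mesh_chain(msh, lb)
    if (length(ch$parts) != 1L)
      stop("region_polygon: chain '", lb, "' must be single-part")
    p <- ch$parts[[1L]]
    if (length(idx) > 0L) {
      if (p[length(p)] == idx[length(idx)]) p <- rev(p)
      if (p[1L] == idx[length(idx)]) p <- p[-1L]
    }
    idx <- c(idx, p)
  }
  if (idx[length(idx)] == idx[1L]) idx <- idx[-length(idx)]
  msh$vertices[idx, , drop = FALSE]
}
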