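# Skeleton-based partition of epithelial regions.
#
# The epithelium is a long curved band; patches for tissue-level analysis
# must follow its growth direction. The band's one-pixel centerline is
# extracted, side branches are removed, the surviving longest axis is cut
# into equal-length segments (target 4096 px at 0.25 um/px), and each
# segment is expanded perpendicular to its chord until it clears the mask,
# giving a quadrilateral patch C'CDD' around axis segment AB.

#' Extract the skeleton of an epithelial region
#'
#' Reduces a binary region mask to its one-pixel-wide centerline by
#' topology-preserving (Zhang-Suen) thinning, and returns it as a pixel
#' graph: nodes are skeleton pixels, edges connect 8-neighbours with
#' Euclidean step weights (1 or sqrt(2)).
#'
#' @param region an `epithelial_region` from [extract_regions()], or a binary
#'   mask matrix.
#' @return object of class `skeleton_graph`: `nodes` (n x 2 matrix of 0-based
#'   x, y in the mask frame), `edges` (m x 2 node indices), `weights`,
#'   `mask` (skeleton raster), `offset` (frame origin, from the region).
#' @export
extract_skeleton <- function(region) {
  offset <- c(x = 0, y = 0)
  if (inherits(region, "epithelial_region")) {
    m <- region$mask_crop
    offset <- region$offset
  } else {
    m <- as_binary_mask(region)
  }
  if (sum(m) == 0) sil_data_error("region mask has no foreground pixels")
  if (sum(m) == 1) {
    warning("degenerate region: single-pixel mask yields a single-node skeleton")
    idx <- which(m == 1, arr.ind = TRUE)
    nodes <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
    return(structure(
      list(nodes = nodes, edges = matrix(0L, 0, 2), weights = numeric(0),
           mask = m, offset = offset),
      class = "skeleton_graph"
    ))
  }
  sk <- cpp_thin(m)
  idx <- which(sk == 1L, arr.ind = TRUE)
  nodes <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  id <- matrix(0L, nrow(sk), ncol(sk))
  id[idx] <- seq_len(nrow(idx))
  # enumerate 8-neighbour edges once (4 forward directions); diagonal edges
  # that shortcut an existing orthogonal corner pixel are redundant and are
  # dropped, which keeps tips at degree 1 instead of closing tiny triangles
  at_id <- function(r, c) {
    out <- rep(0L, length(r))
    ok <- r >= 1 & r <= nrow(sk) & c >= 1 & c <= ncol(sk)
    out[ok] <- id[cbind(r[ok], c[ok])]
    out
  }
  eds <- list()
  dirs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))  # (dy, dx)
  for (k in seq_len(nrow(dirs))) {
    dy <- dirs[k, 1]; dx <- dirs[k, 2]
    to <- at_id(idx[, 1] + dy, idx[, 2] + dx)
    sel <- to > 0L
    if (abs(dx) == 1 && abs(dy) == 1) {
      corner <- at_id(idx[, 1] + dy, idx[, 2]) > 0L | at_id(idx[, 1], idx[, 2] + dx) > 0L
      sel <- sel & !corner
    }
    if (any(sel))
      eds[[length(eds) + 1]] <- cbind(
        from = id[idx[sel, , drop = FALSE]],
        to = to[sel],
        w = sqrt(dx^2 + dy^2)
      )
  }
  eds <- if (length(eds)) do.call(rbind, eds) else matrix(0, 0, 3)
  structure(
    list(
      nodes = nodes,
      edges = matrix(as.integer(eds[, 1:2]), ncol = 2),
      weights = eds[, 3],
      mask = sk,
      offset = offset
    ),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d node(s), %d edge(s)\n", nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Prune a skeleton and return its longest axis
#'
#' Iteratively removes side branches whose geodesic length from endpoint to
#' the nearest junction is below `min_branch`, then returns the maximal
#' geodesic (weighted) simple path between skeleton endpoints as an ordered
#' polyline. On tree-shaped skeletons (the usual case for bands) the
#' double-sweep search is exact; cyclic skeletons fall back to the longest
#' shortest-path arc with a warning. The polyline is oriented so its start
#' has the smaller x (ties: smaller y).
#'
#' @param sk a `skeleton_graph`.
#' @param min_branch branches shorter than this many pixels are cut off.
#' @return ordered polyline, n x 2 matrix of 0-based x, y.
#' @export
prune_to_longest_axis <- function(sk, min_branch = 256) {
  n <- nrow(sk$nodes)
  if (n == 0) sil_data_error("empty skeleton")
  if (n == 1) return(sk$nodes)

  adj <- vector("list", n)
  wadj <- vector("list", n)
  for (i in seq_len(nrow(sk$edges))) {
    a <- sk$edges[i, 1]; b <- sk$edges[i, 2]; w <- sk$weights[i]
    adj[[a]] <- c(adj[[a]], b); wadj[[a]] <- c(wadj[[a]], w)
    adj[[b]] <- c(adj[[b]], a); wadj[[b]] <- c(wadj[[b]], w)
  }
  alive <- rep(TRUE, n)
  deg <- lengths(adj)

  repeat {
    removed_any <- FALSE
    endpoints <- which(alive & deg == 1)
    for (e in endpoints) {
      if (!alive[e] || deg[e] != 1) next
      path <- e; len <- 0; prev <- 0L; cur <- e
      repeat {
        nxt <- adj[[cur]][alive[adj[[cur]]] & adj[[cur]] != prev]
        wts <- wadj[[cur]][alive[adj[[cur]]] & adj[[cur]] != prev]
        if (length(nxt) == 0) { cur <- 0L; break }   # other endpoint: main path
        if (deg[cur] >= 3 && cur != e) break          # reached a junction
        len <- len + wts[1]
        prev <- cur; cur <- nxt[1]
        if (deg[cur] >= 3) break
        path <- c(path, cur)
        if (len > min_branch) break
      }
      reached_junction <- cur != 0L && deg[cur] >= 3
      if (reached_junction && len < min_branch) {
        for (p in path) {
          alive[p] <- FALSE
          for (nb in adj[[p]]) deg[nb] <- deg[nb] - 1L
        }
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }

  keep <- which(alive)
  if (length(keep) == 1) return(sk$nodes[keep, , drop = FALSE])
  emask <- alive[sk$edges[, 1]] & alive[sk$edges[, 2]]
  g <- igraph::graph_from_edgelist(sk$edges[emask, , drop = FALSE], directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = sk$weights[emask])
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))

  comp <- igraph::components(g)
  comp$membership[!alive] <- NA
  big <- which.max(tabulate(comp$membership[keep]))
  verts <- keep[comp$membership[keep] == big]

  has_endpoint <- any(igraph::degree(g, v = verts) == 1)
  if (!has_endpoint && length(verts) > 2)
    warning("skeleton has no endpoints (cycle); using the longest shortest-path arc")

  d0 <- igraph::distances(g, v = verts[1], to = verts)
  u <- verts[which.max(d0)]
  d1 <- igraph::distances(g, v = u, to = verts)
  w <- verts[which.max(d1)]
  vp <- igraph::shortest_paths(g, from = u, to = w, output = "vpath")$vpath[[1]]
  poly <- sk$nodes[as.integer(vp), , drop = FALSE]

  a <- poly[1, ]; b <- poly[nrow(poly), ]
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2]))
    poly <- poly[nrow(poly):1, , drop = FALSE]
  poly
}

polyline_arclength <- function(poly) {
  if (nrow(poly) < 2) return(0)
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

# Point at arc length s along the polyline (linear interpolation).
polyline_point_at <- function(poly, cum, s) {
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- max(1, min(i, nrow(poly) - 1))
  seg <- cum[i + 1] - cum[i]
  t <- if (seg > 0) (s - cum[i]) / seg else 0
  poly[i, ] * (1 - t) + poly[i + 1, ] * t
}

#' Divide an axis polyline into equal-length segments
#'
#' The longest axis is divided into `k = ceiling(L / segment_target_length)`
#' segments of equal arc length `L / k`; consecutive segments share
#' endpoints. Equal lengths take precedence over hitting the target exactly,
#' which guarantees full axis coverage with near-target lengths.
#'
#' @param polyline n x 2 matrix of ordered axis points.
#' @param segment_target_length target arc length per segment (default 4096
#'   px, i.e. about 1 mm at 0.25 um/px).
#' @return list of `axis_segment`s: `A`, `B` (endpoints), `polyline`
#'   (resampled points from A to B), `length` (arc length).
#' @export
bisect_axis <- function(polyline, segment_target_length = 4096) {
  L <- polyline_arclength(polyline)
  if (L <= 0) sil_data_error("axis polyline has zero length")
  k <- ceiling(L / segment_target_length)
  d <- diff(polyline)
  cum <- c(0, cumsum(sqrt(rowSums(d^2))))
  lapply(seq_len(k), function(j) {
    s0 <- (j - 1) * L / k; s1 <- j * L / k
    inner <- which(cum > s0 & cum < s1)
    pts <- rbind(
      polyline_point_at(polyline, cum, s0),
      polyline[inner, , drop = FALSE],
      polyline_point_at(polyline, cum, s1)
    )
    structure(
      list(
        A = pts[1, ], B = pts[nrow(pts), ],
        polyline = pts, length = L / k, index = j
      ),
      class = "axis_segment"
    )
  })
}

segment_intersects_mask <- function(p0, p1, offset_vec, mask) {
  n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2))) * 2L)
  t <- seq(0, 1, length.out = n)
  xs <- p0[1] + t * (p1[1] - p0[1]) + offset_vec[1]
  ys <- p0[2] + t * (p1[2] - p0[2]) + offset_vec[2]
  any(sample_nearest(mask, xs, ys, outside = 0L) != 0L)
}

#' Expand an axis segment into a patch quadrilateral
#'
#' Translates the chord AB perpendicular to itself in increments of `step`
#' until the translated segment no longer intersects the SE mask (the "rapid
#' expansion" of the partition), refines the stopping offset by a few
#' bisection halvings, and does the same in the opposite direction. The
#' returned corners are C' and D' on the negative side and C and D on the
#' positive side of the chord, so CD and C'D' are parallel to AB and CC',
#' DD' perpendicular to it.
#'
#' @param segment an `axis_segment`.
#' @param se_mask binary mask in the same coordinate frame as the segment.
#' @param step expansion increment in pixels.
#' @param refine number of bisection halvings applied to the final offset.
#' @return object of class `patch_quad` with `corners` (4 x 2 matrix, rows
#'   `C'`, `C`, `D`, `D'`), `A`, `B`, `source_segment`.
#' @export
expand_to_quad <- function(segment, se_mask, step = 16, refine = 4) {
  A <- segment$A; B <- segment$B
  chord <- B - A
  clen <- sqrt(sum(chord^2))
  if (clen == 0) sil_data_error("axis segment has zero length")
  nvec <- c(-chord[2], chord[1]) / clen  # +90 deg; positive side = +y for x-oriented chords

  cap <- sqrt(nrow(se_mask)^2 + ncol(se_mask)^2) + 2 * step
  expand_one <- function(sgn) {
    t <- step
    while (segment_intersects_mask(A, B, sgn * t * nvec, se_mask)) {
      t <- t + step
      if (t > cap) break
    }
    lo <- t - step; hi <- t
    for (i in seq_len(refine)) {
      mid <- (lo + hi) / 2
      if (segment_intersects_mask(A, B, sgn * mid * nvec, se_mask)) lo <- mid else hi <- mid
    }
    hi
  }
  tp <- expand_one(+1)
  tm <- expand_one(-1)

  corners <- rbind(
    "C'" = A - tm * nvec,
    "C"  = A + tp * nvec,
    "D"  = B + tp * nvec,
    "D'" = B - tm * nvec
  )
  colnames(corners) <- c("x", "y")
  structure(
    list(corners = corners, A = A, B = B, source_segment = segment,
         t_plus = tp, t_minus = tm),
    class = "patch_quad"
  )
}

#' @export
print.patch_quad <- function(x, ...) {
  cat(sprintf(
    "<patch_quad> axis %.1f px, thickness %.1f px\n",
    x$source_segment$length, x$t_plus + x$t_minus
  ))
  invisible(x)
}

#' Rectify a patch quadrilateral
#'
#' Perspective-warps the quadrilateral onto an axis-aligned rectangle: the
#' A-to-B axis direction becomes the output x axis and the C'-to-C
#' perpendicular becomes the output y axis, so the epithelium's growth
#' orientation is preserved in every patch. The slide is sampled bilinearly,
#' masks with nearest-neighbour lookup (out-of-bounds samples are 0).
#'
#' @param quad a `patch_quad`.
#' @param slide a [slide_raster()], or NULL to warp masks only.
#' @param masks named list of integer masks in the slide frame.
#' @param out_size output `c(width, height)` in pixels.
#' @return the quad with `rectified` (RGB array or NULL) and
#'   `rectified_masks` (named list) attached.
#' @export
rectify_patch <- function(quad, slide = NULL, masks = list(), out_size = c(512, 512)) {
  w <- out_size[1]; h <- out_size[2]
  src <- quad$corners[c("C'", "D'", "D", "C"), ]  # TL, TR, BR, BL
  dst <- rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1), c(0, h - 1))
  H <- solve_homography(dst, src)  # maps output pixels to slide coordinates
  g <- expand.grid(y = seq_len(h) - 1, x = seq_len(w) - 1)
  p <- apply_homography(H, g$x, g$y)
  if (!all(is.finite(p$x)) || !all(is.finite(p$y)))
    sil_data_error("degenerate quadrilateral: warp produced non-finite coordinates")

  rectified <- NULL
  if (!is.null(slide)) {
    px <- if (inherits(slide, "slide_raster")) slide$pixels else slide
    rectified <- array(0, c(h, w, 3))
    for (ch in 1:3)
      rectified[, , ch] <- matrix(sample_bilinear(px[, , ch], p$x, p$y), h, w)
  }
  rectified_masks <- lapply(masks, function(m) {
    matrix(as.integer(sample_nearest(m, p$x, p$y, outside = 0L)), h, w)
  })
  quad$rectified <- rectified
  quad$rectified_masks <- rectified_masks
  quad
}

# Extend an axis polyline at both ends along the local end direction until
# it exits the mask: recovers the half-thickness the thinning retracts at
# band tips, so end patches reach the region boundary.
extend_axis_ends <- function(poly, mask, lookback = 8) {
  if (nrow(poly) < 2) return(poly)
  extend_dir <- function(tip, inner) {
    d <- tip - inner
    len <- sqrt(sum(d^2))
    if (len == 0) return(NULL)
    d <- d / len
    k <- 0
    while (k < max(dim(mask)) &&
           sample_nearest(mask, tip[1] + (k + 1) * d[1], tip[2] + (k + 1) * d[2],
                          outside = 0L) != 0L) {
      k <- k + 1
    }
    if (k > 0) tip + k * d else NULL
  }
  n <- nrow(poly)
  i0 <- min(lookback + 1, n)
  head_ext <- extend_dir(poly[1, ], poly[i0, ])
  tail_ext <- extend_dir(poly[n, ], poly[n - i0 + 1, ])
  if (!is.null(head_ext)) poly <- rbind(head_ext, poly)
  if (!is.null(tail_ext)) poly <- rbind(poly, tail_ext)
  poly
}

#' Partition an epithelial region into oriented patches
#'
#' Runs the full skeleton partition on one region: skeletonize, prune to the
#' longest axis, optionally extend the axis ends to the region boundary,
#' divide into equal-length segments, expand each into a quadrilateral, and
#' (when a slide is supplied) rectify image and masks for each patch.
#'
#' @param region an `epithelial_region`.
#' @param slide optional [slide_raster()] (whole-slide frame).
#' @param masks named list of whole-slide masks to carry through the warp.
#' @param segment_target_length target axis length per patch (default 4096).
#' @param min_branch skeleton branches shorter than this are pruned.
#' @param step perpendicular expansion increment.
#' @param out_size rectified patch `c(width, height)`; NULL skips
#'   rectification.
#' @param extend_ends extend the axis to the region boundary before
#'   segmentation (default TRUE).
#' @param fill_holes fill enclosed holes in the region mask before
#'   skeletonization (default TRUE): the epithelium is simply connected, and
#'   pinholes from segmentation noise would otherwise knot the skeleton into
#'   loops.
#' @return list with `patches` (list of `patch_quad`, corners in the
#'   whole-slide frame) and `manifest` (one row per patch: segment index,
#'   arc length, corner coordinates, thickness).
#' @export
partition_region <- function(region, slide = NULL, masks = list(),
                             segment_target_length = 4096, min_branch = 256,
                             step = 16, out_size = c(512, 512),
                             extend_ends = TRUE, fill_holes = TRUE) {
  if (fill_holes) {
    filled <- EBImage::fillHull(region$mask_crop)
    region$mask_crop <- matrix(as.integer(filled), nrow(region$mask_crop))
  }
  sk <- extract_skeleton(region)
  poly <- prune_to_longest_axis(sk, min_branch = min_branch)
  if (nrow(poly) < 2)
    sil_data_error("region skeleton is a single point; cannot partition")
  if (extend_ends) poly <- extend_axis_ends(poly, region$mask_crop)
  segments <- bisect_axis(poly, segment_target_length)
  off <- region$offset

  patches <- lapply(segments, function(seg) {
    quad <- expand_to_quad(seg, region$mask_crop, step = step)
    # shift into the whole-slide frame
    quad$corners <- sweep(quad$corners, 2, off, "+")
    quad$A <- quad$A + off
    quad$B <- quad$B + off
    if (!is.null(out_size) && (!is.null(slide) || length(masks) > 0))
      quad <- rectify_patch(quad, slide = slide, masks = masks, out_size = out_size)
    quad
  })
  manifest <- do.call(rbind, lapply(patches, function(q) {
    data.frame(
      segment = q$source_segment$index,
      arc_length = q$source_segment$length,
      ax = q$A[1], ay = q$A[2], bx = q$B[1], by = q$B[2],
      cpx = q$corners["C'", 1], cpy = q$corners["C'", 2],
      cx = q$corners["C", 1], cy = q$corners["C", 2],
      dx = q$corners["D", 1], dy = q$corners["D", 2],
      dpx = q$corners["D'", 1], dpy = q$corners["D'", 2],
      thickness = q$t_plus + q$t_minus
    )
  }))
  list(patches = patches, manifest = manifest)
}
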