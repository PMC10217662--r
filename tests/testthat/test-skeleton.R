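test_that("a wide rectangle thins to its horizontal midline", {
  m <- matrix(0L, 40, 300)
  m[11:30, 21:280] <- 1L  # height 20 centred on rows 11..30 (y 10..29)
  sk <- extract_skeleton(m)
  interior <- sk$nodes[sk$nodes[, 1] > 60 & sk$nodes[, 1] < 240, , drop = FALSE]
  expect_gt(nrow(interior), 100)
  expect_lte(mean(abs(interior[, 2] - 19.5)), 1)
})

test_that("a disk collapses to a few central pixels", {
  g <- expand.grid(y = 0:60, x = 0:60)
  m <- matrix(as.integer((g$x - 30)^2 + (g$y - 30)^2 <= 25^2), 61, 61)
  sk <- extract_skeleton(m)
  expect_lte(nrow(sk$nodes), 12)
  expect_true(all(abs(sk$nodes[, 1] - 30) <= 4))
  expect_true(all(abs(sk$nodes[, 2] - 30) <= 4))
})

test_that("degenerate single-pixel masks warn and give a single node", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_warning(sk <- extract_skeleton(m), "single-pixel")
  expect_equal(nrow(sk$nodes), 1)
  expect_error(extract_skeleton(matrix(0L, 5, 5)), "no foreground")
})

# build a skeleton_graph directly from a polyline drawing
graph_from_pixels <- function(pts, shape = c(200, 200)) {
  m <- matrix(0L, shape[1], shape[2])
  m[cbind(pts[, 2] + 1, pts[, 1] + 1)] <- 1L
  sk <- extract_skeleton(m)
  sk
}

test_that("pruning keeps the two longest arms of a Y and drops short stems", {
  # Y: two long horizontal arms (100, 90) and a short vertical stem (20)
  arm1 <- cbind(x = 0:100, y = 100L)
  arm2 <- cbind(x = 101:190, y = 100L)
  stem <- cbind(x = 100L, y = 80:99)
  sk <- graph_from_pixels(rbind(arm1, arm2, stem))
  # the raw skeleton has one branch point (degree >= 3)
  deg <- tabulate(c(sk$edges), nbins = nrow(sk$nodes))
  expect_equal(sum(deg >= 3), 1)

  poly <- prune_to_longest_axis(sk, min_branch = 30)
  L <- sum(sqrt(rowSums(diff(poly)^2)))
  expect_equal(L, 190, tolerance = 1)
  expect_true(all(poly[, 2] == 100))  # stem removed

  # straight line passes through unchanged
  line <- graph_from_pixels(cbind(x = 10:150, y = 50L))
  poly2 <- prune_to_longest_axis(line, min_branch = 30)
  expect_equal(nrow(poly2), 141)

  # stem longer than min_branch survives pruning and wins the diameter
  poly3 <- prune_to_longest_axis(sk, min_branch = 5)
  expect_equal(sum(sqrt(rowSums(diff(poly3)^2))), 190, tolerance = 1)
})

test_that("bisect_axis cuts the axis into equal near-target segments", {
  straight <- cbind(x = c(0, 12288), y = c(0, 0))
  segs <- bisect_axis(straight, 4096)
  expect_length(segs, 3)
  lens <- vapply(segs, `[[`, 0, "length")
  expect_lt(diff(range(lens)), 1e-9)
  expect_equal(lens[1], 4096)
  # consecutive segments share endpoints
  for (i in 1:2) expect_equal(segs[[i]]$B, segs[[i + 1]]$A)

  expect_length(bisect_axis(cbind(c(0, 3000), c(0, 0)), 4096), 1)

  segs3 <- bisect_axis(cbind(c(0, 10000), c(0, 0)), 4096)
  expect_length(segs3, 3)
  expect_equal(vapply(segs3, `[[`, 0, "length"), rep(10000 / 3, 3),
               tolerance = 0.5 / 3333)

  # curved polyline: arc-length equality still holds
  t <- seq(0, 4 * pi, length.out = 2000)
  curve <- cbind(x = 600 * t / (4 * pi), y = 40 * sin(t))
  segsc <- bisect_axis(curve, 200)
  lensc <- vapply(segsc, function(s) {
    sum(sqrt(rowSums(diff(s$polyline)^2)))
  }, 0)
  expect_lt(diff(range(lensc)), 1)
})

test_that("expand_to_quad reaches the mask boundary within one step", {
  H <- 60
  m <- matrix(0L, 100, 300)
  m[21:(20 + H), 21:280] <- 1L
  seg <- structure(
    list(A = c(60, 50), B = c(240, 50), polyline = cbind(c(60, 240), c(50, 50)),
         length = 180, index = 1L),
    class = "axis_segment"
  )
  q <- expand_to_quad(seg, m, step = 16)
  expect_equal(q$t_plus + q$t_minus, H, tolerance = 16)
  expect_true(q$t_plus + q$t_minus >= H - 2)

  # mask equal to the 1-px line of the segment itself
  thin <- matrix(0L, 100, 300)
  thin[51, 61:241] <- 1L
  q2 <- expand_to_quad(seg, thin, step = 16)
  expect_lte(q2$t_plus + q2$t_minus, 2 * 16)

  seg0 <- seg; seg0$B <- seg0$A
  expect_error(expand_to_quad(seg0, m), "zero length")
})

test_that("rectifying an axis-aligned quad equals direct slicing", {
  set.seed(5)
  px <- array(runif(80 * 120 * 3), c(80, 120, 3))
  sl <- slide_raster(px)
  msk <- matrix(sample(0:1, 80 * 120, TRUE), 80, 120)
  corners <- rbind(
    "C'" = c(20, 10), "C" = c(20, 49), "D" = c(79, 49), "D'" = c(79, 10)
  )
  quad <- structure(
    list(corners = corners, A = c(20, 29.5), B = c(79, 29.5),
         source_segment = list(length = 60, index = 1L),
         t_plus = 19.5, t_minus = 19.5),
    class = "patch_quad"
  )
  out <- rectify_patch(quad, sl, list(m = msk), out_size = c(60, 40))
  expect_equal(out$rectified, px[11:50, 21:80, ], tolerance = 1e-12)
  expect_identical(out$rectified_masks$m, msk[11:50, 21:80])

  # warping an all-ones mask stays all ones
  ones <- matrix(1L, 80, 120)
  out1 <- rectify_patch(quad, NULL, list(m = ones), out_size = c(60, 40))
  expect_true(all(out1$rectified_masks$m == 1L))
})

test_that("rectifying a 90-degree rotated quad equals the rotated crop", {
  set.seed(6)
  px <- array(runif(100 * 100 * 3), c(100, 100, 3))
  sl <- slide_raster(px)
  # axis A->B pointing down (+y); the perpendicular +90 rotation of (0,1)
  # is (-1, 0), so C sits at smaller x
  corners <- rbind(
    "C'" = c(70, 20), "C" = c(31, 20), "D" = c(31, 59), "D'" = c(70, 59)
  )
  quad <- structure(
    list(corners = corners, A = c(50.5, 20), B = c(50.5, 59),
         source_segment = list(length = 40, index = 1L),
         t_plus = 19.5, t_minus = 19.5),
    class = "patch_quad"
  )
  out <- rectify_patch(quad, sl, out_size = c(40, 40))
  crop <- px[21:60, 32:71, ]  # 0-based x 31..70 -> R columns 32..71
  # output x axis runs along A->B (down the crop's rows); output y runs from
  # C' (x = 70) to C (x = 31), i.e. against the crop's columns
  expected <- array(0, c(40, 40, 3))
  for (ch in 1:3) expected[, , ch] <- t(crop[, 40:1, ch])
  expect_equal(out$rectified, expected, tolerance = 1e-12)
})

test_that("partition covers a sinusoidal band and preserves orientation", {
  m <- sinusoidal_band_mask(900, 260, thickness = 70, amplitude = 25,
                            wavelength = 800)
  # lesion occupies the basal (lower) third of the band everywhere
  xs <- seq_len(900) - 1
  centre <- 260 / 2 + 25 * sin(2 * pi * xs / 800)
  rowg <- matrix(seq_len(260) - 1, 260, 900)
  cmat <- matrix(centre, 260, 900, byrow = TRUE)
  lesion <- (m == 1L & (rowg - cmat) >= 70 / 2 - 70 / 3) * 1L

  reg <- extract_regions(m, min_area = 1000)[[1]]
  part <- partition_region(reg, slide = NULL,
                           masks = list(se = m, lesion = lesion),
                           segment_target_length = 250, min_branch = 40,
                           step = 8, out_size = c(128, 128))
  cov <- quad_coverage(part$patches, reg)
  expect_gte(cov$coverage, 0.95)
  expect_lte(cov$max_claims, 2)

  for (q in part$patches) {
    se_r <- q$rectified_masks$se
    le_r <- q$rectified_masks$lesion
    se_rows <- which(rowSums(se_r) > 0)
    le_rows <- which(rowSums(le_r) > 0)
    # lesion thickness fraction ~ 1/3 of the epithelial thickness (+-10%)
    expect_lt(abs(length(le_rows) / length(se_rows) - 1 / 3), 0.1)
    # and it sits at the bottom (basal side) of the rectified patch
    expect_gt(min(le_rows), stats::median(se_rows))
    expect_equal(max(le_rows), max(se_rows), tolerance = 3)
  }
})
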