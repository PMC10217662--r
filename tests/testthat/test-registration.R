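test_that("contour mapping applies the field point-wise", {
  shp <- c(300, 300)
  f0 <- make_field("identity", shape = shp)
  pts <- cbind(x = c(10, 100.5, 250), y = c(20, 200.25, 40))
  expect_equal(map_contour_to_ihc(pts, f0), pts, ignore_attr = TRUE)

  ft <- make_field("translation", list(dx = 10, dy = -5), shp)
  out <- map_contour_to_ihc(cbind(100, 200), ft)
  expect_equal(unname(out[1, ]), c(90, 205))

  expect_error(
    map_contour_to_ihc(cbind(c(10, 500), c(10, 10)), f0),
    "index 2"
  )
})

test_that("affine fields map contours like the closed-form affine transform", {
  A <- matrix(c(1.02, 0.01, -0.015, 0.98), 2, 2)
  b <- c(3.5, -2.25)
  fld <- make_field("affine", list(A = A, b = b), c(400, 400))
  set.seed(3)
  pts <- cbind(x = runif(50, 10, 380), y = runif(50, 10, 380))
  mapped <- map_contour_to_ihc(pts, fld)
  expected <- t(A %*% t(pts)) + matrix(b, 50, 2, byrow = TRUE)
  expect_lt(max(abs(mapped - expected)), 1e-6)
})

test_that("pull-back reproduces copies, shifts and zero-fill at borders", {
  m <- matrix(0L, 60, 80)
  m[20:40, 30:60] <- 1L
  shp <- c(60, 80)
  expect_identical(pull_back_mask(m, make_field("identity", shape = shp)), m)

  ft <- make_field("translation", list(dx = -7, dy = 4), shp)
  out <- pull_back_mask(m, ft)
  # H&E pixel (x, y) samples IHC at (x + 7, y - 4)
  oracle <- matrix(0L, 60, 80)
  for (r in 1:60) for (c in 1:80) {
    sr <- r - 4; sc <- c + 7
    if (sr >= 1 && sr <= 60 && sc >= 1 && sc <= 80) oracle[r, c] <- m[sr, sc]
  }
  expect_identical(out, oracle)

  expect_error(
    pull_back_mask(m, make_field("identity", shape = c(10, 10)), shp),
    "does not match"
  )
})

test_that("affine pull-back composed with its inverse is the identity", {
  A <- matrix(c(1.05, 0.02, -0.01, 0.97), 2, 2)
  b <- c(4, -3)
  Ainv <- solve(A)
  binv <- -Ainv %*% b
  shp <- c(128, 128)
  f1 <- make_field("affine", list(A = A, b = b), shp)
  f2 <- make_field("affine", list(A = Ainv, b = as.vector(binv)), shp)
  m <- matrix(0L, 128, 128)
  m[30:100, 40:90] <- 1L
  back <- pull_back_mask(pull_back_mask(m, f1), f2)
  expect_gte(mask_iou(back, m), 0.99)
})

test_that("smooth random fields are band-limited, bounded and reproducible", {
  f1 <- make_field("smooth_random", list(amplitude = 8, correlation_length = 256),
                   c(200, 200), seed = 7)
  f2 <- make_field("smooth_random", list(amplitude = 8, correlation_length = 256),
                   c(200, 200), seed = 7)
  expect_identical(f1, f2)
  expect_lte(max(abs(c(f1$f_x, f1$f_y))), 8)
  # smoothness: neighbouring pixels differ by much less than the amplitude
  expect_lt(max(abs(diff(f1$f_x))), 8 / 16)
  f3 <- make_field("smooth_random", list(amplitude = 8, correlation_length = 256),
                   c(200, 200), seed = 8)
  expect_false(identical(f1, f3))
  expect_error(make_field("vortex", shape = c(10, 10)), "unknown field kind")
})

test_that("field files round-trip losslessly and reject wrong plane counts", {
  tmp <- withr::local_tempdir()
  f <- make_field("smooth_random", list(amplitude = 8, correlation_length = 64),
                  c(50, 70), seed = 1)
  p <- file.path(tmp, "f.tif")
  write_field(f, p)
  g <- read_field(p)
  # float32 storage: second round trip is bit-identical
  expect_equal(g$f_x, f$f_x, tolerance = 1e-6)
  p2 <- file.path(tmp, "g.tif")
  write_field(g, p2)
  expect_identical(read_field(p2), g)

  # truncate the IFD chain to one plane -> plane-count error
  raw <- readBin(p, "raw", file.size(p))
  nbytes <- 4 * 50 * 70
  next_ptr <- 8 + 2 * nbytes + 2 + 12 * 10  # offset of IFD1's next-IFD field
  raw[next_ptr + (1:4)] <- as.raw(0)
  p3 <- file.path(tmp, "one_plane.tif")
  writeBin(raw, p3)
  expect_error(read_field(p3), "exactly 2 planes")
})

test_that("contour mapping and mask pull-back agree up to a boundary band", {
  shp <- c(220, 220)
  fld <- make_field("smooth_random", list(amplitude = 5, correlation_length = 128),
                    shp, seed = 12)
  # convex polygon in the H&E frame, densely resampled
  theta <- seq(0, 2 * pi, length.out = 257)[-257]
  pts_he <- cbind(x = 110 + 60 * cos(theta), y = 110 + 55 * sin(theta))
  he_mask <- rasterize_annotations(
    annotation_set(list(list(label = "SE", points = pts_he))), "SE", shp
  )
  # forward: rasterize the mapped contour in the IHC frame, then pull back
  pts_ihc <- map_contour_to_ihc(pts_he, fld)
  ihc_mask <- rasterize_annotations(
    annotation_set(list(list(label = "SE", points = pts_ihc))), "SE", shp
  )
  back <- pull_back_mask(ihc_mask, fld, shp)
  # disagreements must hug the polygon boundary (1-px band)
  sym <- (back != he_mask) * 1
  if (sum(sym) > 0) {
    brush <- EBImage::makeBrush(3, "box")
    band <- EBImage::dilate(he_mask, brush) - EBImage::erode(he_mask, brush)
    expect_true(all(band[sym == 1] == 1))
  }
  expect_gte(mask_iou(back, he_mask), 0.95)
})
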