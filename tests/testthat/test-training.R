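test_that("cross-entropy matches closed forms on worked cases", {
  y1 <- matrix(1, 2, 2)
  expect_equal(cross_entropy_loss(matrix(1, 2, 2), y1), 0, tolerance = 1e-5)
  expect_equal(
    cross_entropy_loss(matrix(0.5, 1, 1), matrix(1, 1, 1)),
    -log(0.5)
  )
  expect_equal(round(cross_entropy_loss(matrix(0.5, 1, 1), matrix(1, 1, 1)), 4), 0.6931)
  expect_error(cross_entropy_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "equal shapes")
  # the positive-term-only form scores all-positive predictions as perfect --
  # which is why it is not the default
  rho_all1 <- matrix(1, 4, 4)
  y_mixed <- matrix(c(1, 0), 4, 4)
  expect_equal(cross_entropy_loss(rho_all1, y_mixed, literal = TRUE), 0,
               tolerance = 1e-5)
  expect_gt(cross_entropy_loss(rho_all1, y_mixed), 100)
})

test_that("dice loss reproduces the worked substitutions", {
  y <- matrix(c(rep(1, 6), rep(0, 10)), 4, 4)
  expect_equal(dice_loss(y, y), 0, tolerance = 1e-12)
  # both empty, eps = 1 -> 1 - 1/1 = 0
  z <- matrix(0, 3, 3)
  expect_equal(dice_loss(z, z), 0)
  # TP=0, FP=4, FN=6 -> 1 - 1/11
  rho <- matrix(0, 4, 4); rho[7:10] <- 1
  y2 <- matrix(0, 4, 4); y2[1:6] <- 1
  expect_equal(dice_loss(rho, y2, epsilon = 1), 1 - 1 / 11)
  expect_equal(round(dice_loss(rho, y2, epsilon = 1), 4), 0.9091)
  # hard counts binarize at 0.5
  expect_equal(dice_loss(y2 * 0.9, y2, soft = FALSE), 0)
  expect_error(dice_loss(z, z, epsilon = 0), "epsilon")
})

test_that("class weights scale the loss as 1 - w_c per true class", {
  set.seed(41)
  rho <- matrix(runif(16), 4, 4)
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  # equal weights halve the unweighted loss
  w_eq <- c("0" = 0.5, "1" = 0.5)
  expect_equal(
    weighted_cross_entropy(rho, y, w_eq),
    0.5 * cross_entropy_loss(rho, y),
    tolerance = 1e-12
  )
  # training composition 961 HSIL / 4921 patches -> HSIL weight 1 - w ~ 0.8047
  w_hsil <- 961 / 4921
  expect_equal(round(1 - w_hsil, 4), 0.8047)
  one_pos <- matrix(1, 1, 1)
  expect_equal(
    weighted_cross_entropy(matrix(0.5, 1, 1), one_pos,
                           c("0" = 1 - w_hsil, "1" = w_hsil)),
    (1 - w_hsil) * (-log(0.5))
  )
  expect_error(
    weighted_cross_entropy(rho, y, c("1" = 0.5)),
    "named class weights"
  )
})

test_that("loss implementations match brute-force summation on random instances", {
  set.seed(42)
  w1 <- 961 / 4921; w0 <- 1 - w1
  for (trial in 1:200) {
    rho <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_lt(abs(cross_entropy_loss(rho, y) - ce_oracle(rho, y)), 1e-9)
    expect_lt(
      abs(weighted_cross_entropy(rho, y, c("0" = w0, "1" = w1)) -
            wce_oracle(rho, y, w0, w1)),
      1e-9
    )
    expect_lt(abs(dice_loss(rho, y) - dice_oracle(rho, y)), 1e-9)
    expect_gte(dice_loss(rho, y), 0)
    expect_lt(dice_loss(rho, y), 1)
    expect_gte(cross_entropy_loss(rho, y), 0)
    expect_lte(
      weighted_cross_entropy(rho, y, c("0" = w0, "1" = w1)),
      cross_entropy_loss(rho, y) + 1e-12
    )
  }
})

test_that("balanced sampler emits half-and-half batches deterministically", {
  items <- data.frame(
    id = seq_len(961 + 3960),
    class = c(rep("HSIL", 961), rep("non_HSIL", 3960))
  )
  batches <- balanced_sampler(items, batch_size = 32, n_batches = 50, seed = 9)
  for (b in batches) {
    expect_equal(sum(b$class == "HSIL"), 16)
    expect_equal(sum(b$class == "non_HSIL"), 16)
  }
  again <- balanced_sampler(items, batch_size = 32, n_batches = 50, seed = 9)
  expect_identical(batches, again)
  other <- balanced_sampler(items, batch_size = 32, n_batches = 50, seed = 10)
  expect_false(identical(batches, other))

  # single item per class: sampled with replacement
  tiny <- balanced_sampler(c("a", "b"), batch_size = 4, n_batches = 3, seed = 1)
  for (b in tiny) expect_equal(sort(unique(b$id)), c(1, 2))

  expect_error(balanced_sampler(c("a", "a"), 4, 1), "two classes")
  expect_error(balanced_sampler(c("a", "b"), 3, 1), "even")
})

test_that("backend fitting recovers the generator palette and beats defaults", {
  s <- generate_slide(synth_config(seed = 51))
  tl_he <- tile_slide(s$he, 256, 128)
  tl_se <- tile_slide((s$se_mask > 0) * 1L, 256, 128)
  pairs <- Map(function(t, y) list(tile = t, y = y), tl_he$tiles, tl_se$tiles)
  pairs <- Filter(function(p) sum(p$y) > 0, pairs)
  fitted <- fit_reference_backend(pairs[seq_len(min(8, length(pairs)))])
  fit <- fitted$params$fit
  # fitted hue interval brackets both epithelium and lesion hues
  expect_lte(fit$h[1], silkit:::SYNTH_PALETTE$hsil$h)
  expect_gte(fit$h[2], silkit:::SYNTH_PALETTE$epithelium$h)
  # and excludes the near-white background via the saturation floor
  expect_gt(fit$s[1], silkit:::SYNTH_PALETTE$he_background$s)

  # argmin property: fitted loss <= loss of an arbitrary default interval
  eval_loss <- function(h, s, v) {
    mean(vapply(pairs[seq_len(min(8, length(pairs)))], function(p) {
      hv <- silkit:::rgb_to_hsv_planes(p$tile)
      pred <- (hv$h >= h[1] & hv$h <= h[2] & hv$s >= s[1] & hv$v <= v[2]) * 1
      dice_loss(pred, p$y) + cross_entropy_loss(pred, p$y) / length(p$y)
    }, 0))
  }
  expect_lte(fit$loss, eval_loss(c(0, 1), c(0.1, 1), c(0, 1)) + 1e-9)

  expect_warning(
    fit_reference_backend(list(list(tile = array(1, c(8, 8, 3)),
                                    y = matrix(0, 8, 8)))),
    "degenerate"
  )
  expect_error(fit_reference_backend(list()), "empty training set")
})
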