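# Losses and sampling used to fit segmentation backends.
#
# Note on the cross-entropy form: written with only the positive term
# (y * log(rho)), the loss is minimized by predicting 1 everywhere. The
# default here is therefore the standard two-class form with both terms;
# literal = TRUE reproduces the positive-term-only form for comparison.

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Pixel-wise cross-entropy loss
#'
#' `-sum(y * log(rho) + (1 - y) * log(1 - rho))` over all pixels.
#' Probabilities are clipped to `[eps_clip, 1 - eps_clip]` before taking
#' logs.
#'
#' @param rho numeric matrix of positive-class probabilities in `[0, 1]`.
#' @param y binary ground-truth matrix of the same shape.
#' @param literal if TRUE, only the positive term `-sum(y * log(rho))` is
#'   returned.
#' @param eps_clip probability clipping bound.
#' @return non-negative scalar loss.
#' @export
cross_entropy_loss <- function(rho, y, literal = FALSE, eps_clip = 1e-7) {
  if (!all(dim(rho) == dim(y)))
    sil_data_error("probability map and label mask must have equal shapes")
  p <- clip_prob(rho, eps_clip)
  if (literal) -sum(y * log(p))
  else -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice loss
#'
#' `1 - (2 TP + eps) / (FP + 2 TP + FN + eps)` with the smoothing parameter
#' `eps` defaulting to 1. With `soft = TRUE` (default) TP/FP/FN are
#' probability-weighted pixel counts, which is the differentiable form used
#' during fitting; `soft = FALSE` binarizes the prediction at 0.5 first
#' (hard counts, the evaluation form).
#'
#' @param rho probability map (or binary prediction).
#' @param y binary ground truth of the same shape.
#' @param epsilon smoothing parameter (> 0), default 1.
#' @param soft probability-weighted counts (TRUE) or hard counts at 0.5.
#' @return loss in `[0, 1)`.
#' @export
dice_loss <- function(rho, y, epsilon = 1, soft = TRUE) {
  if (!all(dim(rho) == dim(y)))
    sil_data_error("probability map and label mask must have equal shapes")
  if (epsilon <= 0) sil_config_error("epsilon must be > 0")
  p <- if (soft) rho else (rho >= 0.5) * 1
  tp <- sum(p * y)
  fp <- sum(p * (1 - y))
  fn <- sum((1 - p) * y)
  1 - (2 * tp + epsilon) / (fp + 2 * tp + fn + epsilon)
}

#' Class-weighted cross-entropy loss
#'
#' Each pixel's cross-entropy term is multiplied by `1 - w_c` of the pixel's
#' true class, where `w_c` is the sample proportion of class `c` — abundant
#' classes are down-weighted. With the training composition of 961 HSIL
#' patches among 4921, the HSIL weight is `1 - 961/4921 ~= 0.805`.
#'
#' @param rho probability map.
#' @param y binary ground truth.
#' @param w named numeric vector with the sample proportions of classes
#'   `"0"` and `"1"`, each in (0, 1).
#' @inheritParams cross_entropy_loss
#' @return non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(rho, y, w, literal = FALSE, eps_clip = 1e-7) {
  if (!all(c("0", "1") %in% names(w)))
    sil_config_error("w must carry named class weights \"0\" and \"1\"")
  if (any(w <= 0) || any(w >= 1))
    sil_config_error("class proportions must lie in (0, 1)")
  if (!all(dim(rho) == dim(y)))
    sil_data_error("probability map and label mask must have equal shapes")
  p <- clip_prob(rho, eps_clip)
  if (literal) {
    -sum((1 - w["1"]) * y * log(p))
  } else {
    -sum((1 - w["1"]) * y * log(p) + (1 - w["0"]) * (1 - y) * log(1 - p))
  }
}

#' Class-balanced batch sampler
#'
#' Emits batches containing exactly `batch_size / 2` items of each class,
#' drawing with replacement whenever a class pool is smaller than required
#' (the minority class is oversampled). Deterministic for a fixed seed.
#'
#' @param items data frame with columns `id` and `class` (two classes), or a
#'   vector of class labels (ids default to indices).
#' @param batch_size even batch size.
#' @param n_batches number of batches to emit.
#' @param seed integer seed.
#' @return list of `n_batches` data frames with columns `id` and `class`.
#' @export
balanced_sampler <- function(items, batch_size, n_batches, seed = 1L) {
  if (batch_size %% 2 != 0) sil_config_error("batch_size must be even")
  if (!is.data.frame(items))
    items <- data.frame(id = seq_along(items), class = items)
  cls <- sort(unique(items$class))
  if (length(cls) != 2)
    sil_config_error("balanced_sampler requires exactly two classes")
  pools <- split(items$id, items$class)
  if (any(lengths(pools) == 0))
    sil_config_error("every class needs at least one item")
  k <- batch_size / 2
  withr::with_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      picked <- lapply(cls, function(cl) {
        pool <- pools[[as.character(cl)]]
        # index-based draw: sample(x, ...) on a length-1 pool would sample 1:x
        pool[sample.int(length(pool), k, replace = length(pool) < k)]
      })
      data.frame(
        id = unlist(picked),
        class = rep(cls, each = k)
      )
    })
  })
}

#' Fit the colour-interval backend to labelled tiles
#'
#' Desk-scale stand-in for training a deep backbone: grid-searches the
#' positive class's hue interval, saturation floor and value ceiling,
#' minimizing the mean over training pairs of the dice loss plus the
#' per-pixel mean cross-entropy of the candidate's binary prediction.
#' Candidates are scored from pooled hue/saturation/value histogram counts,
#' so the search is exact for interval-rule predictions and fast.
#' Deterministic.
#'
#' @param train_pairs list of `list(tile = RGB array, y = binary mask)`.
#' @param hue_breaks number of candidate hue interval edges on `[0, 1]`.
#' @param sat_floors candidate saturation lower bounds.
#' @param val_ceilings candidate value upper bounds (1 = no ceiling).
#' @param closing_radius closing radius handed to the fitted backend.
#' @param epsilon dice smoothing parameter.
#' @return a [reference_color_backend()] whose `params$fit` records the
#'   selected intervals and achieved loss.
#' @export
fit_reference_backend <- function(train_pairs, hue_breaks = 25,
                                  sat_floors = c(0.10, 0.20, 0.30),
                                  val_ceilings = c(0.65, 1.0),
                                  closing_radius = 2, epsilon = 1) {
  if (length(train_pairs) < 1) sil_config_error("empty training set")
  has_pos <- any(vapply(train_pairs, function(p) sum(p$y) > 0, logical(1)))
  if (!has_pos)
    warning("degenerate fit: no positive pixels in any training pair")

  edges <- seq(0, 1, length.out = hue_breaks)
  n_hbin <- hue_breaks - 1
  sat_edges <- sort(unique(c(0, sat_floors, 1)))
  val_edges <- sort(unique(c(0, val_ceilings, 1)))
  n_sbin <- length(sat_edges) - 1
  n_vbin <- length(val_edges) - 1

  bin_of <- function(v, e) pmin(pmax(findInterval(v, e, rightmost.closed = TRUE), 1), length(e) - 1)
  n_cells <- n_hbin * n_sbin * n_vbin
  npairs <- length(train_pairs)
  cnt_pos <- matrix(0, npairs, n_cells)
  cnt_neg <- matrix(0, npairs, n_cells)
  npix <- numeric(npairs)
  for (i in seq_len(npairs)) {
    p <- train_pairs[[i]]
    tile <- if (inherits(p$tile, "slide_raster")) p$tile$pixels else p$tile
    hv <- rgb_to_hsv_planes(tile)
    cell <- (bin_of(hv$h, edges) - 1) +
      n_hbin * (bin_of(hv$s, sat_edges) - 1) +
      n_hbin * n_sbin * (bin_of(hv$v, val_edges) - 1) + 1
    y <- as.vector(p$y)
    cnt_pos[i, ] <- tabulate(cell[y == 1], nbins = n_cells)
    cnt_neg[i, ] <- tabulate(cell[y == 0], nbins = n_cells)
    npix[i] <- length(y)
  }
  pos_tot <- rowSums(cnt_pos)

  eps_clip <- 1e-7
  cell_h <- rep(seq_len(n_hbin), times = n_sbin * n_vbin)
  cell_s <- rep(rep(seq_len(n_sbin), each = n_hbin), times = n_vbin)
  cell_v <- rep(seq_len(n_vbin), each = n_hbin * n_sbin)

  best <- NULL
  for (lo_i in seq_len(n_hbin)) for (hi_i in lo_i:n_hbin) {
    for (sf in sat_floors) for (vc in val_ceilings) {
      s_min <- which(sat_edges == sf)
      v_max <- which(val_edges == vc) - 1
      sel <- cell_h >= lo_i & cell_h <= hi_i & cell_s >= s_min & cell_v <= v_max
      tp <- as.vector(cnt_pos %*% sel)
      fp <- as.vector(cnt_neg %*% sel)
      fn <- pos_tot - tp
      tn <- npix - tp - fp - fn
      dice <- 1 - (2 * tp + epsilon) / (fp + 2 * tp + fn + epsilon)
      ce <- ((fp + fn) * (-log(eps_clip)) + (tp + tn) * (-log(1 - eps_clip))) / npix
      loss <- mean(dice + ce)
      if (is.null(best) || loss < best$loss)
        best <- list(
          loss = loss,
          h = c(edges[lo_i], edges[hi_i + 1]),
          s = c(sf, 1), v = c(0, vc)
        )
    }
  }
  palette <- list(positive = list(h = best$h, s = best$s, v = best$v))
  backend <- reference_color_backend(palette, closing_radius = closing_radius)
  backend$params$fit <- best
  backend
}
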