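#' Segmentation backends
#'
#' A segmentation backend is the pluggable model slot of the pipeline: any
#' object exposing `predict(tile)` mapping an RGB tile (array `h x w x 3` in
#' `[0, 1]`) to a per-pixel probability map of the positive class. The deep
#' backbone used on clinical slides is one such backend; the deterministic
#' colour-interval backend below is another, and is what the synthetic test
#' bench runs.
#'
#' @param name backend name.
#' @param predict function taking an RGB array and returning a numeric matrix
#'   of probabilities in `[0, 1]` with matching height/width.
#' @param label_set labels the backend distinguishes.
#' @param params backend parameters (kept for serialization).
#' @return object of class `segmentation_backend`.
#' @export
segmentation_backend <- function(name, predict, label_set = c(0L, 1L), params = list()) {
  if (!is.function(predict)) sil_config_error("predict must be a function")
  structure(
    list(name = name, predict = predict, label_set = label_set, params = params),
    class = "segmentation_backend"
  )
}

#' @export
print.segmentation_backend <- function(x, ...) {
  cat(sprintf("<segmentation_backend> %s\n", x$name))
  invisible(x)
}

#' Deterministic colour-interval segmentation backend
#'
#' Classifies each pixel by membership of hue/saturation/value intervals and
#' smooths the result with a morphological closing. Pixels matching any of
#' the configured classes receive probability 1, all others 0. Hue intervals
#' may wrap around 0 (specify `lo > hi`).
#'
#' @param palette named list of classes; each class is a list with `h`, `s`,
#'   `v` interval vectors `c(lo, hi)` in `[0, 1]` (missing intervals default
#'   to the full range).
#' @param classes names of palette entries that count as positive (default:
#'   all of them).
#' @param closing_radius disc radius (pixels) of the morphological closing
#'   applied to the accepted region; 0 disables smoothing.
#' @return a [segmentation_backend()].
#' @export
reference_color_backend <- function(palette, classes = names(palette), closing_radius = 2) {
  if (length(palette) == 0 || is.null(names(palette)))
    sil_config_error("palette must be a non-empty named list of classes")
  missing_cls <- setdiff(classes, names(palette))
  if (length(missing_cls) > 0)
    sil_config_error(sprintf(
      "classes not in palette: %s", paste(missing_cls, collapse = ", ")
    ))
  predict <- function(tile) {
    if (inherits(tile, "slide_raster")) tile <- tile$pixels
    hsv <- rgb_to_hsv_planes(tile)
    acc <- matrix(FALSE, nrow(hsv$h), ncol(hsv$h))
    for (cls in classes) {
      spec <- palette[[cls]]
      acc <- acc | hsv_interval_member(hsv, spec)
    }
    if (closing_radius > 0 && any(acc) && !all(acc)) {
      brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
      acc <- EBImage::closing(acc * 1, brush) > 0.5
    }
    acc * 1.0
  }
  segmentation_backend(
    name = sprintf("color[%s]", paste(classes, collapse = "+")),
    predict = predict,
    params = list(palette = palette, classes = classes, closing_radius = closing_radius)
  )
}

hsv_interval_member <- function(hsv, spec) {
  h <- spec$h %||% c(0, 1); s <- spec$s %||% c(0, 1); v <- spec$v %||% c(0, 1)
  hm <- if (h[1] <= h[2]) hsv$h >= h[1] & hsv$h <= h[2]
        else hsv$h >= h[1] | hsv$h <= h[2]  # wrap-around interval
  hm & hsv$s >= s[1] & hsv$s <= s[2] & hsv$v >= v[1] & hsv$v <= v[2]
}

#' Segment a whole slide
#'
#' Tiles the slide into `window`-sized fragments, rescales each to the model
#' input side, runs the backend, thresholds the probability maps and
#' stitches the per-tile binary masks back into a whole-slide mask
#' (probability `>= threshold` -> 1).
#'
#' @param slide a [slide_raster()].
#' @param backend a [segmentation_backend()].
#' @param threshold binarization threshold in (0, 1); default 0.5.
#' @param window tile window side (pixels).
#' @param model_input backend input side (pixels).
#' @return integer whole-slide binary mask.
#' @export
segment_slide <- function(slide, backend, threshold = 0.5,
                          window = 4096, model_input = 512) {
  if (threshold <= 0 || threshold >= 1)
    sil_config_error("threshold must be in (0, 1)")
  d <- dim(slide)[1:2]
  window <- min(window, max(d))
  model_input <- min(model_input, window)
  tl <- tile_slide(slide, window = window, model_input = model_input)
  masks <- vector("list", nrow(tl$grid))
  for (i in seq_len(nrow(tl$grid))) {
    p <- tryCatch(backend$predict(tl$tiles[[i]]), error = function(e) {
      sil_data_error(sprintf(
        "backend '%s' failed on tile (row %d, col %d): %s",
        backend$name, tl$grid$row[i], tl$grid$col[i], conditionMessage(e)
      ))
    })
    if (any(p < 0 | p > 1))
      sil_data_error(sprintf(
        "backend '%s' returned probabilities outside [0, 1] on tile (row %d, col %d)",
        backend$name, tl$grid$row[i], tl$grid$col[i]
      ))
    masks[[i]] <- (p >= threshold) * 1L
  }
  stitch_masks(tl$grid, masks, d)
}

#' Extract epithelial regions from a binary mask
#'
#' Finds 8-connected components of the squamous-epithelium mask, drops
#' components below `min_area`, and returns one region per component with
#' its traced boundary contour, bounding box and mask crop, sorted by area
#' (largest first). The default `min_area` of 5000 px (at 0.25 um/px)
#' removes segmentation specks that would destabilize skeletonization.
#'
#' @param se_mask binary integer matrix.
#' @param min_area minimum component area in pixels.
#' @return list of `epithelial_region` objects: `contour` (n x 2, 0-based
#'   x/y), `bbox` (`xmin`, `ymin`, `xmax`, `ymax`, 0-based inclusive),
#'   `mask_crop`, `offset` (`c(x, y)` of the crop origin), `area`.
#' @export
extract_regions <- function(se_mask, min_area = 5000) {
  m <- as_binary_mask(se_mask)
  lab <- cpp_label8(m)
  if (max(lab) == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    ymin <- min(idx[, 1]) - 1L; ymax <- max(idx[, 1]) - 1L
    xmin <- min(idx[, 2]) - 1L; xmax <- max(idx[, 2]) - 1L
    crop <- (lab[(ymin + 1):(ymax + 1), (xmin + 1):(xmax + 1), drop = FALSE] == k) * 1L
    contour <- cpp_trace_boundary(lab, k)
    structure(
      list(
        contour = contour,
        bbox = c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
        mask_crop = crop,
        offset = c(x = xmin, y = ymin),
        area = areas[k]
      ),
      class = "epithelial_region"
    )
  })
}

#' @export
print.epithelial_region <- function(x, ...) {
  cat(sprintf(
    "<epithelial_region> area %d px, bbox x[%d,%d] y[%d,%d]\n",
    x$area, x$bbox["xmin"], x$bbox["xmax"], x$bbox["ymin"], x$bbox["ymax"]
  ))
  invisible(x)
}
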