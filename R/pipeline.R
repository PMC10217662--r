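# End-to-end orchestration: synth -> fit -> segment -> transfer ->
# partition -> score -> evaluate. Stage outputs are plain files under the
# run directory so any stage can be re-run standalone; a stage is executed
# only when its sentinel output is missing, which makes re-runs idempotent
# and recomputes exactly the stages whose outputs were deleted.

#' Default pipeline configuration
#'
#' Returns the run configuration as a plain list; pass overrides as named
#' arguments or load one from a YAML file with [read_run_config()]. The
#' clinical-scale defaults of 4096/512 (window/model input) are scaled to
#' 256/128 to match the synthetic slide size; the partition target length
#' scales identically.
#'
#' @param out_dir run directory.
#' @param ... overrides of the default entries.
#' @return named list.
#' @export
run_config <- function(out_dir, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = 1L,
    n_slides = 6L,
    hsil_prevalence = 0.5,
    window = 256L,
    model_input = 128L,
    segment_threshold = 0.5,
    min_area = 2000L,
    segment_target_length = 256,
    min_branch = 48,
    expand_step = 8,
    patch_size = c(192L, 192L),
    p16_threshold = 0.05,
    hsil_threshold = 0.10,
    gate_on_p16 = TRUE,
    patient_rule = "any_patch",
    min_count = 1L,
    synth = list(),
    log_level = "info"
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' @rdname run_config
#' @param path YAML file of overrides; entries not present fall back to the
#'   defaults.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) sil_config_error(sprintf("config file not found: %s", path))
  ov <- yaml::read_yaml(path)
  cfg <- do.call(run_config, c(list(out_dir = out_dir %||% ov$out_dir %||% "."),
                               ov[setdiff(names(ov), "out_dir")]))
  cfg
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

synth_cfg_of <- function(cfg) {
  do.call(synth_config, cfg$synth)
}

scoring_cfg_of <- function(cfg) {
  scoring_config(
    p16_threshold = cfg$p16_threshold, hsil_threshold = cfg$hsil_threshold,
    gate_on_p16 = cfg$gate_on_p16, patient_rule = cfg$patient_rule,
    min_count = cfg$min_count
  )
}

#' Run the whole-slide assessment pipeline end to end
#'
#' Executes, in order: synthetic cohort generation, colour-backend fitting
#' on the training split, SE/HSIL segmentation of the H&E rasters and p16
#' segmentation of the IHC rasters, pull-back of the p16 masks onto the H&E
#' frame through each slide's displacement field, skeleton partition of the
#' predicted SE regions, per-patch diffuse-proportion calls (predicted and
#' ground-truth masks alike), slide-level aggregation, and evaluation
#' (patch/slide confusion metrics, ROC with DeLong CI, transfer IoU). All
#' stages are deterministic given `cfg$seed`.
#'
#' @param cfg a [run_config()] list.
#' @return invisibly, a list with `calls` (per-patch data frame), `slides`
#'   (per-slide data frame), `metrics`, `manifest` (file inventory with
#'   md5 hashes).
#' @export
run_pipeline <- function(cfg) {
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  synth_dir <- file.path(out, "synth")
  scfg <- synth_cfg_of(cfg)

  # --- stage: synth ---------------------------------------------------
  cohort_path <- file.path(synth_dir, "cohort.tsv")
  if (!file.exists(cohort_path)) {
    pipeline_log(cfg, "[synth] generating %d slides", cfg$n_slides)
    generate_cohort(
      cfg$n_slides, scfg, seed = cfg$seed,
      hsil_prevalence = cfg$hsil_prevalence,
      out_dir = synth_dir
    )
  }
  cohort <- utils::read.delim(cohort_path)

  # --- stage: fit-backend ----------------------------------------------
  backends_path <- file.path(out, "backends.yaml")
  if (!file.exists(backends_path)) {
    pipeline_log(cfg, "[fit] fitting colour backends on the training split")
    fits <- fit_pipeline_backends(cohort, synth_dir, cfg)
    yaml::write_yaml(fits, backends_path)
  }
  backends <- load_pipeline_backends(backends_path)

  sc <- scoring_cfg_of(cfg)
  calls_path <- file.path(out, "calls.tsv")
  slides_path <- file.path(out, "slides.tsv")
  manifest_rows <- list()

  all_calls <- list()
  all_slides <- list()
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$slide[s]
    sdir <- file.path(synth_dir, sid)
    wdir <- file.path(out, "work", sid)
    dir.create(wdir, recursive = TRUE, showWarnings = FALSE)
    sl <- read_synth_slide(sdir, scfg$microns_per_pixel)

    # --- stage: segment ------------------------------------------------
    seg_paths <- file.path(wdir, c("se_pred.png", "hsil_pred.png", "p16_ihc_pred.png"))
    if (!all(file.exists(seg_paths))) {
      pipeline_log(cfg, "[segment] %s", sid)
      se_pred <- segment_slide(sl$he, backends$se, cfg$segment_threshold,
                               cfg$window, cfg$model_input)
      hsil_pred <- segment_slide(sl$he, backends$hsil, cfg$segment_threshold,
                                 cfg$window, cfg$model_input)
      p16_ihc_pred <- segment_slide(sl$ihc, backends$p16, cfg$segment_threshold,
                                    cfg$window, cfg$model_input)
      write_mask(se_pred, seg_paths[1])
      write_mask(hsil_pred, seg_paths[2])
      write_mask(p16_ihc_pred, seg_paths[3])
    }
    se_pred <- read_mask(seg_paths[1])
    hsil_pred <- read_mask(seg_paths[2])
    p16_ihc_pred <- read_mask(seg_paths[3])

    # --- stage: transfer -----------------------------------------------
    transfer_path <- file.path(wdir, "p16_he_pred.png")
    if (!file.exists(transfer_path)) {
      pipeline_log(cfg, "[transfer] %s", sid)
      p16_he_pred <- pull_back_mask(p16_ihc_pred, sl$field, dim(se_pred))
      write_mask(p16_he_pred, transfer_path)
    }
    p16_he_pred <- read_mask(transfer_path)

    # --- stage: partition + score ---------------------------------------
    slide_calls_path <- file.path(wdir, "calls.tsv")
    if (!file.exists(slide_calls_path)) {
      pipeline_log(cfg, "[partition/score] %s", sid)
      regions <- extract_regions(se_pred, min_area = cfg$min_area)
      rows <- list()
      masks <- list(
        se_pred = se_pred, hsil_pred = hsil_pred, p16_pred = p16_he_pred,
        se_true = sl$se_mask, hsil_true = sl$hsil_mask, p16_true = sl$p16_mask_he
      )
      for (ri in seq_along(regions)) {
        part <- partition_region(
          regions[[ri]], slide = NULL, masks = masks,
          segment_target_length = cfg$segment_target_length,
          min_branch = cfg$min_branch, step = cfg$expand_step,
          out_size = cfg$patch_size
        )
        for (pi in seq_along(part$patches)) {
          q <- part$patches[[pi]]
          rm_ <- q$rectified_masks
          if (sum(rm_$se_pred) == 0 || sum(rm_$se_true) == 0) next
          pred <- call_patch(rm_$p16_pred, rm_$hsil_pred, rm_$se_pred, sc)
          true <- call_patch(rm_$p16_true, rm_$hsil_true, rm_$se_true, sc)
          rows[[length(rows) + 1]] <- cbind(
            data.frame(slide = sid, region = ri, patch = pi),
            part$manifest[pi, ],
            data.frame(
              diffuse_p16_pred = pred$diffuse_p16,
              diffuse_hsil_pred = pred$diffuse_hsil,
              p16_pred = pred$p16_status, label_pred = pred$label,
              diffuse_p16_true = true$diffuse_p16,
              diffuse_hsil_true = true$diffuse_hsil,
              p16_true = true$p16_status, label_true = true$label
            )
          )
        }
      }
      if (length(rows) == 0)
        sil_data_error(sprintf("pipeline stage partition: no scorable patches on %s", sid))
      utils::write.table(do.call(rbind, rows), slide_calls_path,
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    sc_calls <- utils::read.delim(slide_calls_path)
    all_calls[[s]] <- sc_calls

    mk_calls <- function(lbl_col, p16_col, dp16, dhsil) {
      lapply(seq_len(nrow(sc_calls)), function(i) {
        structure(list(
          diffuse_p16 = sc_calls[[dp16]][i],
          diffuse_hsil = sc_calls[[dhsil]][i],
          p16_status = sc_calls[[p16_col]][i],
          label = sc_calls[[lbl_col]][i]
        ), class = "patch_call")
      })
    }
    agg_pred <- aggregate_slide(
      mk_calls("label_pred", "p16_pred", "diffuse_p16_pred", "diffuse_hsil_pred"), sc
    )
    agg_true <- aggregate_slide(
      mk_calls("label_true", "p16_true", "diffuse_p16_true", "diffuse_hsil_true"), sc
    )
    all_slides[[s]] <- data.frame(
      slide = sid, split = cohort$split[s],
      n_patches = agg_pred$n_patches,
      n_hsil_pred = agg_pred$n_hsil, n_p16_pred = agg_pred$n_p16_positive,
      max_diffuse_p16 = agg_pred$max_diffuse_p16,
      max_diffuse_hsil = agg_pred$max_diffuse_hsil,
      label_pred = agg_pred$label, label_true = agg_true$label,
      label_cohort = cohort$label[s]
    )
  }

  calls <- do.call(rbind, all_calls)
  slides <- do.call(rbind, all_slides)
  utils::write.table(calls, calls_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(slides, slides_path, sep = "\t", row.names = FALSE, quote = FALSE)

  # --- stage: evaluate --------------------------------------------------
  pipeline_log(cfg, "[evaluate] %d patches, %d slides", nrow(calls), nrow(slides))
  metrics <- evaluate_calls(calls, slides, cohort, synth_dir)
  utils::write.table(metrics$table, file.path(out, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(metrics$roc_points, file.path(out, "roc.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(
    file = sub(paste0("^", out, "/?"), "", files),
    md5 = md5_of(files)
  )
  jsonlite::write_json(
    list(
      parameters = cfg[setdiff(names(cfg), "out_dir")],
      files = manifest
    ),
    file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(calls = calls, slides = slides, metrics = metrics,
                 manifest = manifest))
}

# Fit the three colour backends (SE / HSIL on H&E, p16 on IHC) from training
# split tiles.
fit_pipeline_backends <- function(cohort, synth_dir, cfg) {
  train <- cohort$slide[cohort$split == "train"]
  pairs_se <- list(); pairs_hsil <- list(); pairs_p16 <- list()
  for (sid in train) {
    sl <- read_synth_slide(file.path(synth_dir, sid))
    tl_he <- tile_slide(sl$he, cfg$window, cfg$model_input)
    tl_ihc <- tile_slide(sl$ihc, cfg$window, cfg$model_input)
    tl_se <- tile_slide((sl$se_mask > 0) * 1L, cfg$window, cfg$model_input)
    tl_hsil <- tile_slide(sl$hsil_mask, cfg$window, cfg$model_input)
    tl_p16i <- tile_slide(sl$p16_mask_ihc, cfg$window, cfg$model_input)
    for (i in seq_along(tl_he$tiles)) {
      if (sum(tl_se$tiles[[i]]) == 0) next
      pairs_se[[length(pairs_se) + 1]] <-
        list(tile = tl_he$tiles[[i]], y = tl_se$tiles[[i]])
      pairs_hsil[[length(pairs_hsil) + 1]] <-
        list(tile = tl_he$tiles[[i]], y = tl_hsil$tiles[[i]])
      pairs_p16[[length(pairs_p16) + 1]] <-
        list(tile = tl_ihc$tiles[[i]], y = tl_p16i$tiles[[i]])
    }
  }
  cap <- 16  # fitting tiles per task; the grid search is exact, more adds nothing
  take <- function(x) x[seq_len(min(length(x), cap))]
  list(
    se = fit_reference_backend(take(pairs_se))$params$fit,
    hsil = fit_reference_backend(take(pairs_hsil))$params$fit,
    p16 = fit_reference_backend(take(pairs_p16))$params$fit
  )
}

load_pipeline_backends <- function(path) {
  fits <- yaml::read_yaml(path)
  mk <- function(fit) {
    reference_color_backend(
      list(positive = list(h = unlist(fit$h), s = unlist(fit$s), v = unlist(fit$v)))
    )
  }
  list(se = mk(fits$se), hsil = mk(fits$hsil), p16 = mk(fits$p16))
}

evaluate_calls <- function(calls, slides, cohort, synth_dir) {
  truth01 <- as.integer(calls$label_true == "HSIL")
  pred01 <- as.integer(calls$label_pred == "HSIL")
  cm <- confusion_from_labels(truth01, pred01)
  roc <- if (length(unique(truth01)) == 2 &&
             length(unique(calls$diffuse_hsil_pred)) > 1) {
    roc_auc(calls$diffuse_hsil_pred, truth01)
  } else NULL
  dl <- if (!is.null(roc) && sum(truth01) >= 2 && sum(1 - truth01) >= 2) {
    delong_ci(calls$diffuse_hsil_pred, truth01)
  } else NULL

  slide_acc <- mean(slides$label_pred == slides$label_true)
  # transfer fidelity on truth masks: generator p16 on H&E vs its pull-back
  ious <- vapply(cohort$slide, function(sid) {
    sl <- read_synth_slide(file.path(synth_dir, sid))
    if (sum(sl$p16_mask_he) == 0 && sum(sl$p16_mask_ihc) == 0) return(NA_real_)
    mask_iou(pull_back_mask(sl$p16_mask_ihc, sl$field), sl$p16_mask_he)
  }, 0)

  table <- data.frame(
    metric = c(
      "patch_accuracy", "patch_sensitivity", "patch_specificity",
      "patch_auc", "patch_auc_lower", "patch_auc_upper",
      "slide_accuracy", "p16_pullback_iou_mean"
    ),
    value = c(
      cm$accuracy, cm$sensitivity, cm$specificity,
      dl$auc %||% NA_real_, dl$lower %||% NA_real_, dl$upper %||% NA_real_,
      slide_acc, mean(ious, na.rm = TRUE)
    )
  )
  roc_points <- if (!is.null(roc)) {
    data.frame(threshold = roc$thresholds, TPR = roc$TPR, FPR = roc$FPR)
  } else data.frame(threshold = numeric(), TPR = numeric(), FPR = numeric())
  list(table = table, roc_points = roc_points, confusion = cm, delong = dl)
}
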