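# Paired H&E/IHC synthetic slide generator.
#
# Clinical slide pairs for this workflow are private, so the test bench
# renders its own: curved epithelium bands on a pale background, HSIL
# subregions of known area fraction drawn as a darker, denser-textured layer
# occupying a configurable thickness of the band, and an IHC partner whose
# geometry is the H&E geometry warped through a known displacement field,
# with DAB-brown p16-positive subregions. Texture realism is deliberately
# minimal (flat colour + noise + dark dots): the pipeline under test is
# geometric and statistical, not a vision benchmark.

SYNTH_PALETTE <- list(
  he_background  = list(h = 0.08, s = 0.03, v = 0.97),
  epithelium     = list(h = 0.88, s = 0.45, v = 0.78),
  hsil           = list(h = 0.72, s = 0.55, v = 0.45),
  ihc_background = list(h = 0.08, s = 0.03, v = 0.97),
  counterstain   = list(h = 0.58, s = 0.25, v = 0.85),
  dab            = list(h = 0.07, s = 0.75, v = 0.50)
)

ARCHITECTURE_DEPTH <- c(lower_third = 1 / 3, two_thirds = 2 / 3, full_thickness = 1)

#' Synthetic slide configuration
#'
#' Defaults define the package's standard study conditions: 640 x 768 px
#' slides (a scaled-down whole-slide analogue; the partition geometry is
#' scale-free), two sinusoidal epithelium bands of thickness 96 px with
#' gentle curvature, lesions drawn as basal layers of known area fraction,
#' p16 block positivity concordant with HSIL in 90% of lesioned regions, and
#' a smooth random displacement field of amplitude 8 px and correlation
#' length 256 px relating the IHC frame to the H&E frame.
#'
#' @param slide_width,slide_height slide size in pixels.
#' @param band_thickness epithelium thickness in pixels (>= 16).
#' @param band_amplitude,band_wavelength sinusoidal curvature of the band
#'   centreline (pixels).
#' @param n_regions number of epithelium bands.
#' @param lesion_fraction_range interval from which per-region HSIL area
#'   fractions are drawn when not given explicitly.
#' @param lesion_architecture lesion thickness class: `"lower_third"`,
#'   `"two_thirds"` or `"full_thickness"` — which fraction of the epithelial
#'   thickness the lesion occupies, measured from the basal side.
#' @param region_lesions optional explicit per-region spec: list of
#'   `list(fraction =, architecture =, extent =)`; overrides the range.
#'   `extent` is `"focal"` (default; the lesion occupies the architecture's
#'   depth over a span sized to hit the requested area fraction — focal
#'   HSIL) or `"diffuse"` (a basal layer along the whole band whose depth
#'   fraction equals the area fraction, capped by the architecture class —
#'   basal/parabasal proliferation).
#' @param p16_concordance probability that a lesioned region carries a
#'   block-positive p16 region over the lesion span (and that a lesion-free
#'   region stays p16-negative).
#' @param field_kind,field_params displacement field for the IHC partner
#'   (see [make_field()]).
#' @param noise_sd per-channel Gaussian colour noise.
#' @param microns_per_pixel pixel pitch metadata on the emitted rasters.
#' @param palette rendering colours (named list of h/s/v), see
#'   `SYNTH_PALETTE` defaults.
#' @param seed integer seed; the whole slide is a deterministic function of
#'   the config.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(slide_width = 768, slide_height = 640,
                         band_thickness = 96,
                         band_amplitude = 24, band_wavelength = 700,
                         n_regions = 2,
                         lesion_fraction_range = c(0.15, 0.45),
                         lesion_architecture = "two_thirds",
                         region_lesions = NULL,
                         p16_concordance = 0.9,
                         field_kind = "smooth_random",
                         field_params = list(amplitude = 8, correlation_length = 256),
                         noise_sd = 0.02,
                         microns_per_pixel = 2,
                         palette = SYNTH_PALETTE,
                         seed = 1L) {
  if (band_thickness < 16)
    sil_config_error("band_thickness must be >= 16 px")
  if (any(lesion_fraction_range < 0) || any(lesion_fraction_range > 1) ||
      lesion_fraction_range[1] > lesion_fraction_range[2])
    sil_config_error("lesion_fraction_range must be an interval within [0, 1]")
  if (!lesion_architecture %in% names(ARCHITECTURE_DEPTH))
    sil_config_error(sprintf(
      "lesion_architecture must be one of %s",
      paste(names(ARCHITECTURE_DEPTH), collapse = ", ")
    ))
  lane <- slide_height / n_regions
  if (band_amplitude + band_thickness / 2 + 4 > lane / 2)
    sil_config_error(sprintf(
      "bands do not fit: amplitude %g + thickness/2 %g exceeds the lane half-height %g",
      band_amplitude, band_thickness / 2, lane / 2
    ))
  structure(
    list(
      slide_width = slide_width, slide_height = slide_height,
      band_thickness = band_thickness,
      band_amplitude = band_amplitude, band_wavelength = band_wavelength,
      n_regions = n_regions,
      lesion_fraction_range = lesion_fraction_range,
      lesion_architecture = lesion_architecture,
      region_lesions = region_lesions,
      p16_concordance = p16_concordance,
      field_kind = field_kind, field_params = field_params,
      noise_sd = noise_sd,
      microns_per_pixel = microns_per_pixel,
      palette = palette,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

palette_rgb <- function(spec) {
  as.vector(grDevices::col2rgb(grDevices::hsv(spec$h, spec$s, spec$v))) / 255
}

render_classes <- function(class_mat, colors, noise_sd, dark_dots = NULL) {
  h <- nrow(class_mat); w <- ncol(class_mat)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    lut <- vapply(colors, `[`, 0, ch)
    plane <- matrix(lut[class_mat + 1L], h, w)
    if (!is.null(dark_dots)) plane[dark_dots] <- plane[dark_dots] * 0.55
    if (noise_sd > 0) plane <- plane + stats::rnorm(h * w, 0, noise_sd)
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  img
}

#' Generate one paired synthetic slide
#'
#' Draws the epithelium bands, lesion and p16 layers in the H&E frame,
#' derives the IHC-frame masks by inverting the configured displacement
#' field (so the IHC raster is exactly the H&E geometry warped through the
#' field), renders both rasters, traces polygon annotations, and records a
#' per-region truth table whose fractions are pixel-count ratios of the
#' emitted masks.
#'
#' @param cfg a [synth_config()].
#' @return object of class `synth_slide`: `he`, `ihc` ([slide_raster()]s),
#'   `se_mask`, `hsil_mask`, `p16_mask_he`, `p16_mask_ihc`, `field`,
#'   `annotations`, `truth_table`, `config`.
#' @export
generate_slide <- function(cfg) {
  h <- cfg$slide_height; w <- cfg$slide_width
  withr::with_seed(cfg$seed, {
    xs <- seq_len(w) - 1
    margin <- 6
    rowg <- matrix(seq_len(h) - 1, h, w)
    se_mask <- matrix(0L, h, w)
    hsil_mask <- matrix(0L, h, w)
    p16_mask <- matrix(0L, h, w)
    truth <- list()

    lane <- h / cfg$n_regions
    for (i in seq_len(cfg$n_regions)) {
      y0 <- (i - 0.5) * lane
      phase <- stats::runif(1, 0, 2 * pi)
      centre <- y0 + cfg$band_amplitude *
        sin(2 * pi * xs / cfg$band_wavelength + phase)
      cmat <- matrix(centre, h, w, byrow = TRUE)
      in_x <- matrix(xs >= margin & xs <= w - 1 - margin, h, w, byrow = TRUE)
      depth <- rowg - cmat  # signed depth; + side is basal
      band <- in_x & abs(depth) <= cfg$band_thickness / 2

      spec <- if (!is.null(cfg$region_lesions)) cfg$region_lesions[[i]] else
        list(
          fraction = stats::runif(1, cfg$lesion_fraction_range[1],
                                  cfg$lesion_fraction_range[2]),
          architecture = cfg$lesion_architecture
        )
      f <- spec$fraction
      arch <- spec$architecture %||% cfg$lesion_architecture
      extent <- spec$extent %||% "focal"
      d_cap <- ARCHITECTURE_DEPTH[[arch]]

      lesion <- matrix(FALSE, h, w)
      p16 <- matrix(FALSE, h, w)
      if (f > 0) {
        if (extent == "diffuse") {
          # basal layer along the whole band; depth fraction = area fraction
          d <- min(f, d_cap)
          span <- c(margin, w - 1 - margin)
        } else {
          d <- d_cap
          span_frac <- min(1, f / d)
          span_len <- span_frac * (w - 2 * margin)
          x_start <- stats::runif(1, margin, w - margin - span_len)
          span <- c(x_start, x_start + span_len)
        }
        in_span <- matrix(xs >= span[1] & xs <= span[2], h, w, byrow = TRUE)
        lesion <- band & in_span &
          depth >= cfg$band_thickness / 2 - d * cfg$band_thickness
        # block positivity accompanies focal (HSIL-type) lesions; diffuse
        # basal layers are p16-negative except for rare aberrant staining
        p_pos <- if (extent == "focal") cfg$p16_concordance else
          1 - cfg$p16_concordance
        if (stats::runif(1) < p_pos) p16 <- band & in_span
      } else {
        # occasional discordant p16-only region exercises the gating logic
        if (stats::runif(1) > cfg$p16_concordance) {
          pf <- stats::runif(1, 0.2, 0.4)
          span_len <- pf * (w - 2 * margin)
          x_start <- stats::runif(1, margin, w - margin - span_len)
          in_span <- matrix(xs >= x_start & xs <= x_start + span_len, h, w,
                            byrow = TRUE)
          p16 <- band & in_span
        }
      }

      se_mask[band] <- 1L
      hsil_mask[lesion] <- 1L
      p16_mask[p16] <- 1L
      truth[[i]] <- data.frame(
        region = i,
        target_fraction = f,
        architecture = arch,
        se_area = sum(band),
        hsil_area = sum(lesion),
        p16_area = sum(p16),
        fraction = sum(lesion) / sum(band)
      )
    }
    truth_table <- do.call(rbind, truth)
    truth_table$label <- ifelse(truth_table$fraction > 0.10, "HSIL", "non_HSIL")

    field_seed <- sample.int(2^31 - 1, 1)
    field <- make_field(cfg$field_kind, cfg$field_params, shape = c(h, w),
                        seed = field_seed)

    # IHC-frame geometry: the exact warp of the H&E geometry through the field
    g <- expand.grid(y = seq_len(h) - 1, x = seq_len(w) - 1)
    inv <- invert_field_at(field, g$x, g$y)
    se_ihc <- matrix(as.integer(sample_nearest(se_mask, inv$x, inv$y)), h, w)
    p16_ihc <- matrix(as.integer(sample_nearest(p16_mask, inv$x, inv$y)), h, w)

    he_class <- matrix(0L, h, w)
    he_class[se_mask == 1L] <- 1L
    he_class[hsil_mask == 1L] <- 2L
    dots <- matrix(FALSE, h, w)
    n_hsil <- sum(hsil_mask == 1L)
    if (n_hsil > 0)
      dots[hsil_mask == 1L] <- stats::runif(n_hsil) < 0.3
    pal <- cfg$palette
    he <- render_classes(
      he_class,
      list(palette_rgb(pal$he_background), palette_rgb(pal$epithelium),
           palette_rgb(pal$hsil)),
      cfg$noise_sd, dark_dots = dots
    )
    ihc_class <- matrix(0L, h, w)
    ihc_class[se_ihc == 1L] <- 1L
    ihc_class[p16_ihc == 1L] <- 2L
    ihc <- render_classes(
      ihc_class,
      list(palette_rgb(pal$ihc_background), palette_rgb(pal$counterstain),
           palette_rgb(pal$dab)),
      cfg$noise_sd
    )

    annotations <- trace_mask_annotations(
      list(SE = se_mask, HSIL = hsil_mask, p16_positive = p16_mask)
    )

    structure(
      list(
        he = slide_raster(he, cfg$microns_per_pixel),
        ihc = slide_raster(ihc, cfg$microns_per_pixel),
        se_mask = se_mask, hsil_mask = hsil_mask,
        p16_mask_he = p16_mask, p16_mask_ihc = p16_ihc,
        se_mask_ihc = se_ihc,
        field = field,
        annotations = annotations,
        truth_table = truth_table,
        config = cfg
      ),
      class = "synth_slide"
    )
  })
}

#' @export
print.synth_slide <- function(x, ...) {
  cat(sprintf(
    "<synth_slide> %d x %d px, %d region(s), slide label %s\n",
    nrow(x$se_mask), ncol(x$se_mask), nrow(x$truth_table),
    if (any(x$truth_table$label == "HSIL")) "HSIL" else "non_HSIL"
  ))
  invisible(x)
}

trace_mask_annotations <- function(masks) {
  polys <- list()
  for (lbl in names(masks)) {
    m <- masks[[lbl]]
    if (sum(m) == 0) next
    lab <- cpp_label8(m)
    for (k in seq_len(max(lab))) {
      ct <- cpp_trace_boundary(lab, k)
      if (nrow(ct) >= 3) {
        colnames(ct) <- c("x", "y")
        polys[[length(polys) + 1]] <- list(label = lbl, points = ct)
      }
    }
  }
  annotation_set(polys, source_format = "asap_xml")
}

#' Generate a synthetic cohort with a stratified train/test split
#'
#' Assigns each slide an HSIL or non-HSIL status at the configured
#' prevalence, draws per-region lesion fractions accordingly (HSIL slides
#' carry one lesioned region with a fraction from `hsil_fraction_range`;
#' all other regions draw thin basal layers from `non_hsil_fraction_range`,
#' both ranges clear of the 10% calling threshold by construction), and
#' splits by slide — never by patch — stratified on slide-level status,
#' 80/20 by default.
#'
#' @param n_slides number of slides (>= 2 per stratum required to split).
#' @param cfg base [synth_config()]; per-slide seeds and lesions are derived
#'   from it and `seed`.
#' @param seed master seed for the cohort.
#' @param hsil_prevalence fraction of HSIL slides.
#' @param hsil_fraction_range,non_hsil_fraction_range lesion-fraction ranges
#'   per stratum.
#' @param train_frac training fraction of the slide-level split.
#' @param out_dir if given, every slide's artifacts (rasters, masks, field,
#'   annotations, truth tables) are written here in the layout the pipeline
#'   consumes, and rasters are dropped from the returned object.
#' @return list with `cohort` (data frame: slide, status, split, label,
#'   seed), `slides` (list of `synth_slide`, NULL when written to disk), and
#'   `dir`.
#' @export
generate_cohort <- function(n_slides, cfg = synth_config(), seed = 1L,
                            hsil_prevalence = 0.5,
                            hsil_fraction_range = c(0.15, 0.45),
                            non_hsil_fraction_range = c(0, 0.07),
                            train_frac = 0.8,
                            out_dir = NULL) {
  if (n_slides < 2) sil_config_error("a cohort needs at least 2 slides")
  n_hsil <- round(hsil_prevalence * n_slides)
  if (n_hsil < 2 || n_slides - n_hsil < 2)
    sil_config_error("too few slides per stratum to stratify the split (need >= 2)")

  withr::with_seed(seed, {
    status <- sample(c(rep("HSIL", n_hsil), rep("non_HSIL", n_slides - n_hsil)))
    slide_seeds <- sample.int(2^31 - 2, n_slides)
    split <- rep("train", n_slides)
    for (st in unique(status)) {
      idx <- which(status == st)
      n_test <- max(1L, round((1 - train_frac) * length(idx)))
      split[sample(idx, n_test)] <- "test"
    }
    draws <- stats::runif(n_slides * cfg$n_regions * 2)
  })

  slides <- vector("list", n_slides)
  cohort <- data.frame(
    slide = sprintf("slide_%02d", seq_len(n_slides)),
    status = status, split = split, seed = slide_seeds,
    label = NA_character_
  )
  di <- 1
  for (s in seq_len(n_slides)) {
    region_lesions <- lapply(seq_len(cfg$n_regions), function(r) {
      u <- draws[di + r]
      if (status[s] == "HSIL" && r == 1) {
        list(
          fraction = hsil_fraction_range[1] +
            u * diff(hsil_fraction_range),
          architecture = "two_thirds",
          extent = "focal"
        )
      } else {
        list(
          fraction = non_hsil_fraction_range[1] +
            u * diff(non_hsil_fraction_range),
          architecture = "lower_third",
          extent = "diffuse"
        )
      }
    })
    di <- di + cfg$n_regions
    cfg_s <- cfg
    cfg_s$seed <- slide_seeds[s]
    cfg_s$region_lesions <- region_lesions
    sl <- generate_slide(cfg_s)
    cohort$label[s] <- if (any(sl$truth_table$label == "HSIL")) "HSIL" else "non_HSIL"
    if (!is.null(out_dir)) {
      write_synth_slide(sl, file.path(out_dir, cohort$slide[s]))
    } else {
      slides[[s]] <- sl
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      cohort, file.path(out_dir, "cohort.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  list(
    cohort = cohort,
    slides = if (is.null(out_dir)) slides else NULL,
    dir = out_dir
  )
}

write_synth_slide <- function(sl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(sl$he, file.path(dir, "he.png"))
  write_raster(sl$ihc, file.path(dir, "ihc.png"))
  write_mask(sl$se_mask, file.path(dir, "se_mask.png"))
  write_mask(sl$hsil_mask, file.path(dir, "hsil_mask.png"))
  write_mask(sl$p16_mask_he, file.path(dir, "p16_mask_he.png"))
  write_mask(sl$p16_mask_ihc, file.path(dir, "p16_mask_ihc.png"))
  write_field(sl$field, file.path(dir, "field.tif"))
  write_annotations(sl$annotations, file.path(dir, "annotations.xml"))
  write_annotations(sl$annotations, file.path(dir, "annotations.geojson"),
                    format = "geojson")
  utils::write.table(
    sl$truth_table, file.path(dir, "truth.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

read_synth_slide <- function(dir, microns_per_pixel = 2) {
  list(
    he = read_raster(file.path(dir, "he.png"), microns_per_pixel),
    ihc = read_raster(file.path(dir, "ihc.png"), microns_per_pixel),
    se_mask = read_mask(file.path(dir, "se_mask.png")),
    hsil_mask = read_mask(file.path(dir, "hsil_mask.png")),
    p16_mask_he = read_mask(file.path(dir, "p16_mask_he.png")),
    p16_mask_ihc = read_mask(file.path(dir, "p16_mask_ihc.png")),
    field = read_field(file.path(dir, "field.tif")),
    truth_table = utils::read.delim(file.path(dir, "truth.tsv"))
  )
}
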