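# Diffuse-proportion lesion calling.
#
# A patch is p16-positive when the p16 diffuse fraction of its epithelium
# exceeds 5%, and HSIL when the HSIL diffuse proportion
#   DiffuseP_HSIL = sum(S_HSIL) / sum(S_SE)
# exceeds 10%. Both thresholds use strict inequality ("above the
# threshold"). HSIL evaluation is restricted to p16-positive patches by
# default, mirroring the diagnostic workflow where morphology review follows
# a block-positive p16 stain.

#' Scoring configuration
#'
#' @param p16_threshold diffuse-fraction threshold for p16 positivity
#'   (default 0.05).
#' @param hsil_threshold diffuse-proportion threshold for HSIL (default
#'   0.10).
#' @param gate_on_p16 evaluate HSIL only on p16-positive patches (default
#'   TRUE); when FALSE all patches are scored.
#' @param patient_rule slide/patient aggregation: `"any_patch"` (HSIL iff at
#'   least one HSIL patch) or `"min_count"`.
#' @param min_count patch count for the `"min_count"` rule.
#' @return object of class `scoring_config`.
#' @export
scoring_config <- function(p16_threshold = 0.05, hsil_threshold = 0.10,
                           gate_on_p16 = TRUE,
                           patient_rule = c("any_patch", "min_count"),
                           min_count = 1L) {
  if (p16_threshold <= 0 || p16_threshold >= 1 ||
      hsil_threshold <= 0 || hsil_threshold >= 1)
    sil_config_error("thresholds must lie in (0, 1)")
  patient_rule <- match.arg(patient_rule)
  structure(
    list(
      p16_threshold = p16_threshold, hsil_threshold = hsil_threshold,
      gate_on_p16 = gate_on_p16, patient_rule = patient_rule,
      min_count = as.integer(min_count)
    ),
    class = "scoring_config"
  )
}

#' Diffuse proportion of a lesion within the epithelium
#'
#' `sum(lesion & se) / sum(se)`: the fraction of epithelial pixels carrying
#' the lesion label. The numerator is intersected with the SE mask so lesion
#' pixels outside the epithelium cannot inflate the score.
#'
#' @param lesion_mask,se_mask binary masks of equal shape.
#' @return fraction in `[0, 1]`.
#' @export
diffuse_proportion <- function(lesion_mask, se_mask) {
  if (!all(dim(lesion_mask) == dim(se_mask)))
    sil_data_error("lesion and SE masks must have equal shapes")
  se <- as_binary_mask(se_mask)
  denom <- sum(se)
  if (denom == 0)
    sil_data_error("empty SE mask: diffuse proportion undefined")
  sum(as_binary_mask(lesion_mask) * se) / denom
}

#' Call one patch
#'
#' Computes the p16 and HSIL diffuse proportions of a patch and applies the
#' threshold rules: p16-positive iff `diffuse_p16 > p16_threshold`, HSIL iff
#' `diffuse_hsil > hsil_threshold` (strict inequalities). With
#' `cfg$gate_on_p16` (the default), p16-negative patches are labelled
#' non_HSIL without consulting the HSIL mask.
#'
#' @param p16_mask,hsil_mask,se_mask aligned binary masks.
#' @param cfg a [scoring_config()].
#' @return object of class `patch_call`: `diffuse_p16`, `diffuse_hsil`,
#'   `p16_status` (`"negative"`/`"positive"`), `label`
#'   (`"non_HSIL"`/`"HSIL"`).
#' @export
call_patch <- function(p16_mask, hsil_mask, se_mask, cfg = scoring_config()) {
  dp16 <- diffuse_proportion(p16_mask, se_mask)
  dhsil <- diffuse_proportion(hsil_mask, se_mask)
  p16_pos <- dp16 > cfg$p16_threshold
  label <- if (cfg$gate_on_p16 && !p16_pos) {
    "non_HSIL"
  } else if (dhsil > cfg$hsil_threshold) {
    "HSIL"
  } else {
    "non_HSIL"
  }
  structure(
    list(
      diffuse_p16 = dp16, diffuse_hsil = dhsil,
      p16_status = if (p16_pos) "positive" else "negative",
      label = label
    ),
    class = "patch_call"
  )
}

#' @export
print.patch_call <- function(x, ...) {
  cat(sprintf(
    "<patch_call> %s (p16 %s; diffuse p16 %.3f, HSIL %.3f)\n",
    x$label, x$p16_status, x$diffuse_p16, x$diffuse_hsil
  ))
  invisible(x)
}

#' Aggregate patch calls to the slide level
#'
#' `any_patch` rule (default, clinically conservative): the slide is HSIL iff
#' at least one patch is HSIL. `min_count` rule: HSIL iff at least
#' `cfg$min_count` HSIL patches.
#'
#' @param calls list of `patch_call`s.
#' @param cfg a [scoring_config()].
#' @return list with `label`, `n_patches`, `n_hsil`, `n_p16_positive`,
#'   `max_diffuse_p16`, `max_diffuse_hsil`.
#' @export
aggregate_slide <- function(calls, cfg = scoring_config()) {
  if (length(calls) == 0) sil_data_error("no patch calls to aggregate")
  n_hsil <- sum(vapply(calls, function(x) x$label == "HSIL", logical(1)))
  n_p16 <- sum(vapply(calls, function(x) x$p16_status == "positive", logical(1)))
  label <- switch(cfg$patient_rule,
    any_patch = if (n_hsil >= 1) "HSIL" else "non_HSIL",
    min_count = if (n_hsil >= cfg$min_count) "HSIL" else "non_HSIL"
  )
  list(
    label = label,
    n_patches = length(calls),
    n_hsil = n_hsil,
    n_p16_positive = n_p16,
    max_diffuse_p16 = max(vapply(calls, `[[`, 0, "diffuse_p16")),
    max_diffuse_hsil = max(vapply(calls, `[[`, 0, "diffuse_hsil"))
  )
}
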