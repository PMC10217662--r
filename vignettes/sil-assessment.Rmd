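---
title: "Skeleton-partitioned assessment of squamous intraepithelial lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-partitioned assessment of squamous intraepithelial lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkit)
```

## The problem

Grading cervical squamous intraepithelial lesions (SIL) on H&E biopsies is a
whole-slide task with poor inter-observer agreement. Under the two-tier LAST
nomenclature, a high-grade lesion (HSIL, CIN2/3) shows basaloid atypia
extending through two thirds or more of the epithelial thickness, while
low-grade lesions confine the proliferation to the basal third. Diffuse
("block") p16 overexpression on an immunohistochemistry (IHC) partner slide
supports the HSIL call, but the IHC section is a physically different cut:
its evidence must be brought into the H&E coordinate frame before it can
label H&E pixels.

`silkit` implements the tissue-level machinery of this workflow:

1. **Tiling** — whole-slide rasters are cut into square windows (4096 px at
   0.25 µm/px in the clinical setting), each rescaled to the model input
   side (512 px); per-tile masks are stitched back losslessly.
2. **Epithelium segmentation** — a pluggable backend maps an RGB tile to a
   per-pixel probability of squamous epithelium (SE); any model exposing
   this contract can be slotted in. The package ships a deterministic
   colour-interval backend as its reference implementation.
3. **Skeleton partition** — each SE region is reduced to its centerline,
   the longest axis is cut into equal-length segments (target 4096 px), and
   each segment is expanded perpendicular to its chord until it clears the
   SE mask, yielding quadrilateral patches that follow the epithelium's
   growth direction.
4. **IHC→H&E transfer** — p16-positive regions found on the IHC raster are
   pulled back into the H&E frame through a dense displacement field:
   the IHC coordinate of H&E point $(x, y)$ is
   $(x - f_x(x,y),\; y - f_y(x,y))$.
5. **Diffuse-proportion calling** — a patch is p16-positive when the p16
   diffuse fraction of its epithelium exceeds 5%, and HSIL when
   $\mathrm{DiffuseP}_{HSIL} = \sum S_{HSIL} / \sum S_{SE}$ exceeds 10%;
   slides aggregate by the any-patch rule (configurable).
6. **Evaluation** — confusion metrics, ROC/AUC with DeLong confidence
   intervals, mask IoU, and seeded bootstrap CIs.

Because clinical slide pairs are private, the package also ships a
synthetic-data generator producing paired H&E/IHC rasters with exact ground
truth; everything the tests and the acceptance script measure is computed on
that bench.

## Losses and sampling

Backends are fitted with the sum of a dice loss and a cross-entropy loss.
The dice loss is
$1 - (2\,TP + \varepsilon)/(FP + 2\,TP + FN + \varepsilon)$ with
$\varepsilon = 1$; soft (probability-weighted) counts are used during
fitting and hard counts for evaluation, since the choice is not dictated by
the loss definition and both are wanted in practice.

A cross-entropy written with only the positive term,
$-\sum y_{ij}\log\rho_{ij}$, is minimized by predicting 1 everywhere; the
package therefore defaults to the standard two-class form
$-\sum [y\log\rho + (1-y)\log(1-\rho)]$ and exposes `literal = TRUE` to
reproduce the positive-term-only form for comparison. Probabilities are
clipped at $10^{-7}$ before logs.

Class imbalance is handled two ways, as in the clinical training setup
(961 HSIL patches among 4921): a class-balanced batch sampler (each batch
half-and-half, minority class drawn with replacement), and a weighted
cross-entropy in which a pixel of true class $c$ is weighted $1 - w_c$,
with $w_c$ the sample proportion of class $c$ (HSIL weight
$1 - 961/4921 \approx 0.805$).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window` | 4096 px | tiling window at 0.25 µm/px (≈ 1 mm of tissue) |
| `model_input` | 512 px | backend input side; tiles are rescaled to it |
| `segment_target_length` | 4096 px | target axis length per partition patch |
| `min_branch` | 256 px | skeleton side branches shorter than this are cut off |
| `step` | 16 px | perpendicular quad-expansion increment |
| `min_area` | 5000 px | SE components below this are dropped (stabilizes skeletons) |
| `p16_threshold` | 0.05 | diffuse-fraction threshold for p16 positivity (strict >) |
| `hsil_threshold` | 0.10 | diffuse-proportion threshold for HSIL (strict >) |
| `epsilon` | 1 | dice smoothing |

Thresholds use strict inequality ("above the threshold" semantics), so a
patch at exactly 5% or 10% is negative. The numerator of every diffuse
proportion is intersected with the SE mask, so lesion pixels outside the
epithelium cannot inflate a score. HSIL is evaluated only on p16-positive
patches by default (`gate_on_p16`), mirroring the diagnostic workflow;
a switch scores all patches.

## Design choices where the design was open

* **Equal segments vs exact 4096.** "Divide equally into segments of length
  4096" is contradictory when the axis length is not a multiple of 4096; we
  use $k = \lceil L/4096 \rceil$ segments of equal length $L/k$, which
  guarantees full axis coverage at near-target lengths.
* **Edge tiles** are kept and rescaled by their own factor, never padded or
  dropped — this preserves the exact-partition invariant of tiling.
* **Skeleton extraction** uses topology-preserving (Zhang–Suen) thinning:
  it yields the connected one-pixel centerline the partition needs, whereas
  a raw distance-transform ridge is disconnected. Redundant diagonal
  adjacencies are dropped from the pixel graph so tips stay at degree 1.
  Pruning removes endpoint-to-junction branches shorter than `min_branch`;
  the surviving longest geodesic path is found by a double Dijkstra sweep
  (exact on trees, which pruned band skeletons are). Enclosed holes are
  filled before skeletonization — epithelium is simply connected, and
  segmentation pinholes would otherwise knot the skeleton into loops.
* **Axis ends** are extended along the end tangent to the region boundary
  before segmentation; thinning retracts the centerline by about half the
  band thickness at the tips, and without the extension the end patches
  would systematically miss the band's extremities.
* **Quads from chords.** The perpendicular direction is taken from the
  chord A→B, not the local tangent; expansion proceeds in `step`-px
  increments until the translated chord no longer meets the SE mask and is
  then refined by four bisection halvings. Patches are rectified by a
  projective (4-point homography) warp — bilinear for RGB, nearest-neighbour
  for masks so labels stay integral — with the A→B direction mapped to the
  output x axis, preserving the epithelium's growth orientation.
* **Field convention.** The displacement field lives on the H&E frame and
  maps H&E to IHC coordinates by subtraction; field values at non-integer
  points are read bilinearly. Mask pull-back samples nearest-neighbour
  (bilinear would fabricate fractional labels) and out-of-bounds samples
  are 0: absent IHC evidence never creates positive labels. Fields are
  stored as two-plane 32-bit-float TIFFs written by the package itself.
* **Connectivity** is 8-connected throughout (components, skeletons).
* **AUC ties** get half credit (Mann–Whitney convention); DeLong CIs come
  from placement-value variances with a normal approximation clipped to
  [0, 1]. Undefined metrics (zero denominators) are flagged, never coerced
  to 0. CIs for proportion metrics use a seeded percentile bootstrap (2000
  resamples), chosen because no method is dictated for them.
* **Patient aggregation** defaults to the clinically conservative any-patch
  rule; a minimum-count rule is available because the patch→patient rule is
  genuinely open.

## The synthetic bench

`generate_slide()` renders epithelium as sinusoidal bands (flat colour +
Gaussian noise + dark nuclear dots in lesions) on a pale background, with
per-region lesions of known area fraction. Lesions are either **focal**
(the lesion occupies a fixed fraction of the epithelial thickness — the
basal third, two thirds, or full thickness — over a span sized to reach the
requested area fraction; models focal HSIL) or **diffuse** (a thin basal
layer along the whole band whose depth fraction equals the area fraction;
models basal/parabasal proliferation in non-HSIL epithelium). The IHC
partner is the H&E geometry warped through a known displacement field
(inverted by fixed-point iteration), with DAB-brown p16 regions; p16 block
positivity accompanies focal lesions with probability `p16_concordance`,
and discordant p16-only or p16-negative regions exercise the gating logic.
The per-region truth table records pixel-count fractions of the emitted
masks, so scoring ground truth is exact by construction.

The standard study conditions used by the tests and the acceptance script:
640×768 px slides (a scaled-down whole-slide analogue — the partition
geometry is scale-free), window 256 / model input 128 / segment target 256
(the same 8:1 window:input and window:thickness proportions as the clinical
4096/512 defaults), band thickness 96 px, amplitude 24 px, wavelength
700 px, noise sd 0.02, smooth random fields of amplitude 8 px and
correlation length 256 px, 20-slide cohorts at 50% HSIL prevalence with
focal two-thirds lesions of fraction U[0.15, 0.45] on HSIL slides and
diffuse basal layers of fraction U[0, 0.07] elsewhere — both ranges clear
of the 10% calling threshold, so label recovery measures the pipeline
rather than threshold quantization. Cohorts split 80/20 by slide, never by
patch, stratified on slide-level status.

What the bench does *not* emulate: nuclear morphology, stain variation,
stromal/glandular confounders, scanner artefacts, section-to-section tissue
loss between H&E and IHC cuts. Passing tests show the geometric and
statistical machinery is correct; they say nothing about the difficulty of
segmenting real epithelium, which is the deep backend's job and out of
scope here.

## A worked run

```{r, eval = FALSE}
cfg <- run_config("silkit_run", seed = 1, n_slides = 6)
res <- run_pipeline(cfg)
res$metrics$table
#>                  metric     value
#> 1        patch_accuracy 1.0000000
#> 2     patch_sensitivity 1.0000000
#> 3     patch_specificity 1.0000000
#> 4             patch_auc 1.0000000
#> 5       patch_auc_lower 1.0000000
#> 6       patch_auc_upper 1.0000000
#> 7        slide_accuracy 1.0000000
#> 8 p16_pullback_iou_mean 0.9999051
```

On a small cleanly coloured cohort the predicted diffuse fractions separate
the classes perfectly, so the AUC is 1 and its DeLong interval degenerates
to zero width (the run warns). The acceptance script uses a 20-slide cohort
where boundary patches keep the separation imperfect.

Stage outputs are plain files under the run directory (`synth/`, `work/`,
`calls.tsv`, `slides.tsv`, `metrics.tsv`, `manifest.json` with md5 hashes);
re-running with unchanged inputs is idempotent, and deleting a stage's
output recomputes exactly that stage. A thin command-line front end wraps
the same functions (`inst/cli/silkit.R`: `synth`, `transfer`, `partition`,
`score`, `evaluate`, `run-all`; exit codes 0/2/3 for ok/config/data
errors).

## Known limitations

* The colour-interval reference backend is a stand-in for a trained
  segmentation network: it is the fixture that makes the surrounding
  pipeline testable, not a histology segmenter.
* Quads are built on segment chords; for very tight curvature (radius
  comparable to the segment length) adjacent quads overlap more and
  coverage at the inflection shoulders degrades. At the default
  segment:wavelength ratios coverage exceeds 95% with at most 2 quads
  claiming a pixel.
* Fields are inputs: the package generates synthetic fields and applies
  them, but estimating a field from a real slide pair (deformable
  registration) is explicitly delegated.
* Moore boundary tracing follows the outer contour; regions with internal
  holes are traced by their outer boundary only (holes are filled before
  partitioning anyway).
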