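---
title: "Methods: spatial immune profiling and the contextual survival classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune profiling and the contextual survival classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmequant)
```

# Overview

`tmequant` turns multichannel tissue images — multiplexed immunofluorescence
(MxIF) or ion-beam imaging (MIBI-TOF), one raster per marker — into
per-patient immune-contexture parameters and a prognostic classifier for
overall survival. The pipeline has six stages:

1. **Load** a channel stack (DAPI, CD3, CD8, CD20, CD56, CD68, pan-CK) with
   its pixel size and patient/region provenance.
2. **Foreground detection.** Each channel is background-corrected by
   subtracting its uniformly filtered image (window `bg_filter_size_px`,
   default 1000 px); a pixel is tissue when any corrected channel exceeds
   `foreground_threshold` (strictly); isolated regions of either polarity
   smaller than `artifact_min_area_px` are reassigned to their surroundings
   ("gap filling").
3. **Compartment segmentation.** The cytokeratin channel is
   Gaussian-smoothed, background-corrected and thresholded at
   `ck_threshold`: above is tumor, below is stroma; patches smaller than
   `compartment_min_area_px` are flipped to the other compartment.
4. **Cell segmentation.** Nuclei are detected on the DAPI channel — either
   through an injected detector plugin (e.g. a star-convex polygon network)
   or a built-in classical fallback (smooth, correct, threshold,
   distance-transform split of touching blobs) — and the foreground is
   tessellated into cells by nearest-seed (Voronoi) assignment from the
   nucleus centroids.
5. **Phenotyping.** Per-cell mean intensities on the shared
   background-corrected channels are gated at the marker thresholds (strict
   `>`), independently per marker; phenotypes are assigned inclusively:
   tumor cell CK+, CD4 T cell CD3+CD8−, CD8 T cell CD3+CD8+, B cell CD20+,
   NK cell CD56+, macrophage CD68+. Each cell takes the compartment under
   its rounded nucleus centroid.
6. **Spatial statistics.** Compartment areas (mm²), phenotype densities
   (cells/mm²), and mean nearest-neighbor distances with permutation
   z-scores for every ordered phenotype pair.

Two instrument presets bundle the tunables (`analysis_settings("mxif")`,
`analysis_settings("mibi")`); every field can be overridden per image.

# Parameters that matter

| field | unit | mxif | mibi | role |
|---|---|---|---|---|
| `foreground_threshold` | a.u. | 0.1 | 0 | tissue detection gate |
| `bg_filter_size_px` | px | 1000 | 1000 | background window |
| `artifact_min_area_px` | px | 5000 | 250 | gap-filling scale |
| `ck_gaussian_size_px` | px (sigma) | 10 | 10 | CK smoothing |
| `ck_threshold` | a.u. | 1.0 | 0.5 | tumor/stroma split |
| `compartment_min_area_px` | px | 5000 | 5000 | compartment cleanup |
| `marker_thresholds` | a.u. | CK .1, CD3 .3, CD8 .4, CD20 .7, CD56 .7, CD68 1.0 | all 0 | gating |
| `zscore_reps` | — | 1000 | 1000 | permutation null size |
| `microns_per_pixel` | µm/px | 0.5 | 0.5 | physical scale |

The physical pixel size is a **required configuration field**: published
area and distance figures are in mm² and µm, but the pixel pitch of the
scans is never part of the image files we read, so it must be supplied
(default 0.5 µm/px, a typical 20× whole-slide scan).

Numerical conventions, chosen once and applied everywhere:

* Coordinates are 0-based `(row, col)` with pixel centers at integers.
* All thresholds are strict (`>`); a value exactly at a threshold falls to
  the lower class.
* Uniform and Gaussian filters use nearest-edge (replicate) padding; the
  CK "size" parameter is interpreted as the Gaussian sigma in pixels.
* Region-size rules use 4-connected components.
* Voronoi ties (pixels equidistant from two seeds) go to the lower seed
  index; seeds stranded on non-foreground keep a possibly-empty cell, and
  empty cells are dropped with a count.
* Compartments are restricted to the detected foreground *before* the
  small-region cleanup.
* Per-cell means are taken over the whole Voronoi cell (not the nucleus
  only) on the same corrected channels used for foreground detection.

# The distance z-score

For ordered phenotypes A → B in a scope (compartment × region), the
observed statistic is the mean over A cells of the minimal **non-zero**
Euclidean distance to a B cell (coincident centroids are excluded, which
also handles self-pairing for A = A). The null is built by drawing |A|
cells uniformly without replacement from *all* cells in the scope, and
independently |B| cells — for a self-distance the same draw serves both
sides — and recomputing the statistic, `zscore_reps` times. Then
`z = (observed − mean_null) / sd_null` with the sample (n−1) standard
deviation. Negative z means the phenotypes are closer than chance
(clustering); |z| > 2 is read as significant. A spread-free null (e.g. the
source phenotype comprises every cell in scope) is flagged degenerate and
yields `NA` rather than a division error.

Calibration, verified in the test suite over 200 random-labeling images:
mean z ≈ 0, sd ≈ 1, |z| < 2 in ≥ 93% of images; parent–offspring clustered
phenotypes give z < −2 in the majority of images. One known limitation:
when the two phenotypes are disjoint but together cover most of the scope
(say > 40% of all cells), the null — whose two draws may overlap — is
slightly narrower than the observed statistic's sampling distribution and
|z| is mildly inflated. Sparse immune phenotypes, the regime the statistic
is used in, are unaffected.

# Per-patient aggregation and the 50-parameter shortlist

Counts and areas are pooled (summed) across a patient's images per scope,
so a pooled density is `total cells / total area` — robust to patients
contributing different numbers of image stamps; distance z-scores are
averaged unweighted across the images where they are defined. The paper
trail for the pooling rule is thin, so the choice is documented here and
kept in one place (`aggregate_patients()`).

The classifier's feature space is the fixed tumor-center shortlist of
exactly 50 parameters: 2 compartment areas + 12 densities (6 phenotypes ×
tumor/stroma) + 36 whole-tissue distance z-scores (6 × 6 ordered pairs).
Cell *counts* are deliberately excluded — they are the product of density
and area and strongly correlated with both — which is encoded as the fixed
shortlist assembler rather than a generic feature selector.

A tumor is called **inflamed** when the border CD8 T-cell density exceeds
200 cells/mm² and the border-to-center density ratio is below 10; a center
density of zero makes the ratio infinite, hence non-inflamed.

# The nested Monte-Carlo classifier

**Inner loop** (`inner_loop()`): each repetition samples 12 patients
without replacement; each parameter is median-split into two groups of 6
(stable sort by value, then patient id) and the groups are compared by
log-rank. Upon significance (p < 0.05) the group with the smaller
Kaplan-Meier area (restricted mean survival over the drawn patients'
follow-up) is labeled "shorter survival" and both group means of the
parameter are recorded. After all repetitions the recorded observations
are averaged per parameter; parameters never significant are dropped. Two
readings of the protocol were possible — averaging over significant
repetitions only, or over all — and the first is implemented, as the
recording step is conditional on significance.

**Majority vote**: a parameter votes "long" when the patient's value is at
least as close to the longer-survival mean as to the shorter-survival mean
(equidistant → long); missing values abstain; a majority of long votes is
good prognosis, ties are conservatively bad; a patient with no defined
parameter is unclassifiable.

**Outer loop** (`rank_parameters()`): each repetition (a) splits the
cohort into train/test halves balanced on survival — shorter- and
longer-than-median survivors divided as evenly as parity allows, redrawn
until the halves do not differ by log-rank (p > 0.05, capped retries);
(b) runs the inner loop on the train half; (c) computes, per surviving
parameter, the log-rank p of its individual closer-to-mean split of the
train set; (d) forms the interim classifier from the parameters that are
individually significant, ranked by that p, pruning the worst-ranked
parameter while the joint majority-vote split of the train set is not
significant; (e) applies the surviving interim classifier to the test
half — if the test split is also significant, every retained parameter
scores one **hit**. Hit counts over all repetitions rank the 50
parameters.

The candidate-filter in step (d) is a deliberate design choice on an
ambiguous protocol description. The recorded means are estimated from the
same train set the vote is evaluated on, so the joint vote of *all*
candidate parameters is essentially always train-significant — an overfit
ensemble. Starting the pruning from that full set makes pruning a no-op
and every hit credits all 50 parameters equally, which cannot produce a
differentiated hit ranking. Requiring each entering parameter to separate
the train set on its own restores the intended behavior: interim
classifiers vary across repetitions and hits concentrate on genuinely
prognostic parameters. One parameter is removed per pruning iteration.

**Final classifier** (`build_final_classifier()`): the inner loop is rerun
on the full cohort restricted to the top parameters (top-10 by hits in the
reference workflow); parameters significant in at least one repetition are
retained with their recorded means. `evaluate_classifier()` reports group
sizes, Kaplan-Meier curves, 5-/10-year overall survival per group and the
log-rank p; `cox_regression()` fits proportional hazards with Breslow tie
handling; `sensitivity_specificity()` scores the identification of
patients dying before 5 years against patients surviving beyond 10.

All Monte-Carlo stages draw from R's RNG, so a single `set.seed()` (or the
`seed` arguments) makes the entire nested procedure reproducible.

# The synthetic world

Because the pipeline's accuracy claims must be testable without external
data, the package ships generators whose outputs carry their own ground
truth.

**Tissue images** (`generate_tissue_image()`): non-overlapping disc nuclei
(dart-throwing placement with a retry cap; mean radius 4 px) inside a
circular tissue region on a 256² canvas; the DAPI channel is the disc
indicator plus dim tissue autofluorescence, lightly blurred, with Gaussian
noise; cytokeratin-high tumor islands define CK and the tumor mask; marker
channels are painted over positive nuclei at 12× the gating threshold so
that, after dilution over the Voronoi cell and background subtraction, a
positive cell's mean stays well above its gate and a negative cell's below
it. Marker positivity is drawn per marker (CSR or parent-offspring
clustered), so CD3 and CD8 overlap independently — the CD4/CD8 phenotype
ground truth combines them. What the generator does **not** emulate:
autofluorescence structure, staining gradients, nucleus shape variation
and segmentation-scale noise of real scans — a green test establishes
algorithmic correctness on well-separated data, not instrument-level
robustness.

**Cohorts** (`generate_cohort()`): 63 patients × the 50-parameter
shortlist. Distance z-scores are standard normal; areas and densities are
log-normal. Survival follows proportional hazards on *standardized*
parameter values — on the log scale for the log-normal columns, since
prognostic abundance effects are log-linear — with exponential event times
(baseline hazard 0.08/year) and administrative censoring uniform over a
10–15-year follow-up window, matching a node-negative cohort followed for
more than a decade (~50–60% observed deaths). Planted effects are named
hazard ratios per standard deviation; 2.5 (or its inverse 0.4) corresponds
to the ~3–4-fold median-split hazard ratios reported for the strongest
real contexture parameters. Non-planted columns are **not** independent:
densities and areas share a latent "inflammation" factor and distance
z-scores a factor per source phenotype (loading 0.45), mirroring the
strong block correlations of real contexture tables; 10% of noise distance
entries are missing, as undefined z-scores are in real per-patient tables.
These last two features matter: with independent, complete noise the
majority vote over-aggregates spurious signal and the hit ranking loses
its resolution — an unrealistic world made the procedure look worse than
it is.

# Known limitations

* The z-score's permutation null allows overlapping draws; for dense,
  mutually exclusive phenotype pairs |z| is mildly anti-conservative (see
  above).
* The built-in nucleus detector is a classical fallback tuned for
  blob-like nuclei; crowded or irregular nuclei need the detector plugin.
* Baseline TIFF only (uncompressed, grayscale, single-sample); vendor
  formats and pyramidal slides are out of scope.
* Whole images are held in memory; rasters beyond the configurable pixel
  budget are rejected with a tiling hint rather than processed.
* Reproducing the published per-patient numbers requires the original
  processed supplementary tables as CSV (`reproduce_cohort_analysis()`);
  they are an optional external input and are not shipped.
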