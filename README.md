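# tmequant

Quantitative spatial immune profiling of the tumor microenvironment (TME)
from multichannel tissue images, and a nested Monte-Carlo procedure that
turns the resulting immune-contexture parameters into a prognostic
classifier for overall survival.

**Who it is for.** Computational pathology and tumor-immunology groups
working with multiplexed immunofluorescence (MxIF) or ion-beam (MIBI-TOF)
imaging of solid tumors — one co-registered raster per marker (DAPI, CD3,
CD8, CD20, CD56, CD68, pan-cytokeratin) — who need a headless, scriptable
pipeline from raw channel stacks to per-patient statistics and survival
models.

## What it computes

**Image pipeline** (per image): background correction by large-kernel mean
subtraction; tissue foreground (any corrected channel > threshold, with
gap filling of small regions); tumor/stroma compartments from the smoothed
cytokeratin channel; nucleus detection (plugin interface for star-convex
polygon networks, plus a classical distance-transform watershed fallback);
Voronoi cell tessellation seeded at nucleus centroids; inclusive per-cell
phenotyping by strict intensity gates (tumor cell CK+; CD4 T cell
CD3+CD8−; CD8 T cell CD3+CD8+; B cell CD20+; NK cell CD56+; macrophage
CD68+).

**Spatial statistics**: compartment areas (mm²), phenotype densities
(cells/mm²), and for every ordered phenotype pair A → B the mean
nearest-neighbor distance

&nbsp;&nbsp;&nbsp;&nbsp;d̄(A→B) = mean over a∈A of min<sub>b∈B, d(a,b)>0</sub> d(a, b)

standardized against a permutation null (random relabeling of the same
numbers of cells within the scope, 1000 repetitions):

&nbsp;&nbsp;&nbsp;&nbsp;z = (d̄ − μ<sub>rand</sub>) / σ<sub>rand</sub>,

negative z indicating clustering beyond chance, |z| > 2 significant.

**Survival classifier**: patients × the fixed 50-parameter tumor-center
shortlist (2 areas + 12 densities + 36 distance z-scores). An inner
resampling loop (draw 12 patients, median-split each parameter 6 v 6,
log-rank; on significance record the parameter means of the shorter- and
longer-surviving halves) feeds an outer loop (balanced train/test split,
rank parameters by their train-set separation, prune a majority-vote
interim classifier to train significance, score a *hit* for every retained
parameter when the classifier also separates the test set). Hits rank the
parameters; the final classifier is rebuilt on the full cohort from the
top-ranked set and evaluated with Kaplan-Meier curves, log-rank tests and
Cox (Breslow) hazard ratios.

## Worked example

Synthetic data generators ship with the package, so the whole pipeline
runs without external inputs:

```r
library(tmequant)

## a ground-truthed synthetic tissue scan: 150 nuclei, 2 tumor islands
g <- generate_tissue_image(seed = 7)
s <- analysis_settings("mxif", compartment_min_area_px = 1000,
                       zscore_reps = 500)
res <- run_image(g$image, s, seed = 1)
print(res$quant)
#> region_quant for image syn-image (center region)
#>   tissue 0.010 mm2 (tumor 0.002, stroma 0.008)
#>   counts: CK=49, CD4=39, CD8=6, CD20=15, CD56=8, CD68=15
```

0.010 mm² of tissue (a 256² px field at 0.5 µm/px) of which 0.002 mm² is
cytokeratin-high tumor; 49 tumor cells, 39 CD4 and 6 CD8 T cells, 15
B cells, 8 NK cells, 15 macrophages. The generator plants the B cells in
clusters, and the distance z-score finds exactly that:

```r
subset(res$quant$distances, source == "CD20" & target == "CD20")
#>  source target n_source d_obs_um  mu_rand         z
#>    CD20   CD20       15 6.562868 14.64049 -4.374881
```

Observed mean B-to-B nearest-neighbor distance 6.6 µm versus 14.6 µm under
random relabeling: z = −4.4, clustering far beyond chance.

```r
## a synthetic 63-patient cohort with two planted prognostic parameters
co <- generate_cohort(planted = c("density of CD8 in Tumor in center" = 2.5,
                                  "area of Tumor in center" = 0.4), seed = 11)
rk <- rank_parameters(co$parameters, co$survival$time, co$survival$event,
                      outer_reps = 100, inner_reps = 200, seed = 42)
print(rk, n = 2)
#> ranking_result: 100 outer repetitions, 6 hits total
#>    1. area of Tumor in center                       2 hits
#>    2. density of CD8 in Tumor in center             2 hits

m <- build_final_classifier(co$parameters, co$survival$time,
                            co$survival$event,
                            names(sort(rk$hits, decreasing = TRUE))[1:5],
                            reps = 200, seed = 43)
ev <- evaluate_classifier(m, co$parameters, co$survival$time,
                          co$survival$event)
ev$groups; ev$os; ev$logrank_p
#> good  bad
#>   22   41
#>   group       os5      os10
#> 1  good 0.7727273 0.5909091
#> 2   bad 0.3902439 0.2926829
#> [1] 0.00302
```

Both planted parameters top the hit ranking; the rebuilt classifier
separates the cohort into 22 good- and 41 bad-prognosis patients with
5-year overall survival 77% vs 39% (log-rank p = 0.003).

A thin command-line wrapper over the same functions lives at
`inst/cli/tme.R` (subcommands `segment`, `run-image`, `run-cohort`,
`rank`, `build-classifier`, `classify`, `evaluate`, `simulate-image`,
`simulate-cohort`).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch — synthetic
image through quantification, then cohort ranking, final classifier and
evaluation — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`. The statistical acceptance checks
themselves (oracle equivalences, z-score calibration, planted-parameter
recovery, type-I control) live in `tests/testthat/test-acceptance.R` and
run with the ordinary test suite. Reproducing the published per-patient
numbers additionally needs the original processed supplementary tables as
CSV (see `?reproduce_cohort_analysis`); they are an optional external
input, not shipped with the package, and that check reports red without
them.
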