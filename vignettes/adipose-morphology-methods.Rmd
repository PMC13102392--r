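---
title: "Quantifying adipose morphology: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adipose morphology: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipomorph)
```

## The scientific problem

White adipose tissue grows along two axes: hyperplasia (more adipocytes)
and hypertrophy (bigger adipocytes). The balance between the two is a
strong correlate of metabolic health. In juvenile zebrafish the
subcutaneous adipose tissue (SAT) is optically accessible, each mature
adipocyte carries one dominant lipid droplet (LD), and LD diameter is a
usable proxy for adipocyte size. `adipomorph` implements a complete
quantitative pipeline from segmented LD label masks to screen-level
statistics for genetic perturbations of adipose morphology.

## From masks to measurements

The pipeline consumes integer-labelled rasters produced by an upstream
segmenter; segmentation itself is out of scope. `measure_droplets()`
reports, per label: the centroid (mean of pixel centres, scaled by the
pixel size in um), the area (pixel count times the squared pixel size),
the perimeter (exposed pixel edges), and the Feret diameter.

The Feret diameter is the maximum caliper width. We compute it as the
largest pairwise distance between vertices of the convex hull of the
pixel *corner* points, so a single pixel has Feret `sqrt(2) *
pixel_size`. The corner convention matches mainstream image-analysis
tools and avoids zero-diameter degenerate objects; the test suite
verifies the hull computation against an all-pairs brute-force oracle.
Objects smaller than 4 pixels are discarded by default (imaging at 1-2
um/px cannot resolve the small secondary LDs of multilocular adipocytes);
the cutoff is a parameter since no principled value exists at this
resolution.

## Spatial strata

LDs are deposited anteriorly first, and new LDs appear posteriorly as the
depot grows. To compare anatomically equivalent positions across fish,
droplets are binned into successive 200 um strata anchored at the
*anterior-most droplet centroid*. We use half-open intervals
`[a + (i-1)w, a + i*w)` so boundary behaviour is deterministic; the
centroid (not the droplet edge) anchors the frame because centroids are
the measured coordinate. The raster itself does not record anatomical
orientation, so `assign_strata()` takes it as an argument
(anterior-at-minimum-x by default).

## The morphology value

Mean LD diameter rises steeply with depot size and saturates near 65 um.
The phenotype score is the residual from that relationship: a penalized
thin-plate regression spline (mgcv) of mean Feret diameter on
`log(AreaSum)` is fitted to control fish, and each fish's *morphology
value* is its observed mean diameter minus the prediction at its depot
size. Positive values mean hypertrophy (fewer, larger droplets than
expected at that depot size), negative values hyperplasia.

Numerical choices:

* Basis dimension defaults to 10 with smoothing chosen by GCV; the
  basis is shrunk automatically when an experiment has few controls.
* Natural logs throughout, consistent with back-transforming mixed-model
  coefficients as `(exp(beta) - 1) * 100`.
* A pooled fit needs at least 8 control fish; experiment-specific fits
  need 5. Experiments below the minimum are dropped with a warning.
* Values are reported in um (additive residuals), the scale on which the
  diet analysis and effect sizes are interpreted.
* Fish outside the fitted `log(AreaSum)` range are scored by spline
  extrapolation but flagged.

## Screen statistics

Each gene is measured in 2-3 independent injection experiments with
matched controls; batch effects are the main threat to validity. Two
complementary analyses are run per gene:

* **Distribution tests.** Two-sample Kolmogorov-Smirnov tests on
  morphology values, both *pooled* (one control fit across experiments)
  and *stratified* (experiment-specific control fits, per-experiment KS
  tests combined with Fisher's method, `chi^2 = -2 sum log p_i` on `2k`
  df). The stratified test cannot be fooled by a between-batch shift.
  The KS effect size is the sample-size-weighted mean of per-experiment
  mutant-minus-control differences.
* **Mixed models.** `log(Feret) ~ log(AreaSum) + Genotype +
  (1 | Experiment)` estimates a uniform log-scale shift; the interaction
  model replaces `+` with `*` and tests whether allometric scaling
  itself changes. Wald normal p-values are the default: at screen sample
  sizes (n of 20-65 per arm) they are practically identical to
  Satterthwaite-corrected ones, which remain available via
  `p_method = "satterthwaite"`.

BH-FDR is applied separately to the four families (pooled KS, stratified
KS, LMM intercept, LMM slope). A gene is a **robust** hit only when both
the stratified KS and the LMM intercept survive FDR at 0.05 — a dual
criterion requiring the effect to be reproducible within batches *and*
significant after modelling batch variance. Stratified-KS-only genes are
*distributional-only* (variance or size-dependent effects); genes with
only a nominal pooled KS signal are *suggestive*.

Genes observed in a single experiment cannot be batch-corrected and are
routed to ordinary least squares plus a pooled KS test, flagged
preliminary, and kept out of every FDR family, as are genes lethal
before phenotyping.

Power for the reported power column uses the exact noncentral t
distribution (`ncp = d sqrt(n1 n2 / (n1 + n2))`), two-sided at alpha =
0.05 and d = 0.8. `sample_size_for_power()` searches that function;
because the allocation behind published minimum-n claims is typically
unstated, allocation (equal vs fixed control group) is an explicit
parameter. Note that at the minimum group size n = 2 the test has only
2 degrees of freedom, so even enormous effects (d around 8) are needed
before n = 2 suffices.

The replicate consistency score has no standard definition; ours is
`(fraction of effect pairs agreeing in sign) / (1 + CV)` with
`CV = sd / |mean|` of the per-experiment effects — 1 for identical
effects, 0 for sign-discordant ones — chosen to be deterministic and
bounded in [0, 1].

## Robustness suite

Four sensitivity analyses guard the mixed-model estimates:

* an F-test on the variance ratio of morphology values (two-sided),
  with method-of-moments skewness, excess kurtosis and the percentage
  of observations beyond 2 SD;
* a heteroscedastic mixed model (nlme, `varIdent` by genotype, ML) whose
  likelihood reduces to the homoscedastic fit when the variances are
  constrained equal — and to generalized least squares when only one
  experiment exists;
* a within-experiment permutation test (labels shuffled inside each
  batch, preserving counts; default B = 1000). We report the add-one
  estimator `(1 + exceedances) / (B + 1)`, which cannot be exactly
  zero, alongside the raw proportion; the permuted statistic is the
  absolute mixed-model genotype coefficient by default, with an
  adjusted mean-difference alternative;
* Welch's t-test on morphology values.

The consensus call is ALL SIG / ALL NS / MIXED at alpha = 0.05.

One caveat established with the generator: when mutant *fish-level*
variance is inflated, the heteroscedastic model's residual-SD ratio is
attenuated below the inflation factor because the residual also contains
droplet-sampling noise and smooth-curve lack-of-fit shared by both
genotypes. The estimator itself is unbiased — data drawn from the mixed
model with a truly doubled residual SD return a ratio of 2.0 — so the
attenuation is a property of the data composition, not the fit; the
F-test on morphology values remains sensitive in that scenario.

## Paired diet analysis

Each fish is imaged before and after a 14-day dietary period (high-fat
immersion or control), and per-stratum mean diameters are compared
within fish. The diet effect per stratum is a difference in differences:
`mean(delta | HFD) - mean(delta | control diet)`, where `delta` is the
fish's post-minus-baseline change. Because each fish contributes exactly
one delta per stratum, the per-stratum test is a Welch t-test on those
deltas, with BH across strata within genotype. Strata existing at only
one timepoint (new posterior growth) are flagged emergent and excluded
from paired contrasts. The overall contrast averages per-stratum effects
unweighted, and the blunting of the mutant response is
`100 * (effect_wt - effect_mut) / effect_wt`, rounded to an integer per
cent.

## The synthetic-data generator

No raw droplet data accompany the published screen, so the generator
provides ground truth for every stage. It encodes the structure the
analysis assumes:

* depot area log-normal around a standard-length-driven mean (SL 7-12
  mm spanning roughly 1e4-1e6 um^2);
* mean diameter on the saturating curve `D(A) = 65 (1 - exp(-0.35
  (log A - 8)))` um — the functional form is our choice; only the ~65 um
  plateau and the curvilinear regime are empirically anchored;
* droplet count = depot area x packing fraction (0.6) / mean droplet
  footprint, so hypertrophy mechanically reduces count at fixed area,
  reproducing the observed inverse count-size relation;
* log-normal noise at droplet (sd 0.30), fish (sd 0.06) and batch
  (sd 0.08) levels. The fish and droplet SDs were calibrated once so a
  194-fish wild-type population yields a smoother R^2 of ~0.85, the
  curvilinear regime reported for real data;
* genotype effects as log-scale intercept shifts, slope shifts around
  the centre of the `log(A)` range, and fish-level variance inflation;
* an anterior-posterior gradient (posterior droplets smaller by 3% per
  stratum) and, for diet experiments, a wild-type per-stratum HFD effect
  rising posteriorly (17.7-28.1 um) with mutant blunting factor 0.32
  (i.e. a 68% true reduction) and a mutant baseline hypertrophy grading
  from +22.2 um anteriorly.

`render_masks()` draws droplets as non-overlapping discs on an integer
canvas (retrying with jitter when crowded) so the geometry module can be
validated by a render-measure round trip: counts are recovered exactly
and Feret diameters within 2 pixel widths.

What the generator does *not* emulate: pigment artefacts, segmentation
errors, non-disc droplet shapes, dorsoventral structure, and any real
count-area allometry beyond the packing argument. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed data-generating process, not performance on real images.

## Problem sizes used in the shipped studies

The simulation studies in the test suite and acceptance script use the
default screen geometry (2 experiments, 30 fish per genotype per
experiment) with 100-200 replicates for recovery and error-control
studies, 60-100 replicates for the confounded-allocation comparison, and
20-100 fish for geometry round trips — sizes at which the Monte-Carlo
error of each reported rate is comfortably below the decision margins.

## Known limitations

* The morphology value inherits the control smoother's bias at the
  edges of the depot-size range; extrapolated fish are flagged but not
  excluded.
* Fisher's method assumes independent per-experiment p-values, which
  holds by design here but would fail if experiments shared controls.
* The permutation test permutes within experiment only; it does not
  address confounding *between* experiments (that is the stratified KS
  test's role).
* With two experiments, the batch variance component is estimated from
  two levels and is frequently at the boundary (singular); the genotype
  fixed effect remains well behaved, which is what the screen uses.
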