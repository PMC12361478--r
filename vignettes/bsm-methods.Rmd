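---
title: "Bodily sensation maps: models, measures and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bodily sensation maps: models, measures and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Bodily Sensation Maps (BSMs) are a self-report instrument for bodily
topography: while viewing a stimulus, a respondent clicks on two body
silhouettes — one for *activations* (stronger sensation, more energy) and
one for *deactivations* (weaker sensation, less energy) — up to ten times
per silhouette. `bsmtools` implements a complete analysis pipeline for
such data: ingestion and validation, region-wise embodiment scoring, map
rendering, pixel quantification, colour-distance clustering, the
individual-level mixed-effects analysis, and a study simulator that makes
every stage testable without human data. This vignette records the models
and the design decisions behind each stage, including the places where the
design was genuinely open and the choices are ours.

## The body template

All spatial quantities are referred to a `bsm_template`: a raster
silhouette partitioned into five disjoint regions — Head, Chest, Abdomen,
Upper Limbs, Lower Limbs — whose union is exactly the silhouette.
Coordinates are 0-based integer pixels with the origin at the top-left and
y increasing downward, matching what click-capture tools record. The
default template is drawn programmatically at 200 × 600 px (a 1:3 aspect
approximates a standing figure); any silhouette/region pair satisfying the
partition invariants can be loaded from PNG files instead. By
construction the neck belongs to Head, hands to Upper Limbs and feet to
Lower Limbs; survey instruments rarely publish their silhouette geometry,
so every pixel-level number in this package is template-relative.

Templates round-trip through one black/white silhouette PNG, one indexed
region PNG (pixel value = region index) and a small index-to-label text
file. Because the region map stores one index per pixel, overlapping
regions are unrepresentable in the external format; the loader instead
validates (and reports with exact pixel counts) the three violations the
format admits: region pixels outside the silhouette, silhouette pixels
with no region, and unknown region indices. Violations are never repaired
silently.

## Ingestion and exclusions

A study is three CSV tables — clicks (participant, image, silhouette kind,
x, y), trials (image, object, activity, image type) and participants
(condition, attention checks) — plus two optional ones: guesses
(participant × image, Mixed condition only) and presentations (one row per
trial actually shown). Guesses cannot live in a one-row-per-participant
table, and presentations are needed so that trials in which a participant
clicked *neither* silhouette still enter the analysis as zeros; both are
therefore separate files. More than ten clicks on one silhouette is an
ingest error rather than something to truncate: the collection interface
caps clicks at ten, so an excess can only be data corruption. Clicks that
land outside the silhouette are retained at ingest but excluded from
region counting, with a side tally, so data-quality problems stay visible.

`apply_exclusions()` implements the study's participant rules: a
participant is removed if they reported no clicks at all or failed an
attention check. The operation is idempotent and reports every exclusion
with its reason and the per-condition retained counts.

## The embodiment score and the mixed model

For each participant × image × region cell, let $x = n_{act} - n_{deact}$
be the difference of activation and deactivation click counts,
$x \in [-10, 10]$. The embodiment score is the signed-log transform

$$\mathrm{score}(x) = \mathrm{sign}(x)\,\log(1 + |x|),$$

which is odd, strictly increasing, and bounded by $\log 11 \approx 2.40$.
We use the natural logarithm: the transform's published form does not name
a base, and the natural log is both the convention of the analysis
language the formula comes from and the one consistent with the reported
score scale. Cells with no clicks enter as $x = 0$; with 265 participants,
34 trials each and 5 regions this gives the dense 45,050-row analysis
table the model expects.

`fit_embodiment_lmm()` fits, by maximum likelihood with the BOBYQA
optimiser,

$$\mathrm{score} \sim \mathrm{Condition} \times \mathrm{ImageType}
\times \mathrm{BodyPart} + (1\,|\,\mathrm{participant}) +
(1\,|\,\mathrm{image}),$$

with treatment coding and reference levels Condition = Mixed,
ImageType = NotArt, BodyPart = Head, so the intercept is that cell's
expected score. Coefficients are reported with Wald t statistics on
residual degrees of freedom computed as
$n_{obs} - n_{fixed} - 3$ (two random-intercept variances plus the
residual variance), the convention that reproduces the df style of
standard mixed-model reporting on this design (45,050 − 30 − 3 = 45,017);
confidence intervals are $\beta \pm 1.96\,SE$. Marginal and conditional
$R^2$ are the variance-partition quantities for this two-intercept model:
fixed-effect variance alone, and fixed plus both intercept variances,
each over the total including the residual. A rank-deficient design
(empty factor cells) or a non-converged optimiser is an error, never a
silent fallback.

Post-hoc contrasts (`emmeans_pairwise()`) are estimated marginal means
with equal weights over the averaged-out factor levels, tested
asymptotically (z), Bonferroni-corrected over the full family of returned
contrasts — 5 for the ImageType contrast within each body part, 15 for
the three condition pairs within each body part. The family is the set of
contrasts actually returned; the summary table records it.

The Mixed-condition guess analysis scores a guess as correct when a
NotArt image is attributed to product sellers or an Art image to
professional artists, reports the percentage correct per image type, and
tests association between image type and guess with Pearson's chi-squared
with Yates' continuity correction on the trial-level 2 × 2 table. The
unit is the trial (image viewing): at roughly 85 participants × 34 trials
the resulting counts are the only scale on which a three-digit
chi-squared statistic can arise.

## Rendering and pixel metrics

A density map is a sum of Gaussian kernels at activation clicks minus the
same sum at deactivation clicks, evaluated on the pixel grid and masked to
the silhouette. The default bandwidth is σ = 5 px on the 200 × 600
template, truncated at 3σ: small enough to preserve regional
localisation, large enough to turn discrete clicks into a readable field.
Density is linear in the click multiset before any normalisation, which
is what makes filtered subsets comparable.

Rendering divides the field by a scale maximum and applies a symmetric
diverging palette: neutral grey (0.85) inside the body at zero, pure red
at +1, pure blue at −1, white background. Neutral grey rather than white
inside the silhouette distinguishes "body, zero net sensation" from "not
body", which downstream pixel classification depends on. The palette is
constructed so that a body pixel's red-minus-blue channel difference
equals its normalised field value exactly; values $v$ and $-v$ therefore
render with red and blue channels swapped. When a set of maps is to be
compared (the `render_filtered_grid()` loop, and any colour-distance
analysis), all maps share one fixed scale maximum — colour distances
between maps on different scales are meaningless, and
`distance_matrix()` refuses them. Per-map scaling is available for
standalone figures.

Pixel quantification classifies each body pixel by the channel
difference: activation if red exceeds blue by more than a dead-band δ
(default 10/255), deactivation in the mirror case, neutral otherwise.
The dead-band is configurable since any published colour threshold would
be palette-specific. Counts per region are exact integer tallies; the
four labels partition the raster and ignore the background colour
entirely.

## Colour distributions, EMD and clustering

Each map's body pixels (background always excluded; neutral pixels
included, because "no sensation" area is information that distinguishes
sparse from dense maps) are binned by k-means in RGB space, k = 10 by
default, with a seeded start and ten restarts (MacQueen updates — the
Hartigan–Wong quick-transfer stage stalls on rasters with massively
duplicated colour values). A map with fewer distinct colours than k gets
exact bins and a warning. Distances between binned distributions are
Earth Mover's Distances with Euclidean RGB ground distance, solved
*exactly* by an in-package transportation simplex (north-west-corner
start, dual pricing, Bland's rule for both entering and leaving variables
so degenerate histograms cannot cycle). Exactness removes a solver
tolerance from every downstream test; with at most a few dozen bins the
LP is trivial. EMD on equal-mass distributions is a metric, and the test
suite checks identity, symmetry and the triangle inequality on random
distributions, plus agreement to 1e−9 with an independent LP solver and
with exhaustive enumeration of candidate bases on small instances.

Hierarchical clustering of the distance matrix uses average linkage by
default (the common exploratory choice; complete and single are
available), with Newick export and heatmap/dendrogram plots that follow
the low-distance = dark-blue, high-distance = pink convention.

## The study simulator

`simulate_study()` generates a complete study in the ingest format.
The study-shaped configuration (`default_study_config()`) has three
between-participant conditions with 92 / 93 / 92 participants
(Museum / Commercial / Mixed), 12 planted inclusion-rule violations
(3 / 2 / 7 per condition — alternately attention-check failures and
zero-click participants — so 89 / 91 / 85 remain), 34 objects spread
round-robin over the 11 everyday activities (eating, walking, sleeping,
working, showering, dressing, watching media, drinking, reading,
cleaning, observing), and 68 images. Each participant sees all 34
objects, 17 as Art and 17 as NotArt, never both versions of one object,
in random order.

Click counts per silhouette are truncated-Poisson(mean 3, max 10) — the
per-trial click distribution is not something published studies report,
so this is a recorded assumption with the mean in the range such
interfaces produce. Click *placement* draws a region from a softmax over
five region logits (activation and deactivation have separate logit
vectors; the default activation baseline is Head-dominant, +1 logit) and
then a uniform pixel within that region's mask. Effects are planted as
additive logit shifts per image type, condition or activity; participant
and image random effects are scalar Gaussian perturbations (sd 0.3 each
by default) of the activation Head logit. Random effects act on the
logit scale because the generator must produce clicks — the pipeline's
raw currency — rather than scores; score-scale consequences emerge
downstream. A single seeded stream drives all sampling, so a
configuration reproduces its dataset byte for byte. Mixed-condition
guesses are independent across trials with configured per-type accuracy,
defaulting to 71.49% (NotArt) and 49.62% (Art) correct.

Because planted logit shifts have no closed-form score-scale effect, the
package includes a calibrator, `expected_region_score()`: it computes the
expected cell score exactly by convolving the truncated-Poisson budget
with the binomial region allocation, and integrates the two Gaussian
random effects (which enter through one shared logit shift) by
Gauss–Hermite quadrature. Recovery tests compare fitted coefficients
against these computed truths, never against assumed ones.

## What the simulations do and do not show

Two structural facts about this pipeline, found and verified during
development, shape how parameter recovery is assessed:

* **Heteroscedasticity across body parts.** Click-count scores have
  higher variance in regions that receive more clicks. Under a
  Head-dominant preference, Head cells' residual variance exceeds the
  pooled estimate, so the homoscedastic model's Wald SEs for
  Head-specific contrasts are anticonservative (we measure empirical
  sampling SDs about 35% above the model SE at the study's size).
* **Region-specific random effects.** A logit-scale image effect shifts
  one region's preference, which a single global image intercept cannot
  fully absorb; the unabsorbed part inflates the sampling variance of
  between-image contrasts beyond what the model reports.

Both are properties of applying a homoscedastic random-intercept model to
click-derived scores — the published analysis design — not implementation
defects; any study using this model on such data inherits them. The test
suite therefore checks *confidence-interval calibration* (coverage
within ±7 points of 95% over 60 study-scale replicates) under the
configuration where the model's variance assumptions hold — uniform
baseline preferences, no logit random effects, a planted Art effect of
+0.35 on the activation Head logit — and checks *point recovery*
(estimate within 0.02 of the calibrator truth on a planted effect of
about 0.12) under the full Head-dominant, random-effects-on generator.
Simulated studies also reproduce the qualitative group-level pattern
that motivates the cluster analysis: with activity-specific preferences
and no condition effect, same-activity maps from different conditions are
closer in EMD than different-activity maps.

What passing these tests does **not** show about real data: the simulator
places clicks uniformly within a region (real clicks concentrate on
salient anatomy), draws activation and deactivation budgets
independently, and knows nothing about stimulus content beyond its
activity label. It validates the pipeline's correctness and the
estimators' behaviour, not the psychology.

## Numerical choices and scaling

Degenerate inputs are handled explicitly: empty click subsets give
all-zero fields (not errors); a zero field renders as a uniform neutral
silhouette; k-means falls back to exact binning below k distinct colours;
a single-map "clustering" is a one-leaf tree; unbalanced transport
problems, non-finite fields, mixed colour scales, empty factor cells and
absent guesses are errors with specific messages. Simulation problem
sizes in the test suite are the package's choices for a laptop-scale run:
geometry and oracle tests use an 80 × 240 template; mixed-model recovery
runs 60 study-scale replicates for coverage and 20 for point recovery;
the type-I-error check runs 2,000 null guess simulations at the Mixed
arm's size; the cluster-pattern check uses 25 + 25 participants over the
full 11-activity design. The acceptance script
(`scripts/acceptance.R`) regenerates the full 277-participant study and
reruns every stage at the default 200 × 600 template in about a minute.

## Known limitations

The silhouette is schematic and frontal-only; no sex- or
posture-specific variants. Region-level scoring cannot distinguish
locations within a region (mouth vs forehead are both Head). The EMD
compares colour *composition*, not colour *location* — two maps with the
same red/blue/grey proportions in different places are identical to it;
that is inherited from the colour-histogram method the analysis follows.
CIELAB or other perceptually uniform spaces are a documented extension
point, not implemented. REML, random slopes and Bayesian fits are out of
scope by design.
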