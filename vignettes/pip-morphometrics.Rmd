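---
title: "Pip outline morphometrics and balanced discriminant inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pip outline morphometrics and balanced discriminant inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipmorph)
```

`pipmorph` analyses the form (shape plus size) of grape pips from
two-view outline coordinates and draws inferences about use, geography,
genetic grouping and domestication status, down to archaeological
assemblages. This vignette is the methods account: what each stage
assumes, which parameters matter and why they default to what they do,
what the synthetic generator does and does not emulate, and where the
method's limits are.

## 1. Registration and the Fourier representation

Each pip contributes two closed contours (dorsal and lateral view), each
with two manually placed tip landmarks. Registration maps the two
landmarks onto Bookstein coordinates (−0.5, 0) and (0.5, 0) by the unique
similarity transform (translation, rotation, uniform scaling), rotates
the point sequence so the stalk-end landmark is first, and normalises
orientation to counterclockwise by signed area. This removes position,
size, rotation and starting point in one deterministic step, so the
Fourier stage needs no ellipse-based normalisation and all four
coefficients of the first harmonic stay informative. Conventions we had
to fix ourselves: which landmark maps to (−0.5, 0) (the stalk end — any
fixed convention works, but it must be fixed) and the counterclockwise
orientation (elliptical Fourier coefficients are orientation-dependent).

Contours are resampled to 300 equally spaced points by cumulative chord
length before the transform. 300 is far above the 4H + 2 points needed at
H = 5 harmonics and well past the density where coefficients stabilise
(the test suite checks 300- vs 1000-point agreement at 1e-3); raising it
only costs time.

The elliptical Fourier transform follows the Kuhl–Giardina formulation
for the chord-length parameterised contour: per harmonic n, coefficients
(aₙ, bₙ) of x(t) and (cₙ, dₙ) of y(t), with DC terms (a0, c0) computed as
the exact mean of the piecewise-linear series. One consequence worth
spelling out: the parameter is arc length, not the trigonometric angle,
so a 2:1 ellipse traced as (2cos t, sin t) does *not* have a1 = 2,
d1 = 1; its arc-length first harmonic is a1 ≈ 1.828, d1 ≈ 1.073, and the
tests pin the implementation to an independent numeric-integration
oracle rather than to the trigonometric intuition.

Harmonic power Pₙ = (aₙ² + bₙ² + cₙ² + dₙ²)/2 calibrates the truncation:
per view, the cumulative power ratios of all outlines are averaged and
the smallest H whose mean ratio reaches the threshold (default 0.95) is
chosen. Averaging per-outline ratios (rather than pooling raw power)
keeps large pips from dominating the calibration. On smooth,
near-elliptical outlines — including our synthetic shapes — the first
harmonic alone carries more than 95% of the power and the calibrated H
is 1. Real pip outlines are rougher, and the standard configuration for
this analysis is five harmonics per view; the pipeline therefore fixes
H = 5 by default (giving the 40-coefficient + length = 41-column feature
matrix) and treats the calibration as a reported diagnostic, with
`H = NULL` opting into the calibrated value.

Pip length is the tip-to-tip landmark distance times the outline's
mm-per-unit scale, computed before registration. Whether "length" should
instead be a bounding measure along the main axis is genuinely open; the
tip-to-tip distance is reproducible from the landmarks alone and is what
the generator round-trips.

## 2. Morphospace and group-mean trees

The PCA is centred but not scaled, computed on the full 41-column matrix
(coefficients plus length in mm) — the matrix that the discriminant
models also use, so the morphospace and the classifiers see the same
data. Including raw length means PC1 largely encodes size on data with
strong length contrasts; that is intentional, since the analysis targets
form rather than shape alone. A deterministic sign convention (largest
loading positive per axis) makes runs comparable.

For each cofactor, the tree stage averages features within each level,
standardises columns to zero mean and unit variance *across levels* (raw
length in millimetres would otherwise dominate the 41-variable
correlation), takes the correlation distance 1 − r between level means,
and clusters by UPGMA. Heights use the ultrametric depth convention
(merge distance / 2). Ties in the distance matrix break deterministically
by lexicographic label order.

Node robustness uses the multiscale bootstrap: at each resampling
proportion r in 0.5…1.4 (step 0.1), round(41·r) feature columns are
resampled with replacement B = 100 times, the tree is rebuilt, and BP_r
is the fraction of replicates containing the node's leaf set. The probit
transforms z_r = Φ⁻¹(1 − BP_r) are fitted by weighted least squares to
z(r) = v√r + c/√r with the variance-stabilised weights
B·φ(z_r)²/(BP_r(1 − BP_r)), and AU = 1 − Φ(v − c). Scales where BP is
exactly 0 or 1 carry no probit information and are excluded from the
fit; a node with fewer than two usable scales (typically one recovered
in every replicate) takes its clamped BP, bounded into
[1/(2B), 1 − 1/(2B)], as the AU value. The resampling unit is the
feature column — the standard choice when the objects being clustered
are group means over features; resampling pips before averaging is
available behind `unit = "pips"` for sensitivity checks.

## 3. Balanced discriminant ensembles

The classifier is linear discriminant analysis with a pooled within-class
covariance and equal priors. Equal priors are deliberate: every training
set is balanced by construction, and proportional priors would
re-introduce exactly the sample-size bias the scheme removes. If the
pooled covariance is numerically singular, a ridge of 1e-8·tr(S)/p is
added and flagged.

Unbalanced cofactors are handled by permutation: each of 100 permutations
samples the minimal group size from every class without replacement, fits
the LDA, and records leave-one-out cross-validated per-class accuracies
and the LOO confusion matrix. Leave-one-out refits use exact rank-one
downdates of the pooled scatter (Sherman–Morrison), which the tests pin
against brute-force refitting and against an independent reference
implementation to ~1e-8. The reported class accuracy is the median over
permutations; the confusion matrix is the per-cell median percentage,
rows renormalised to 100.

Chance is calibrated empirically: each permutation also fits a
shuffled-label null on the identical row draw, and a class is flagged
significant only when its median accuracy exceeds the *maximum* class
accuracy any null permutation achieved. Under the null the overall
accuracy behaves like Binomial(n, 1/k)/n; the tests verify this
calibration for k = 2, 4, 5, 8, 10 within three Monte-Carlo standard
errors, and LOOCV within each balanced subset is the cross-validation
unit throughout. Tree nodes get the same treatment as two-class problems
(node's classes against all others), giving the per-node cv accuracy
reported next to AU/BP.

## 4. Filtering and archaeological inference

New pips are classified by majority rule across the ensemble's models;
ties break by higher median posterior, then lexicographically, and are
logged. Two filtering statistics are tracked per pip: the median (over
models) posterior probability of its winning class, and the fraction of
models voting for that class. The filter curves report, per cut-off, the
accuracy among retained pips and the retention — the trade-off a user
buys into when filtering. The archaeological defaults are the two
standard cut-offs: median posterior ≥ 0.8 and vote fraction ≥ 0.5
(inclusive, so a pip attributed to its class exactly half the time is
kept).

Assemblage inference is two-stage: a wild/domesticated status ensemble
labels every pip by majority rule; wild-type pips are counted and
discarded; the cofactor ensembles then classify the survivors, with
proportions reported under no filtering and both cut-offs. Pip counts
are conserved across the stages by construction and asserted in tests.
Mean domesticated pip length per phase feeds a deliberately simple
berry-size call: nearest reference size class by absolute distance to
class median lengths. The size classes in the reference are compared by
one-tailed Wilcoxon rank tests (medium vs small, large vs small), exact
for combined samples up to 12 without ties, normal approximation with
continuity correction otherwise.

## 5. The synthetic generator

There is no public reference collection of registered two-view pip
outlines with cultivar metadata, so the package generates one with the
statistical structure the analysis assumes. Archetypes differ only in
interpretable parameters: first-harmonic axis ratio (elongation),
second-harmonic egg-shape asymmetry, third-harmonic stalk prominence,
and pip length. The defaults build one wild archetype (axis ratio 1.15,
short stalk, mean length 5.2 mm) and ten domesticated archetypes
crossing wine/table use (elongation 1.80/1.45; length 6.0/7.0 mm — table
pips longer, matching the reported direction) with five geographic
groups at stepped stalk/asymmetry offsets. A 4-level SNP-style and a
5-level SSR-style genetic grouping cover subsets of the use-by-geography
cells, leaving NA labels elsewhere, as in real reference collections.

Variation is hierarchical: cultivar offsets at sd 0.012 (first-harmonic
scale) within groups, pip noise at sd 0.004 within cultivars, both
decaying as 1/n across harmonics so high-frequency noise cannot
dominate the outline. The class offsets are at least three within-group
standard deviations apart, the regime in which the recovery properties
(every model's median accuracy above its null maximum) are the intended
outcome. Berry size classes shift cultivar length means by −0.8/0/+0.8
mm, producing the monotone small < medium < large association. Labels go
missing completely at random at 5%, and 5% of domesticated cultivars are
recorded as "mixed" use; the use model drops those rows.

Synthesised coefficient sets are inverted to 300-point outlines with
landmarks at the extremes along the first-harmonic major axis and the mm
scale set so tip-to-tip distance equals the drawn length. The generator
refuses configurations whose noise self-intersects more than 1% of
outlines. The bulk check uses the O(n) turning-number test (a simple
closed curve has winding ±1; coefficient noise that pinches the outline
adds a full turn); the exact O(n²) segment-intersection test validates
the archetypes and, in tests, the proxy itself.

What the generator does **not** emulate: raster images and contour
extraction error, operator landmark placement error, charring and
taphonomic deformation of archaeological pips, true varietal genetics,
and realistic within-class overlap structure. Passing recovery tests
therefore show the chain is correct and calibrated under its own
assumptions — not that real pip data are this separable; real class
accuracies are far below the near-perfect values the defaults produce.

## 6. Problem sizes and numerical choices

The shipped analyses run at a deliberately reduced scale chosen once:
the standard test/acceptance collection is 11 groups × 4 cultivars × 8
pips = 352 pips (two views each), with 100 permutations per model, B =
100 bootstrap replicates per scale, and two assemblages of 128 and 204
pips — minutes on one CPU. The structure, not the size, is what the
statistical machinery sees; all sizes scale through the configuration
objects.

Other numerical policies, in one place: degenerate contours (zero
perimeter, coincident landmarks) are errors, not warnings; bootstrap BP
values are clamped to [1/(2B), 1 − 1/(2B)] before the probit transform;
posterior softmax subtracts the row maximum for stability; filter-curve
accuracy over an empty retained set is NA, never 0; median aggregation
is used wherever the method reports medians, without rounding before
comparisons; and every stochastic stage (generation, permutation draws,
label shuffles, bootstrap) is driven by explicit integer seeds, making
identical-seed runs byte-identical — which the pipeline tests assert.

## 7. Known limitations

- The synthetic archetypes are smooth and near-elliptical; harmonic
  calibration on them selects H = 1, so the H = 5 default is a
  configuration choice, not a data-driven one, on synthetic input.
- AU p-values for nodes recovered in every replicate fall back to the
  clamped BP; their scale-curve information is genuinely zero and no
  extrapolation is attempted.
- The berry-size call is a nearest-median heuristic, not a fitted model;
  it inherits the reference collection's length distribution.
- LOOCV inside balanced subsets estimates the accuracy of models of
  that subset size; with very small minimal group sizes the estimates
  are noisy, and the ensembles refuse minimal sizes below 5.
- The wild/domesticated status model trains on synthetic archetypes
  here; applying the package to real material requires a real reference
  collection for that stage.
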