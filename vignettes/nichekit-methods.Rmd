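---
title: "Models and methods behind nichekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nichekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nichekit` implements a complete two-range climatic-niche comparison and
distribution-modelling workflow. This vignette is the package's account
of the underlying models, the tunable parameters, the numerical choices,
and what the synthetic validation does and does not demonstrate. The
functions themselves are the interface: every stage takes and returns
data frames (or the light `env_stack` raster container), so a study is a
pipe of ordinary calls, and `run_pipeline()` with a seeded configuration
list is the one-shot orchestration of all of them.

## Environmental space and occupancy grids

All niche comparisons happen in an environmental space built by a PCA of
the standardized background climates, pooled across the two ranges
(`fit_pca()`). Pooling is deliberate: the 2-D statistics need both
ranges on one common grid, and a pooled calibration is the standard
choice for that. Components are sign-fixed (largest-magnitude loading
positive) so results are reproducible across platforms.

`occupancy_grid()` turns occurrence and background scores on the first
two components into an `R` x `R` grid (default `R = 100`) spanning the
pooled background envelope plus a 5% margin. Gaussian kernel densities
are evaluated at cell centres with per-axis normal-reference (Silverman)
bandwidths computed from the occurrence scores (background availability
uses its own rule); the user can override the bandwidths. The corrected
occupancy is `z = (o/e) / max(o/e)` on cells with available environment,
the variant recommended for comparing ranges with different climate
availability; the uncorrected `o/max(o)` surface is kept alongside, and
both normalized forms (`Z`) are reported, since either may be wanted for
Schoener's D.

Three numerical guards matter here and are deliberate choices:

* kernel densities are flushed to exact zero below `1e-8` of their
  maximum, so "occupied" and "unoccupied" cells are well defined in
  floating point;
* background availability below `e_support = 1e-4` of its maximum is
  treated as absent. The `o/e` ratio is noise-dominated where both
  densities are vanishing, and without this cutoff a handful of fringe
  cells can dominate the corrected surface;
* for the niche-dynamics indices (below), a range's *occupied set* is
  the set of cells carrying the top 95% of its occurrence-density mass
  (`occupancy_quantile = 0.05`). Gaussian kernel tails otherwise extend
  4–5 bandwidths beyond the data and blanket the grid, which would force
  expansion and unfilling toward zero regardless of the data. Setting
  `occupancy_quantile = 0` restores the raw `z > 0` support.

## 2-D overlap statistics

Schoener's overlap is `D = 1 − 0.5 * sum(|Z1 − Z2|)` on the normalized
occupancies; 0 means disjoint niches, 1 identical ones. D is symmetric
and, on smooth niches, stable to grid refinement: doubling `R` while
halving the bandwidth moves D by less than 0.02 in the test suite.

The **equivalency test** asks whether the two occurrence sets are
interchangeable: the null distribution of D is built by pooling the
occurrence scores, re-splitting them at random into groups of the
original sizes, rebuilding the occupancy grids against the *fixed*
backgrounds and recomputing D. The **similarity test** asks whether the
observed overlap differs from what random placement of one niche within
its own background would give: the moving range's scores are translated
by a uniform random offset, toroidally wrapped within the shared grid
extent, and shifts that move more than half of the occurrence density
off that range's background support are rejected and redrawn. Both tests
report a divergence p-value (`P(null D ≤ observed D)`) and a
conservatism p-value (upper tail), using the +1-corrected permutation
formula `(count + 1)/(reps + 1)` with ties counted as extreme, so p lies
in (0, 1] and the smallest attainable value at the default 100
replicates is about 0.01.

The **niche dynamics** indices use the occupied sets `S_A`, `S_B`
(quantile-trimmed as above, optionally restricted to analogue
environments available in both backgrounds, the default):
expansion = share of B's occupancy in cells B uses but A does not;
stability = 1 − expansion; unfilling = share of A's occupancy in cells
A uses but B does not. The identity expansion + stability = 1 holds
exactly by construction.

## 3-D overlap: polyhedra and ellipsoids

The conservative 3-D niche is the convex polyhedron connecting the
extreme occurrence scores. The hull is built by an incremental algorithm
written for this package (no computational-geometry package is a
dependency), volumes come from a signed-tetrahedron sum, and the
directional overlap is the intersection volume as a percentage of each
niche. The intersection is computed exactly — vertex enumeration over
facet-plane triples followed by a per-face pyramid decomposition, which
is robust to the exactly coplanar vertex sets polytope faces produce —
whenever the two hulls together have at most 90 distinct facet planes;
beyond that the O(m³) enumeration is no longer worth it and a seeded
Monte-Carlo estimate (10⁶ points rejection-sampled in the smaller
hull's bounding box) is used and reported together with its standard
error. Occurrence clouds of a few hundred points typically have 40–60
facet planes per hull, so the exact route covers most real comparisons.

The probabilistic niche is a multivariate normal with unknown mean and
covariance. `posterior_niche()` draws from the conjugate
normal–inverse-Wishart posterior under the noninformative reference
prior: covariance ~ inverse-Wishart((n−1)S, n−1) and mean | covariance ~
normal(sample mean, covariance/n). The α-niche region of a draw is its
Mahalanobis ellipsoid at the chi-squared α quantile. `ellipsoid_overlap()`
pairs posterior draws of the two niches and, per pair, estimates the
probability that a draw from A lands in B's region by sampling `nprob`
points; the posterior sample of overlaps is summarized by its mean and
an equal-tailed 95% credible interval. The defaults (10,000 draws x
1,000 points) hold the Monte-Carlo contribution to the interval
endpoints near one percentage point; per-axis overlaps run the same
machinery in one dimension, where the closed normal-CDF form serves as
the test oracle. Overlap is directional by construction — a narrow niche
can sit wholly inside a broad one while the reverse overlap is small —
and both directions are reported, at α = 0.95 and 0.99.

## The maximum-entropy distribution model

The suitability model is the classical presence–background
maximum-entropy (Gibbs) model: features h(x) built from the predictors
(linear, quadratic, pairwise products, forward/reverse hinges and step
thresholds at 10 quantile knots per predictor, all min–max scaled to
[0, 1] on the calibration background), and coefficients maximizing the
mean presence score minus the log partition function over the
background, minus per-feature L1 penalties
`lambda_j = rm * tau(class_j, n) * sd_j / sqrt(n)`. The per-class
constants `tau` interpolate the canonical defaults of the family
(linear/quadratic 1 → 0.05 as n grows, products 2.2 → 0.05, hinge 0.5,
threshold 2 → 1); they are an approximation documented as such, with the
regularization multiplier `rm` as the single user-facing dial. The
problem is convex; an accelerated proximal-gradient solver with
backtracking runs to a 1e-6 stationarity (KKT) residual within 5,000
iterations and is deterministic, and the tests verify its optimum
against a brute-force grid search and the non-increasing L1 path in
`rm`. Ten knots per predictor is a desk-scale default (the original
implementation uses many more); it is configurable.

Prediction offers the raw probability (re-normalized over the
prediction region, summing to one) and the bounded cloglog transform
`1 − exp(−exp(H) · p_cal)` with `H` the calibration entropy and `p_cal`
the calibration-normalized probability — so a featureless model scores
`1 − e⁻¹ ≈ 0.632` everywhere. "No extrapolation" is implemented
strictly: cells with any predictor outside the calibration range are
masked (NA); clamping to the range boundary is available.

## Candidate calibration and selection

Candidates are the Cartesian grid of regularization multipliers
(default ladder 0.1–1 by 0.1, 2–6 by 1, 8, 10 — 17 values), all 31
non-empty feature-class subsets, and the predictor sets; one seeded
75/25 occurrence split is shared by every candidate. Per candidate:
partial ROC (AUC ratio restricted to sensitivity ≥ 0.95, against the
random diagonal over the same interval; 500 bootstrap half-resamples of
the test points; p = share of ratios ≤ 1), omission rate at the 5%
training threshold, and AICc from the raw-probability likelihood of
*all* occurrences with k = nonzero coefficients. A model is selected if
its partial ROC is significant, its omission rate is at most 5%, and
its AICc is within 2 of the minimum among candidates passing the first
two filters (the delta baseline can instead be taken over all
candidates). Two conventions worth stating: the AUC ratio equals 1
under random prediction (ratios meaningfully above 1 indicate signal;
descriptions placing "random" at 0 on a 0–2 scale conflict with this
standard convention and are not followed); and the omission threshold
is the order-statistic (type-1) quantile — the `ceiling(E·n)`-th
smallest training suitability — so at most an E share of training
presences falls strictly below it. Because the omission filter compares
an approximately unbiased estimate of E against E itself, roughly half
of all splits will push even a perfect model over the 5% line; this is
a property of the design, mitigated in practice by the size of the
candidate grid, and the test suite asserts selection behaviour across
several independent splits for that reason.

## Transfer, agreement and spread stages

`transfer()` refits the chosen model on bootstrap resamples of the
presences (30 replicates by default; resampling unit is the occurrence
record) and predicts each replicate on the scenario stack with the
no-extrapolation mask, reporting the cell-wise mean (median available)
and standard deviation. The mask depends only on the fixed calibration
background, so it is identical across replicates and propagates to the
summary. `agreement_map()` intersects two thresholded maps (default
0.5) and counts the common cells. `classify_spread()` compares local
and continental suitabilities at each occurrence: both high →
stabilizing; local only → adaptation; continental only → colonization;
neither → sink. A value exactly at the threshold counts as high (the
verbal definitions "above" and "less than" leave the boundary
unassigned; assigning it to the high side is the documented choice),
and occurrences on masked cells are reported as `unscored` with a
warning rather than silently dropped.

## The virtual-species generator

`make_landscape()` builds environmental layers as Gaussian white noise
smoothed with a Gaussian kernel whose standard deviation is the
autocorrelation range in map units (a kernel-smoothing construction
rather than a full Gaussian-process solve: only the statistical
structure matters at these scales), standardized per layer and linearly
mixed to a target inter-layer correlation matrix. `sample_occurrences()`
draws cells without replacement with probability proportional to a
Gaussian niche suitability `exp(−½ (x−μ)ᵀ Σ⁻¹ (x−μ))`, restricted to a
range mask, placing records at cell centres so per-pixel deduplication
downstream is a meaningful operation. `make_paleo_stack()` perturbs a
stack by per-layer constant shifts plus autocorrelated noise of
controlled per-cell standard deviation. `analytic_overlap()` and
`analytic_schoener_d()` supply the ground truths — the normal-CDF /
high-n Monte-Carlo niche-region overlap, and the brute-force density
integral of D on a fine grid — against which the estimators are tested.

The default two-range study (`default_config()`) mirrors the study
design the workflow is built for: 561 western and 201 eastern records
of one ecotype on a landscape split by a barrier, a 100 x 100 E-space
grid, 100 permutation replicates, 10,000 posterior draws at α = 0.95
and 0.99, E = 0.05, the 17 x 31 candidate grid, a 500-unit calibration
buffer, 30 transfer replicates and a 0.5 spread threshold.
`synth_demo_config()` scales the expensive stages down (99 permutation
replicates, 2,000 draws, a handful of candidates, 5 transfer
replicates) so the full pipeline runs in well under a minute; the test
suite uses still smaller instances (landscapes of 45–150 cells a side,
1,000–10,000 posterior draws, 50 coverage replicates), sizes chosen as
the smallest at which the statistical assertions have adequate power.

What the synthetic validation shows: the estimators recover known
overlap values (D within 0.05 of the analytic integral at 600 records;
95% credible intervals covering the true niche-region overlap in ≥ 90%
of replicates), the permutation tests hold their nominal size, and the
spread classification responds directionally to a planted niche shift.
What it does not show: robustness to spatial sampling bias, to
non-Gaussian or multimodal niches, to collinear predictor sets beyond
what PCA removes, or to the geographic dispersal constraints real
ranges carry — synthetic occurrences are an equilibrium sample of the
niche, which is exactly the assumption the real-data methods also make.

## Seeds and reproducibility

Every stochastic operation takes an explicit seed; `run_pipeline()`
derives per-stage seeds from the master seed by a fixed affine rule
(`(7919·seed + 104729·stage) mod 2³¹−1`), so a configuration reruns to
bit-identical tables. Distances are Euclidean in map units on projected
data and great-circle kilometres (spherical Earth, R = 6371 km) on
geographic data.

## Known limitations

The ESRI ASCII grid is the only raster format read or written (one
plain-text file per layer); GeoTIFF users should convert externally.
Hull overlap beyond three dimensions, minimum-volume enclosing
ellipsoids, kernel shapes other than Gaussian, categorical predictors,
and sampling-bias grids are out of scope. The per-class regularization
constants approximate, not replicate, the original maximum-entropy
implementation's tables, so coefficient-level agreement with that
program should not be expected even though the model family and the
selection machinery are the same.
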