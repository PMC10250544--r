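# nichekit

Climatic-niche comparison and species-distribution modelling for
two-range study designs, with a virtual-species simulator that makes the
whole workflow testable against analytic ground truth.

## The problem

When a species occupies two disjunct ranges — a native range and a
(possibly human-mediated) introduced range — the niche-conservatism
question is whether the two populations use the same climatic conditions,
and, if they largely do, where and when a source area could have existed.
Answering it takes a chain of analyses that are usually scattered across
several packages and a Java program: environmental-space ordination,
kernel-smoothed niche overlap with permutation inference,
three-dimensional volume and probabilistic niche-region overlap,
calibrated maximum-entropy distribution models transferred across climate
scenarios, and a spread-stage classification of the introduced
populations. `nichekit` implements that chain end to end, in R, behind
tidy data-frame interfaces, for ecologists and biogeographers working on
introduced or disjunct taxa.

Because real occurrence data for such studies are often not publicly
deposited, the package ships a first-class synthetic-data module:
landscapes with controlled spatial autocorrelation, virtual species with
known Gaussian niches, and two-range occurrence samples. Every estimator
in the package can therefore be validated against closed-form or
brute-force ground truth, and the test suite does exactly that.

## What it computes

**Environmental space (E-space).** A PCA of the pooled background
climates (`fit_pca()`), projection of occurrences and scenario stacks
onto its components (`project_espace()`, `espace_scores()`), and an
R x R kernel-density occupancy grid per range (`occupancy_grid()`):
occurrence density *o*, background availability *e*, corrected occupancy
*z* = (*o*/*e*)/max(*o*/*e*).

**2-D overlap.** Schoener's overlap
*D* = 1 − ½ Σ |*Z*₁ − *Z*₂| over grid cells (`schoener_d()`); the niche
**equivalency** permutation test (pool and re-split occurrences) and the
**similarity** background-randomization test (translate one niche within
its own background), each with divergence and conservatism one-sided
p-values using the +1-corrected permutation formula
(`equivalency_test()`, `similarity_test()`); and the
**expansion / stability / unfilling** niche-dynamics indices with
expansion + stability = 1 (`niche_dynamics()`). `overlap2d_table()`
returns the two-directional comparison as one tidy table.

**3-D overlap.** Convex-polyhedron niches with exact volumes and exact
(or Monte-Carlo, for very complex hulls) intersection volumes
(`hull_niche()`, `hull_overlap()`), and Bayesian ellipsoidal niche
regions: a normal–inverse-Wishart posterior over (mean, covariance)
(`posterior_niche()`) and the posterior distribution of the probability
that a draw from niche A falls inside niche B's α-probability ellipsoid,
with equal-tailed credible intervals, for the full PC set or single PCs
(`ellipsoid_overlap()`, `overlap3d_table()`).

**Distribution models.** An L1-regularized maximum-entropy
presence–background model with linear/quadratic/product/hinge/threshold
features (`build_features()`, `fit_maxent()`), raw and cloglog output
with a strict no-extrapolation mask (`predict()`); candidate-model
calibration over the 17-value regularization ladder x 31 feature-class
subsets x predictor sets (1581 candidates at the defaults), filtered by
partial-ROC significance, omission rate ≤ 5% and ΔAICc ≤ 2
(`candidate_grid()`, `evaluate_candidates()`, `select_models()`);
bootstrap-replicate transfer to alternative scenarios and cross-model
agreement maps (`transfer()`, `agreement_map()`); and the four-way
sink / stabilizing / adaptation / colonization spread classification at a
0.5 suitability threshold (`classify_spread()`).

`run_pipeline()` chains all stages from a single seeded configuration
(`default_config()`, `synth_demo_config()`) and writes tidy result
tables, ESRI ASCII rasters and a stage log.

## A worked example

Two ranges of one virtual ecotype, separated by a barrier, sampled from
the *same* Gaussian niche:

```r
library(nichekit)

land <- make_landscape(landscape_spec(80, 80, n_layers = 3,
                                      autocorr_range = 6, seed = 1))
xy    <- xy_from_cell(land, seq_len(n_cells(land)))
west  <- xy$x < 38; east <- xy$x > 42
sp    <- virtual_species(c(0.5, 0.5, 0), diag(0.36, 3), label = "ecotype")
occ_w <- sample_occurrences(sp, land, 300, west, seed = 2, range_label = "west")
occ_e <- sample_occurrences(sp, land, 150, east, seed = 3, range_label = "east")

pca <- fit_pca(land, west | east)
tidy(pca)
#>   component explained cumulative
#> 1 PC1           0.466      0.466
#> 2 PC2           0.289      0.754
#> 3 PC3           0.246      1

overlap2d_table(
  espace_scores(pca, occ_w, land)[, 1:2],
  espace_scores(pca, occ_e, land)[, 1:2],
  project_espace(pca, land$values[west, ])[, 1:2],
  project_espace(pca, land$values[east, ])[, 1:2],
  reps = 99, seed = 4, labels = c("west", "east"))
#>       d similarity_p_div similarity_p_con equivalency_p_div equivalency_p_con
#> 1 0.672                1             0.01              0.99              0.02
#> 2 0.672                1             0.01              0.99              0.02
#>   unfilling stability expansion
#> 1     0.283     0.982     0.018
#> 2     0.018     0.717     0.283
```

The two ranges share one niche, and the statistics say so: overlap
D = 0.672 is high for kernel-smoothed samples of 300 and 150 records;
the similarity test finds the niches more similar than random placement
within their backgrounds (conservatism p = 0.01, the smallest value 99
replicates can produce); the equivalency test finds no divergence
(p = 0.99); and the dynamics indices show almost no expansion in either
direction (0.018 / 0.283 — the larger west sample fills more of the
shared niche, which the east sample "unfills").

The ellipsoidal niche-region overlap in three dimensions agrees:

```r
ellipsoid_overlap(posterior_niche(espace_scores(pca, occ_w, land), 2000, seed = 5),
                  posterior_niche(espace_scores(pca, occ_e, land), 2000, seed = 6),
                  alpha = 0.95, seed = 7)
#> <overlap_posterior> alpha = 0.95: mean 69.2%, 95% CI [60.7, 77.2]%
```

i.e. a posterior-mean 69% of the western niche's probability mass lies
inside the eastern 95% niche region, with a credible interval reflecting
the finite samples.

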