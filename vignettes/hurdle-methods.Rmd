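---
title: "Methods: semi-continuous hurdle analysis of single-cell expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-continuous hurdle analysis of single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scHurdle)
```

# The data and the model

Targeted single-cell expression panels produce, per cell and gene, a count
that is log-transformed as `lcount = log2(count + 1)`. Across cells the log
counts for a gene are typically bimodal: a background ("noise") cluster near
zero and a positive ("signal") cluster at a gene-specific level. `scHurdle`
treats the two modes with a two-part (hurdle) model: a logistic regression
for whether a gene clears the detection hurdle, and a Gaussian linear model
for the positive values, fitted conditional on positivity. Because the
likelihood factorises, the joint log-likelihood is the exact sum of the two
parts and likelihood-ratio statistics add across parts, with chi-square
degrees of freedom summed accordingly.

Assumptions worth stating explicitly:

* given the covariates, the positive values are Gaussian on the log2 scale
  with constant variance within a gene;
* the detection indicator and the positive value are conditionally
  independent given covariates (this is what lets the likelihood split);
* the cellular detection rate `ngeneson` (fraction of panel genes detected
  in a cell) is a technical nuisance, not a biological signal. It is
  included as an unpenalized/untested covariate everywhere.

# Thresholding

Positive log counts from all genes are pooled and fitted with a
two-component Gaussian mixture by EM ("omnibus" fit). The omnibus
guarantees both clusters are represented before any per-gene fit is
attempted. Per-gene fits are maximum a posteriori under a conjugate prior
built from the omnibus by moment matching:

* cluster means: Gaussian priors centred at the omnibus means with
  pseudo-observation weight `kappa * Nt` (defaults 3 and 5, so weight 15);
* cluster variances: inverse-gamma priors whose mode equals the omnibus
  variance with the same effective weight (`shape = w/2`,
  `scale = (shape + 1) * var`);
* mixing proportion: Beta(5, 5), i.e. prior mass worth 10 observations,
  giving the closed-form MAP update `(n_signal + 4)/(n + 8)` at each
  E-step.

The per-gene optimiser is Expectation Conditional Maximization: given
responsibilities, the means, then the variances, then the mixing proportion
are maximised in turn. Convergence is declared when the relative change in
the log-posterior objective falls below `1e-8` (at most 500 iterations;
non-convergence is flagged, never silently accepted). The omnibus EM is
initialised by a deterministic 2-means pass started from the data extremes,
so results are reproducible without a random seed.

The upstream framework this design follows used a flow-cytometry mixture
engine whose exact prior-construction formulas are not public in printed
form; the Normal-Inverse-Gamma + Beta construction above is this package's
own, documented stand-in with the same stated hyperparameters (`kappa`,
`Nt`, Beta(5,5)). Per-gene thresholds may therefore differ slightly from
other implementations in the hard-to-classify middle region.

Observations with posterior noise probability strictly greater than 0.5 are
set to zero; ties at exactly 0.5 are kept. Zero inputs (count 0) are
assigned to the background unconditionally and never enter the mixture
fits — a zero count cannot be signal, and a point mass at zero would
distort the Gaussian fit. If a gene's MAP fit is effectively unimodal
(cluster means closer than half the pooled standard deviation), the gene
falls back to the omnibus-derived threshold rather than accepting an
arbitrary split of a unimodal distribution.

# Normalization

Plates are grouped into experimental batches (run dates). Within each
batch, preliminary signal/noise labels come from the thresholding machinery
applied per batch. The additive model
`lcount ~ gene + cluster + plate:cluster` is then fitted by backfitting
(Gauss-Seidel on the normal equations, iterated to `1e-10`, so the
converged solution is the least-squares fit), and each record is corrected
by the deviation of its plate-by-cluster intercept from that cluster's
across-plate mean. Only locations move: within-plate, within-cluster
differences are preserved exactly, and no variance harmonisation is
attempted. A plate missing a cluster contributes no correction for that
cluster; a single-plate batch is returned unchanged.

Whether gene main effects should enter the alignment regression at all is a
genuinely open design point; we use a shared gene term per batch (the
minimal model consistent with subtracting plate-specific cluster
intercepts). A per-gene alignment would also be defensible but estimates
many more parameters from few observations per cell.

After alignment, each gene is translated so its minimum normalized value is
exactly zero (well-defined as long as no gene is expressed in every cell),
and thresholding is re-run jointly on the normalized data.

# Quality control

Cells with no expressed gene are removed unconditionally. Two robust
z-scores are computed per remaining cell — the proportion of genes
expressed, and the mean expression over expressed genes only — using
median/MAD with the 1.4826 normal-consistency constant (falling back to the
standard deviation with a warning when the MAD is zero). A cell is removed
when at least `n_outlier = 2` of the two criteria exceed their cutoffs
(`sigma_proportion = 2`, `sigma_continuous = 5`): with the defaults, both
must fire. The "mean positive expression" uses expressed genes only; using
all genes would conflate the two criteria.

Genes are then filtered on the cells that survived: a gene is kept only if
detected in at least 1% of cells in *every* cell line. Cell filtering
precedes gene filtering, matching the order the criteria are defined in.

# Tests of cycle effects

Factors use sum-to-zero coding, so cell-line effects, cycle effects, and
the interaction matrix all satisfy the zero-sum constraints and every test
is invariant to the choice of reference level (asserted numerically in the
test suite). Two contrasts are exposed:

* **differential expression** (default): cycle main effects are dropped
  from a model with cell line and `ngeneson` but no interactions; 2 + 2 = 4
  degrees of freedom;
* **deviance analysis**: the full model adds the line-by-cycle interaction
  and the reduced model drops all cycle terms.

The logistic part is fitted by iteratively reweighted least squares to a
gradient norm below `1e-8`; on (quasi-)separation a fixed ridge of `1e-6`
on non-intercept coefficients keeps the optimum finite, and the fit is
flagged. The Gaussian part is closed-form with the ML (n-denominator)
variance so that deviances are comparable across nested models. Genes
expressed in all cells (or none) contribute only the available component,
with the degrees of freedom reduced and a per-gene flag; for highly
expressed genes the discrete part carries little information anyway, and
this degradation costs at most the unused degrees of freedom.

The union-intersection alternative rejects when either component test
rejects at `alpha / 2`. The component level is a real design choice: at
`alpha` per component the union can exceed the nominal size, so the
size-controlling Bonferroni split is the default and the component level is
exposed as an argument. Per-gene p-values are Bonferroni-adjusted across
the panel and reported also as `-log10(p)`.

Nested-model statistics are clamped at zero if they come out negative
beyond `1e-6` (a numerical impossibility for exact nested optima, flagged
when it happens).

# Deviance partitioning

The cycle deviance ratio is `(D0 - D1)/D0` with `D1`, `D0` the deviances of
the full and cycle-free models. The package computes this ratio on the GLM
deviance scale — binomial deviance for the discrete part (the saturated
log-likelihood of a Bernoulli fit is zero) plus the residual sum of squares
for the continuous part. On this scale the ratio is exactly the coefficient
of determination of the cycle terms when the data are fully continuous,
which is the property that justifies reading it as "proportion of
variability explained by cycle". Computing the same ratio from
`-2 * loglik` (which for the Gaussian part involves `n log RSS`) does not
reduce to R² and mixes scales less interpretably; both quantities are kept
on the fitted object (`deviance` and `deviance_glm`), and only the ratio
uses the GLM scale.

The deflated ratio divides by the largest ratio in the panel (or a supplied
reference), reading the top gene as fully cycle-regulated and every other
gene's ratio as a fraction of that upper bound.

# Co-expression networks

Each gene is regressed on all other genes' thresholded values — logistic
for its detection indicator, linear for its positive values — with an L1
penalty on the gene coefficients only; `ngeneson`, cell line, and
optionally cycle and the line-by-cycle interaction are unpenalized.
Predictors are standardized inside each fit so one penalty, shared across
all gene-wise regressions of a component, is meaningful; a single shared
penalty per component is calibrated so the union-symmetrized network hits a
fixed edge budget. When the edge count jumps past the budget between grid
points, edges entering at the next grid point are ranked by absolute
coefficient magnitude and the top ones are kept, so the budget is met
exactly whenever attainable. Edge counts are checked for monotonicity along
the path on every calibration run. The discrete and continuous networks
are combined by union, with provenance recording edges found by both.

The continuous neighborhood regression restricts rows to cells where the
*target* gene is positive but uses other genes' full thresholded values
(zeros included) as predictors — the conditioning in the model is on the
target's positivity only. The per-cell detection rate is the global one; a
leave-one-gene-out recomputation per regression would change it by at most
1/G and is not performed.

"Raw" comparison networks are ordinary penalized linear regressions on
un-thresholded log counts with identical covariate handling; they exist to
quantify what ignoring bimodality does to network estimates. Peak-time
concordance of a network is the fraction of edges joining genes annotated
with the same peak phase; continuous 0-100 peak-time annotations are binned
into the three assayable phases by thirds, with configurable boundaries
since no canonical boundary exists — concordance percentages depend on this
choice. No consistency theory is claimed for the network procedure, and no
stability selection or bootstrap edge confidence is provided.

# The synthetic generator

`simulate_dataset()` draws from exactly the model the fitting code assumes:
per-gene baseline detection frequency (uniform on [0.56, 0.9] by default,
matching typical targeted-panel interquartile ranges), signal means uniform
on [6, 11] log2 units with unit-variance Gaussian positive values,
background draws from a normal with location 0.5 and scale 0.5 truncated at
zero (reproducing the near-zero noise mode without negative counts),
sum-to-zero cell-line and cycle effects on both parts, a per-cell
efficiency shift loading on both the log-odds (loading 1) and the positive
mean (loading 0.75; calibrated once so the detection-rate/log-sum
correlation exceeds 0.8 under the defaults, the qualitative association
such panels show), additive plate intercepts (sd 0.5), and optional planted
conditional dependencies between genes. Values are rounded through
`count = round(2^value - 1)` so the emitted table carries genuine count
artefacts.

What the generator does *not* emulate: molecular amplification kinetics
(efficiency is a phenomenological additive shift), heavy-tailed or skewed
positive clusters, gene-specific variances, dropout that depends on
expression level within the positive cluster, and empty wells or doublets.
Passing tests on this generator therefore demonstrates correctness of the
estimators under the model's own assumptions — parameter recovery,
calibration, and identifiability — not robustness to the many ways real
panels violate them.

# Problem sizes and numerical conventions

The test suite calibrates the combined test on 1000 simulated null genes at
900 cells each, measures estimator bias over 200 replicate datasets at 900
cells, and exercises networks on panels of 10-12 genes with planted
structure; the acceptance script runs the full pipeline at the study scale
of 253 genes and 936 cells (3 lines x 3 phases x 104 cells, 10 plates)
plus a 500-gene null panel. These sizes give Monte-Carlo error comfortably
inside the asserted bounds while keeping a full run to minutes on one core.

Numerical conventions collected in one place: EM/ECM relative tolerance
`1e-8`, at most 500 iterations; IRLS gradient tolerance `1e-8`, ridge
`1e-6` on separation; backfitting tolerance `1e-10`; variance floors
`1e-6` (omnibus) and `1e-8` (per-gene MAP); covariance decomposition uses
the population (divisor n) convention so the within/between identity is
exact; ties in peak-phase estimation resolve to the earlier phase
(G0/G1 < S < G2/M) with a flag.

# Known limitations

* The prior construction is a moment-matched stand-in (see Thresholding);
  thresholds for borderline observations can differ from implementations
  built on other mixture engines.
* The union network combination is a pragmatic rule, not an optimal
  combination of discrete and continuous evidence.
* Mixed models (random plate or batch effects) are out of scope; plates
  enter only through the location alignment.
* The generator's defaults describe a well-behaved panel; none of the
  acceptance properties speak to mis-specified noise distributions.
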