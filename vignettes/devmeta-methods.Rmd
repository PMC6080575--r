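---
title: "Stage-evolving meta-network decomposition: models, choices, limits"
author: "devmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-evolving meta-network decomposition: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devmeta)
```

This vignette documents the models implemented in `devmeta`, the
assumptions behind them, the numerical choices made where the design was
genuinely open, and what the synthetic-data experiments do and do not
demonstrate.

## 1. From morphometry tables to developmental networks

The input is one subject-by-ROI table per age. Confounds — by default
gender and each subject's overall mean thickness — are removed per ROI by
ordinary least squares (`regress_confounds`); residuals are exactly
zero-mean and uncorrelated with every numeric confound, and the residual
networks are invariant to affine rescaling of a confound. Categorical
confounds are dummy-coded against a first-level reference. A covariate
that is constant within an age group is absorbed by the intercept and
dropped (the regression then reduces to mean removal); genuine collinearity
among varying confounds raises an error naming the offending covariate.
Missing values are rejected rather than imputed: imputation would inject a
model we have no basis to choose.

`build_correlation_network` stores the absolute Pearson correlation of
each ROI pair across subjects, with a zero diagonal: the sign of a
structural correlation is not interpretable as presence/absence of a
connection, so magnitude is the weight, and self-correlation carries no
information. Networks are kept fully weighted; no thresholding or
binarization is applied. Vectorization takes the strict upper triangle in
row-major order, giving `M = N(N-1)/2` connections per network; the
round trip through `devectorize_network` is exact. Matrix inputs may be
asymmetric up to `1e-8` (floating-point I/O noise) and are then
symmetrized by averaging; anything worse is rejected.

## 2. Developmental stages by consensus clustering

For each candidate stage count `G`, `consensus_cluster` runs k-means on
the `tau` network columns 100 times (the default) with randomized
initialization, forms the co-clustering consensus matrix, and scores it
with the dispersion coefficient

$$\rho(C) = \frac{1}{\tau^2}\sum_{i,j} 4\,(C_{ij}-\tfrac12)^2,$$

the standard consensus-clustering consistency index: 1 when all runs
agree, near 0 when co-clustering is a coin flip. `select_stage_partition`
keeps, among candidates attaining the maximal dispersion, the **largest**
`G` (finest granularity), and takes the final labels from the
best-inertia run at that `G`.

Two choices deserve comment.

* **Seeding.** Runs are initialized with k-means++ (distance-weighted
  random seeding) rather than uniformly random points. Uniform seeding
  leaves Hartigan–Wong in degenerate local optima (a singleton cluster
  plus two merged ones) in a substantial fraction of runs even when the
  stage clusters are strongly separated, which caps the dispersion
  coefficient well below 1 for perfectly clean data; k-means++ is the
  modern default in the major clustering libraries and makes consensus
  unanimity achievable exactly when the data warrant it. The seeding is
  still random, so consensus across runs remains informative.
* **No temporal constraint.** Stage contiguity is *not* enforced; when the
  chosen partition is non-contiguous a warning is logged. Contiguity
  emerging from an unconstrained clustering is itself evidence that the
  network sequence changes smoothly.

## 3. The factorization

With stages fixed, the staged stack `X = [X^1 ... X^G]` is modelled
stage-wise as `X^t ≈ U^t V^tT`: `p` meta-networks whose `M`-vector
connection patterns (columns of `U^t`, non-negative, near-orthonormal) may
take a different state in each stage, sharing one `tau x p` trajectory
matrix `V` whose stage blocks are selected by 0/1 mask matrices. The
objective combines stage-wise reconstruction, a ridge `lambda/2 ||V||_F^2`
(the non-negative surrogate of a nuclear-norm penalty on the
reconstruction, given the orthonormality of `U^t`), and quadratic
smoothness penalties on chain graphs linking consecutive stages
(weight `alpha`) and consecutive time points (weight `beta`). Chains are
the natural topology for a regularizer motivated by slow temporal change;
nothing in the machinery depends on that choice and the graphs are built
in one replaceable function (`build_smoothness_graphs`).

### Updates and the monotonicity safeguard

`update_V` is the classic graph-regularized multiplicative update and is
monotone in the objective as-is. `update_U` applies, per stage,

$$U^t \leftarrow U^t \odot
\frac{X^tV^t + \alpha\sum_k W_U(t,k)\,U^k}
     {U^t\,(V^{tT}X^{tT}U^t) + \alpha\,d_t\,U^t + \varepsilon},$$

whose reconstruction part is the orthogonality-enforcing form: at
`alpha = 0` it is the classic orthogonal-NMF update, an exact
factorization with orthonormal states is a fixed point, and the
denominator's Gram term continuously pulls the states toward the Stiefel
manifold. The smoothness part uses the graph-Laplacian degree split
(`d_t = sum_k W_U(t,k)`), the standard stable treatment; the
"cross-Gram" alternative `U^t U^{tT} U^k` is equivalent on the orthogonal
manifold but diverges from random non-negative starts, so it is not used.

Orthogonality-enforcing multiplicative steps are *not* monotone in the
plain objective: from a random start the column scales of `U` and `V`
fight each other in a slowly damped two-cycle, and a full step can
transiently raise `J` by tens of percent. Inside `dmd_fit` the `U` sweep
therefore applies the multiplier with exponent `1/2` — which corrects a
pure scale error in one step instead of oscillating, and preserves the
update's fixed points exactly, since a multiplier of 1 stays 1 under any
exponent — and backs off by further halvings whenever the stage-wise
coordinate objective would still increase, keeping the state unchanged as
a last resort. The recorded objective trace is thus non-increasing by
construction, while on structured data the backtracking essentially never
engages beyond the initial iterations and the dynamics are those of the
plain damped update. The one-step operations exported as `update_U` and
`update_V` remain the pure formulas.

Each restart draws `U, V` uniformly on `(0, 1]`, normalizes `U`'s columns,
and scales `V` by the global least-squares constant so restarts start at
comparable objective values; `n_init = 100` restarts (the default) keep
the least-cost fit. Convergence is declared at relative objective change
below `1e-6` or 1000 iterations; the denominator guard is `1e-12`. No
post-hoc rescaling of `U` or `V` is applied after convergence; instead the
per-stage **orthogonality gap** `||U^tT U^t - I||_F` is reported as a
diagnostic. On converged noiseless planted runs the off-diagonal part of
the Gram matrix (pattern overlap, the quantity the constraint is meant to
suppress) stays below 0.1, while the diagonal equilibrates near but not
exactly at 1 — the ridge on `V` trades scale against the soft constraint —
so the full gap is typically 0.2–0.4 rather than the sub-0.1 one would see
with hard renormalization.

### Choosing the number of meta-networks

`compute_mtd` is the minimal Euclidean distance between L2-normalized
trajectory columns; normalization makes the criterion comparable across
`p`, and ties in `select_num_dms` break toward the smallest `p`
(parsimony). On fitted factorizations the curve drops sharply once `p`
exceeds the planted component count, because extra components duplicate a
trajectory; that drop is the reliable signature of the true `p`. The
*rising* branch below the true `p` — reported for real developmental
networks, where coarse fits split a dominant global mode into components
with nearly identical time courses — does **not** occur on planted models
with disjoint supports: there, an underfitted least-cost factorization
merges components, and merged trajectory sets are never less separated
than the closest planted pair, so the curve is flat-to-decreasing up to
the true `p` and the literal arg-max rule favours small `p`. Users of the
planted generator should read the MTD curve's elbow, not only its
maximum; on real data both signals can be present.

## 4. Characteristic connections

Per meta-network `r`, the normalized divergence of connection `m` is the
sum over ordered stage pairs of `|U_r(m,k) - U_r(m,l)|` divided by the
mean strength across stages (ordered pairs count each difference twice;
only the ranking matters). Connections with zero mean strength get an
infinite divergence — they can never be "stable" — rather than raising an
error. Stable connections are the top 2% (of `M`, configurable) by
ascending divergence after excluding connections whose mean strength falls
below the adaptive threshold `delta_r`, the root mean square of all `G*M`
entries of the stage-state matrix; exclusion happens *before* the
truncation, so the report can be shorter than the budget. Ties in
divergence break toward higher mean strength.

Rapidly-changing connections are scored per adjacent stage transition: the
per-connection change `Delta u` must share its sign with the
stage-contribution change `Delta v-bar` (the change in the within-stage
mean of the trajectory), and the largest such changes (the same 2%
convention, configurable) are reported as increased or decreased sets. A
transition with exactly zero contribution change yields an empty selection
rather than a guessed sign.

## 5. Split-half reproducibility

`split_half` places the 1st, 3rd, 5th, … time points (odd ages, when ages
are consecutive integers) in half A and the rest in half B. Each half
inherits the full-sequence stage partition restricted to its time points —
this isolates factorization reproducibility from clustering variance —
with re-estimation available behind a flag; a stage emptied by the split
is merged into its chronological neighbour with a warning. Components of
the two independently fitted halves are matched by the Hungarian
algorithm on cosine similarity between stacked stage-state vectors (a
meta-network is its whole evolution, one `M*G` vector), and trajectory
columns are compared under the same permutation. Cosine similarity judges
orientation, not magnitude, which suits halves offset by one time step.
The assignment solver is an O(p^3) Kuhn–Munkres implementation, verified
against exhaustive permutation search for `p <= 6` in the test suite.

Note that half sequences have small stages (two time points per stage
under the default planted geometry), so `p` can exceed the smallest stage
size; the fit warns about the rank-deficient stage blocks but proceeds,
since the shared trajectory matrix and the smoothness coupling still
identify the states. For the same reason the component count is validated
only against `M` and `tau`.

## 6. The synthetic generator

`generate_planted_networks` emulates the generative structure the
factorization assumes: per stage, `p` meta-networks with **disjoint edge
supports** (hence exactly orthonormal planted states, making recovery
well-posed), a fraction `drift` of each support swapped at every stage
transition (smooth evolution of the patterns), trajectories that are
smooth logistic plateau curves — decaying, rising, unimodal, flat — with
transitions centred on the planted stage boundaries, and additive
Gaussian noise truncated at zero (a half-normal alternative is exposed).
Defaults: `N = 40`, `tau = 12`, `G = 3`, `p = 3`, `drift = 0.1`,
`noise_sd = 0.02`, support size `floor(0.02 * M)` = the top-2% budget
used by the stable-connection report.

Three geometry choices matter and are deliberate:

* **Plateau trajectories.** Within-stage loadings are nearly constant and
  jump across boundaries; this is what "stage clusters" means, and it
  makes the between-stage column separation (about 1.7 in Euclidean norm
  at defaults) dominate both the within-stage spread and the noise floor
  (`sqrt(2 M) * noise_sd ≈ 0.8`), so consensus clustering is unanimous.
  The between-stage mean gap exceeds five noise standard deviations by a
  wide margin.
* **Near-vanishing curves.** Non-flat trajectories span `[0.05, 1.2]`, so
  each meta-network is effectively "off" somewhere. Strictly positive
  trajectories bounded away from zero make the non-negative factorization
  non-identifiable — rotated mixtures fit equally well — and no optimizer
  can then recover the planted patterns; the soft orthogonality constraint
  resolves the remaining ambiguity.
* **A broad background component.** When `p >= 4`, the flat-trajectory
  component receives an 8x larger support, emulating the dominant shared
  covariance of real structural correlation networks (the stable,
  short-range homotopic background).

`generate_thickness_tables` emulates the upstream inputs: per-age
subject-by-ROI tables driven by shared latent factors (ROIs in a group
correlate), a gender offset, a per-subject global scale, and measurement
noise, with `gender` and `mean_thickness` covariates attached — the
default 45 subjects per age matches a typical youngest-age sample size.

What passing tests on these data do **not** show: real cortical-thickness
networks have overlapping (not disjoint) meta-network supports,
heavier-tailed and spatially correlated noise, hub/small-world topology,
and subjects scanned repeatedly across ages; the generator makes no claim
about any of those, and recovery rates reported by the test suite are
upper bounds on what comparable real data would allow.

## 7. Problem sizes and budgets used by the test suite

The suite exercises the full pipeline at the generator defaults (780
connections, 12 time points). Recovery experiments use 10 random seeds
with 5 restarts and up to 800 iterations per fit; optimizer property
checks use 50 random instances with at most 30 connections and 8 time
points; consensus experiments use 100 runs per candidate stage count.
These sizes give stable pass/fail behaviour at a few minutes of total
runtime; all of them scale linearly in `M`, so larger problems are a
matter of patience, not design.

## 8. Known limitations

* The factorization is cross-sectional: it models the sequence of group
  networks, not within-subject longitudinal trajectories.
* The orthogonality constraint is soft; reports should always be read
  together with the orthogonality-gap diagnostic.
* Model-order selection by the MTD maximum is unreliable on data whose
  components have disjoint supports (see Section 3); inspect the curve.
* Hyperparameters `lambda`, `alpha`, `beta` default to 0.1; recovery on
  planted data is robust across an order of magnitude around that value,
  but no automatic tuning is provided beyond grid exposure in the
  selection helpers.
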