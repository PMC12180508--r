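---
title: "Comparing symptom correlation networks between clinical groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing symptom correlation networks between clinical groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`psynetcomp` compares the inter-scale correlation architecture of
psychopathology between two clinical groups. This vignette is the package's
own account of the statistical machinery: the models and their assumptions,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method leaves room.

## Standardization model

Raw questionnaire scores are not comparable across instruments, so each case
group's scores are expressed relative to its *own* age-matched control group,
never to pooled controls — the two case groups may differ in age structure,
and group-specific referencing is what makes their z-scores comparable on a
common impairment scale. Two referencing modes exist per instrument:

- **mean/SD**: `z = (x − mean_ctrl) / sd_ctrl`;
- **age-residual**: a linear model `score ~ age` is fitted in the controls
  alone and `z = (x − prediction at the case subject's age) / rse`, with
  `rse` the control residual standard error on `n − 2` degrees of freedom
  (the usual unbiased regression scale).

The choice is made by an age-by-group interaction screen: for each scale of
an instrument, `score ~ age + group + age:group` is fitted over the combined
case + control subjects, and the instrument switches to age-residual
referencing when any of its scales has an interaction p below `alpha_screen`.
The screen is instrument-level because missingness is instrument-level (a
subject fills in an entire questionnaire or none of it), so all scales of an
instrument should share one reference model. `alpha_screen` defaults to 0.05
uncorrected — a deliberately sensitive screen, since the cost of switching
(slightly wider reference bands) is lower than the cost of missing a real
age-dependent reference; a per-scale mode is available via
`standardization_methods(per_scale = TRUE)`.

Scales on which a higher raw score means *better* functioning (a polarity
flag of −1 in the scale metadata, e.g. prosocial or motor-competence scales)
are sign-inverted after z-scoring so that higher always means greater
impairment.

Per-scale group effect sizes are the OLS coefficient of a 0/1 group indicator
in a model over case + matched-control standardized scores — equivalently the
difference of standardized group means, in control-SD units.

## Networks, degree, fingerprints

Each group's architecture is the `p × p` Pearson correlation matrix of its
standardized scores, computed over *pairwise-complete* observations by
default: instrument coverage differs across subjects, and pairwise deletion
maximizes the data behind each edge (listwise deletion is available as a
toggle). The minimum pairwise sample size per edge is `min_n = 10`;
correlations below that are refused rather than silently computed, because
tiny-sample correlations are unstable enough to dominate network statistics.

Off-diagonal correlations are Fisher-Z transformed, `z = atanh(r)`, which
stabilizes variance and makes edge values approximately additive targets for
subtraction and averaging. The diagonal (r = 1, infinite z) is masked and
excluded from every downstream statistic — this is why nodal degree averages
`p − 1` entries per row, and why fingerprint correlations use `p − 1`-length
rows with the self entry removed: including a constant, infinite self term
would be undefined and, were it finite, would bias every row correlation
toward 1.

Nodal degree is the off-diagonal row mean of the Z matrix; congruence is the
Pearson correlation of the two groups' degree vectors across scales.
Fingerprint divergence for scale *i* is `1 − cor(Z_A[i, −i], Z_B[i, −i])`,
ranging 0 (identical profile) to 2 (anti-correlated profile).

### Deming regression

Whether the degree-vs-degree scatter deviates from the identity line is
tested with Deming regression, the errors-in-both-variables fit whose slope is

$$\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
\sqrt{(s_{yy}-\lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}}.$$

Both axes are sample estimates with comparable noise, so ordinary least
squares (which attributes all error to y) would bias the slope toward zero
and make the result depend on which group is x. The error-variance ratio is
fixed at λ = 1 (orthogonal regression): the two degree vectors are estimated
from samples of broadly similar size with the same estimator, and no
information supports an unequal ratio. Standard errors are leave-one-out
jackknife — distribution-light and consistent with common Deming
implementations — with two-sided t tests (`n − 2` df) of slope vs 1 and
intercept vs 0. On an exactly collinear configuration the jackknife SE is 0
and the p-value degenerates to 0 or 1 according to whether the estimate
equals the null value.

## Permutation inference

Every p-value in the pipeline is an empirical permutation p. The null is
built by shuffling case-group labels across all case subjects while each
subject *keeps its own control-referenced z-scores*: re-standardizing under
relabeling is not possible, because controls are matched to a specific case
group. For each permutation both pseudo-groups' networks are rebuilt from
the score rows and every registered statistic is re-evaluated, so all tests
share one stream (`n_perm = 10000` by default) and are mutually consistent.

The p-value is `#{|null| ≥ |observed|} / n_perm`, two-sided on absolute
values, with ties counting *against* rejection (conservative). This plain
count can return an exact 0; an add-one smoothing option
(`(count+1)/(n_perm+1)`) exists behind a flag, off by default, because the
unsmoothed count is the conventional definition even though exact-zero
p-values are statistically awkward.

A permutation that drops any scale pair below `min_n` pairwise-complete
observations in either pseudo-group is redrawn (missingness patterns travel
with subjects), with a hard cap of `10 × n_perm` draws. Multiplicity
correction is Bonferroni: over the `p` scales for degree tests (threshold
`.05/p`), and over the `K(K+1)/2` unique blocks for block tests. Fingerprint
tests report nominal p-values as the primary column (profile divergence is
screened per scale, with edge-level follow-up as the confirmatory step) with
the Bonferroni column alongside.

## Edge-distribution comparison

The `p(p−1)/2` unique Fisher-Z edges of each group are compared as
distributions: absolute mean difference (permutation p), two-sample
Kolmogorov–Smirnov distance `D = sup |ECDF_A − ECDF_B|` with the p-value
taken from the *permutation* stream (the asymptotic `ks.test` p is logged
alongside for reference but edges are not independent observations, so the
asymptotic null is not trusted), and Pearson kurtosis `b2 = m4/m2²` with
biased (1/n) moments — the non-excess convention on which a normal
distribution scores 3 and leptokurtic means > 3. Kurtosis is reported
descriptively, without a significance test.

## The weighted stochastic block model

Coordinated group differences — sets of scale pairs whose coupling shifts
together — are found by clustering the delta matrix `D = Z_A − Z_B` (positive
cells: stronger coupling in group A) with a Gaussian WSBM:

$$g_i \sim \mathrm{Cat}(\pi), \qquad
x_{ij} \mid g_i = r, g_j = s \;\sim\; N(\mu_{rs}, \sigma^2),\quad i<j.$$

Each unordered pair contributes once; the diagonal is excluded entirely.
Because block *means* are modeled for every cluster pair, the WSBM detects
assortative and non-assortative (e.g. core–periphery) structure alike, which
matters for a delta matrix whose interesting blocks are often off-diagonal.
A single shared σ² is the default (block-pair-specific variances are
available behind `per_block_variance = TRUE`; they add K(K+1)/2 − 1
parameters that are rarely identifiable at p ≈ 50).

Fitting is variational EM with a mean-field posterior over node labels:

- **E-step**: node responsibilities are updated *one node at a time* by
  exact coordinate ascent. Batch updates of all nodes can oscillate;
  sequential updates guarantee the evidence lower bound never decreases,
  a property the test suite asserts to 1e−8 relative tolerance.
- **M-step**: closed-form weighted ML for `π`, `μ`, `σ²`.
- **Initialization**: first restart from spectral clustering (k-means on the
  top-|eigenvalue| eigenvectors of the weight matrix), remaining restarts
  (10 by default) from random labels — EM here is multimodal and the
  spectral start alone can sit in a shallow basin.
- **Degeneracies**: σ² is floored at 1e−10 so that noiseless
  planted-partition input (zero residual variance at the optimum) stays
  finite; a cluster whose total responsibility falls below 1e−6 is pruned
  and the model refit at the reduced K; hard labels are the posterior
  argmax with ties broken toward the lowest cluster index (deterministic).

The returned `μ` is recomputed at the hard labels, so block means equal the
brute-force per-block sample means exactly. The number of clusters is chosen
over `k_range = 1:10` by the integrated classification likelihood

$$\mathrm{ICL}(K) = \log p(x, \hat g) -
\tfrac12\Big(\tfrac{K(K+1)}{2} + 1\Big)\log\frac{p(p-1)}{2} -
\tfrac12 (K-1)\log p,$$

the completed-data log-likelihood at the hard assignment minus the standard
Gaussian-SBM penalties for edge parameters and mixing proportions. The search
range 1..10 comfortably brackets the handful of clusters that ~50-node
batteries support.

Block inference holds the observed partition *fixed*: each permutation
rebuilds both networks, forms the null delta matrix, and computes null block
means for the same edge sets. Refitting the WSBM per permutation would test
a different (data-dependent) partition each time and answer a different
question; fixing the partition tests whether the observed blocks' mean
deltas are extreme for those edge sets. A within-cluster block of a
single-member cluster has no edges and is reported as missing rather than
invented.

As a complementary view, `per_group_wsbm()` clusters each group's own Z
matrix separately; partitions are compared by cross-tabulation and adjusted
Rand index.

## The synthetic-cohort generator

No cohort of this kind is publicly deposited, so the generator is the test
bed. It is a cluster-structured factor model: subject *s* in group *g* draws
latent cluster factors `u ~ MVN(0, Φ_g)` and scores

$$x_{js} = \delta_{jg} + b_{inst(j)}(age_s - \overline{age}) +
\lambda_j u_{c(j)} + \varepsilon_{js},\qquad
\varepsilon_{js} \sim N(0, \sigma_j^2),$$

with ages uniform on 5–25 years and missingness MCAR at *instrument*
granularity — a subject misses a whole questionnaire or none of it,
mirroring age-applicability-driven missingness in real batteries. The
implied population correlation
`λ_j λ_k Φ_{c(j)c(k)} / √((λ_j²+σ_j²)(λ_k²+σ_k²))` is verified against
sample correlations at n = 10⁵ in the tests.

Presets fix the study conditions used throughout the test suite:

- `preset_null()` — p = 20 scales in 4 clusters, 60/60 case subjects with
  60/60 controls, one shared Φ so the case groups are exchangeable: the
  calibration condition. Loadings vary across scales (0.4–0.95) so that
  population nodal degrees are heterogeneous, as in real batteries where
  summary scales couple far more strongly than narrow ones; with constant
  loadings degree congruence would be undefined noise.
- `preset_planted_delta(effect, blocks)` — constant loadings (0.8, noise SD
  0.6) so a planted inter-cluster difference is uniform within its block;
  the two groups' Φ entries are moved apart symmetrically on the atanh
  scale so the *population* delta equals `effect` exactly in the planted
  cells and 0 elsewhere. If the shift breaks positive semidefiniteness the
  matrices are repaired by eigenvalue clipping and rescaling to unit
  diagonal, and the achieved (post-repair) effect is recorded.
- `preset_rewired_scale()` — one scale couples to a different home cluster
  in each group (its own singleton factor, correlated 0.8 with cluster 1 in
  group A and cluster 3 in group B): a pure fingerprint effect.
- `preset_paperlike()` — 53 scales from 9 instruments in 6 clusters, group
  sizes 102/64 cases with 74/60 controls, instrument completeness drawn in
  [0.65, 0.98], per-instrument age slopes, per-scale case shifts, two
  inverted-polarity scales, and Φ_A/Φ_B differing in three inter-cluster
  cells.

What the generator does **not** emulate: real instruments' skewness, floor
and ceiling effects, ordinal scoring, rater effects, or non-MCAR
missingness. Passing tests therefore demonstrate that the *statistical
machinery* is calibrated and powerful under a Gaussian factor world, not
that any specific clinical finding generalizes; with skewed or censored
scores the Pearson edges themselves change meaning, which is a property of
the method, not of this implementation.

## Test problem sizes

The suite's simulation scales are package choices balancing Monte-Carlo
error against run length: calibration uses 200 replicate null cohorts with
500 permutations each, testing each of the five permutation tests' type-I
error against the 95% binomial interval around α = .05 for 200 trials
(pooling per-scale rejections within a replicate first, which is
conservative); WSBM recovery uses 20 seeds per planted K ∈ {2, 3, 4} at
p = 24 (noiseless, exact recovery required) and 20 ICL-selection runs at
p = 40 with block-mean separation 3σ (≥ 80% required); end-to-end power uses
50 replicate cohorts at 150 subjects per case group (planted 0.4-z block
flagged, and rewired scale top-ranked by fingerprint divergence, each in
≥ 80%).

## Numerical details in one place

- Symmetry checks on matrix input: tolerance 1e−12.
- Fisher Z requires |r| < 1; an exact ±1 off-diagonal is an error naming the
  pair (inside the permutation engine, correlations are clamped to
  1 − 1e−12 in magnitude — degenerate permutations of continuous data are
  measure-zero but floating point is not).
- ELBO convergence: relative change below 1e−8; maximum 200 EM iterations;
  non-convergence in all restarts returns the best solution with a flag
  rather than an error.
- Variational responsibilities, mixing proportions and σ² are floored
  (1e−6 cluster mass for pruning, 1e−12 for π, 1e−10 for σ²).
- Edge ordering everywhere is the row-major upper triangle
  (1,2), (1,3), …, (1,p), (2,3), …, so vectors align across modules by
  construction.
- All randomness flows from explicit seeds (`synth_spec$seed`,
  `permutation_plan$seed`, WSBM `seed`); identical seeds give byte-identical
  outputs, which the tests assert at run level.

## Known limitations

- Permutation inference assumes exchangeability of case subjects under the
  null *after* group-specific standardization; finite control samples make
  the two groups' reference parameters differ slightly, a second-order
  effect the calibration tests bound but do not eliminate.
- Pairwise-complete correlation matrices are not guaranteed positive
  semidefinite; none of the statistics used here require PSD input, but
  eigen-decomposition-based extensions would.
- The WSBM's shared-variance Gaussian emission treats edge weights as
  conditionally independent given the partition, ignoring the correlation
  among edges that share a node; the permutation null accounts for this at
  test time, but ICL's penalties do not, so the selected K should be read
  as a parsimony choice rather than an inferential statement.
- Deming jackknife SEs assume approximately independent points; degree
  values share underlying subjects, so the slope test is approximate (the
  permutation tests, which re-use the subjects, are the primary inference).
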