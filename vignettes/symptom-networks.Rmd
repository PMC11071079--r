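---
title: "Estimating and stress-testing MHT symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and stress-testing MHT symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhtnet)
```

## The instrument and its decision rules

The MHT is a 100-item yes/no questionnaire scored 0/1. Eight content
subscales (labelled MHT1–MHT8: learning anxiety, social anxiety,
loneliness tendency, self-blame tendency, allergy tendency, physical
symptoms, horror tendency, impulsive tendency) are summed per participant;
a separate 10-item lie scale screens for socially desirable responding and
never enters the total. The published decision rules are encoded directly:

* protocols with any missing answer are removed first (listwise deletion,
  no imputation), then protocols with a lie score of 7–10;
* a subscale score of 8 or more flags a clear problem tendency, 3 or less
  no tendency;
* totals of 0–55 are graded *normal*, 56–64 *poor*, and 65 or more
  *severe*. The upper boundary is deliberately resolved as severe ≥ 65:
  prevalence counts in this literature treat 65 as part of the severe
  group, so the poor band is exactly 56–64.

The authentic item-to-subscale key is proprietary and not printed in the
screening literature; `mht_default_spec()` therefore ships a documented
stand-in layout (contiguous blocks of 15, 10, 10, 10, 10, 15, 10, 10
content items, lie items 91–100, matching the long learning-anxiety and
physical-symptoms scales of the real instrument) and
`mht_instrument_spec()` accepts the real key when the user holds it. All
scoring, exclusion and flagging logic is key-agnostic.

Descriptive statistics use the sample SD (n−1) and Fisher moment
coefficients (skewness $g_1 = m_3/m_2^{3/2}$, excess kurtosis
$g_2 = m_4/m_2^2 - 3$, population central moments); excess kurtosis is the
convention under which typical MHT samples show mildly platykurtic
subscale distributions (negative values). Constant columns yield `NA`
skew/kurtosis rather than `NaN`.

## The network model

Subscale scores are modelled as a Gaussian graphical model: an undirected
network whose edge weights are partial correlations between two symptoms
controlling for all remaining ones,
$\rho_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}$ for precision
matrix $K = \Sigma^{-1}$. Estimating all $p(p-1)/2$ edges from moderate
samples overfits, so $K$ is estimated by the graphical lasso, maximizing

$$\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \neq j} |\kappa_{ij}|$$

by block coordinate descent (compiled; diagonal unpenalized; tolerance
$10^{-6}$ on the maximum parameter change, at most 10,000 sweeps, with a
duality-gap estimate reported on the rare non-convergence). Absent edges
are *exact* zeros produced by the penalty — no post-hoc thresholding.

The penalty is selected on a log-spaced 100-point grid from
$\lambda_{\max}$ (the largest absolute off-diagonal correlation, where the
model is empty) down to $0.01\,\lambda_{\max}$, by minimizing
$\mathrm{EBIC} = -2\ell + E\log n + 4E\gamma\log p$ with $\gamma = 0.5$,
the standard conservative choice for symptom networks. EBIC ties break
toward the larger penalty, i.e. the sparser, more interpretable model.
Pearson correlation of the subscale sums is the default input (Spearman is
available for ordinal robustness; an indefinite rank-based matrix is
projected to the nearest PSD correlation matrix and the smoothing
recorded). Two numerical details worth knowing: the grid endpoints are
pinned exactly to $\lambda_{\max}$ and $0.01\lambda_{\max}$ because
`exp(log(x))` can undershoot by one ulp and manufacture a spurious
$10^{-17}$ edge at the grid head; and glasso solution sparsity patterns
are *not* nested along the path, so single edges occasionally drop out as
$\lambda$ decreases — the package asserts the monotone trend, not strict
edge-count monotonicity.

## Centrality and predictability

Strength $s_i = \sum_j |w_{ij}|$ and expected influence
$ei_i = \sum_j w_{ij}$ summarize direct connectedness (they coincide when
no incident edge is negative). Closeness and betweenness use the symptom-
network convention of edge length $1/|w_{ij}|$; closeness is
$(p-1)/\sum_j d_{ij}$, set to 0 for any node with an unreachable peer so
the index stays bounded (a harmonic variant is available), and betweenness
gives fractional credit across tied shortest paths. Z-scores standardize
each index across the $p$ nodes with the population (n-denominator) SD;
a constant index z-scores to all zeros with a warning.

Predictability is computed as the ordinary least-squares $R^2$ of each
node on all remaining nodes. The mixed-effects nodewise approach used
elsewhere in this literature reduces to exactly this quantity for a single
cross-sectional sample under a Gaussian approximation; for bounded integer
scores the linear-Gaussian $R^2$ is a mild approximation, and the package
validates it against the closed-form Gaussian conditional variance
$R^2_i = 1 - 1/(\kappa_{ii}\sigma_{ii})$ on synthetic data.

## Accuracy and stability diagnostics

Edge accuracy uses a nonparametric bootstrap: participants are resampled
with replacement at the original $n$ and the *entire* estimation pipeline
(correlation, glasso path, EBIC selection) is re-run per replicate —
2000 replicates by default for edge CIs. Confidence intervals are
empirical type-7 quantile intervals; difference tests declare two edges
(or two nodes' centralities) distinct when the bootstrap interval of their
difference excludes zero. Replicate failures are logged and skipped, with
a hard error above 5%.

Centrality stability uses the case-dropping bootstrap: for each drop
proportion (default grid 0.05–0.75 in steps of 0.05) participants are
subsampled without replacement and the pipeline re-run (default 1000
subsamples per proportion). The CS coefficient is the largest tested
proportion at which the 5th percentile of correlations between subsample
and full-sample statistics still reaches 0.7; below 0.25 the statistic is
considered unstable, above 0.5 good. The package follows this definition
literally (largest qualifying proportion, 0 if none); degenerate
zero-variance statistic vectors count as correlation 0, which biases CS
*downwards* for empty networks — the conservative direction. Note that a
0.05-step grid can only produce CS values on that grid; published CS
values on other grids (e.g. 0.67) are not representable, so comparisons
should be made at grid resolution.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated, mirroring a typical senior-high-school MHT sample:

* **Truth.** `make_precision_matrix()` draws a sparse symmetric precision
  matrix: default 8 nodes, edge density 0.6 (17 of 28 pairs), absolute
  partial correlations 0.05–0.35, one negative edge — the shape of
  published MHT networks (dense, almost all positive, strongest edges
  ≈ 0.3). Positive definiteness is guaranteed by diagonal inflation plus
  rescaling to unit diagonal; the implied partial correlations are the
  recorded ground truth.
* **Marginals.** `default_marginals()` fixes per-subscale support maxima
  (15 for the two long scales, 10 otherwise), means 3.3–8.9 and SDs
  2.4–3.6 — the range reported for this population. Each node is
  discretized through a *beta-binomial* quantile map: plain binomial
  marginals cannot reach the observed overdispersion (an SD of 3.6 on a
  0–15 scale), while the beta-binomial matches both target mean and SD on
  the bounded integer support.
* **Copula.** Latent scores are multivariate normal with the truth's
  correlation structure; the monotone quantile map preserves latent ranks
  exactly. Lie scores are drawn independently (binomial 0–10), so
  exclusion logic is testable orthogonally to network structure; the
  item-level generator drives independent Bernoulli items from each
  subscale's latent propensity and can inject exact numbers of incomplete
  and lie-invalid rows.

What the generator does **not** emulate: item-level dependence beyond the
subscale propensity (no 2PL/graded-response structure), demographic
covariate effects, and — importantly — the discretization perturbs Pearson
correlations non-uniformly, so the observed-scale partial correlations can
deviate from the latent truth by up to ≈ 0.06 for unlucky truth draws.
Passing recovery tests therefore demonstrate correctness of the estimation
machinery under a realistic bounded-ordinal regime, not that ±0.05
recovery is guaranteed for every possible network; on the package's
default fixture the recovery error is ≈ 0.04 for edges and ≈ 0.02 for
predictability at n = 5000.

## Problem sizes and test design

The validation suite scales simulation sizes to what the checks need:
moment and scoring oracles at n ≤ 625; independence and recovery checks at
n = 5000 (sampling error $3/\sqrt{n} \approx 0.042$ frames the ±0.05
tolerances); CS behaviour over 10 seeds with 40 subsamples per proportion
(enough for a 5th-percentile estimate); difference-test level over 20
seeds with 100 bootstrap replicates each (the smallest B for which 2.5%
quantiles are meaningful). Production defaults remain B = 2000 (edge CIs)
and B = 1000 (case-dropping), both overridable via `estimation_config()`
and `pipeline_config()`.

## Known limitations

* Cross-sectional GGMs say nothing about direction or causality.
* Pearson input on bounded ordinal scores attenuates associations;
  polychoric/mixed models are out of scope by design.
* The default instrument key is a documented stand-in; authentic-key
  results require `mht_instrument_spec()` with the real mapping.
* CS coefficients are only defined on the tested proportion grid, and the
  literal "largest qualifying proportion" rule can differ from
  implementations requiring all smaller proportions to qualify when the
  correlation profile is non-monotone.
```{r session}
sessionInfo()
```
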