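# mhtnet

Symptom-network analysis of the **Middle School Student Mental Health Test
(MHT)** — a 100-item yes/no screening questionnaire for Chinese secondary
school students with eight content subscales (learning anxiety, social
anxiety, loneliness tendency, self-blame tendency, allergy/oversensitivity
tendency, physical symptoms, horror tendency, impulsive tendency) and a
lie (validity) scale.

The package covers the full analysis pipeline used in contemporary
psychometric network studies:

1. **Scoring and validity exclusion.** Items are scored 0/1 and summed per
   subscale; protocols with missing answers are removed first, then
   protocols with a lie score in 7–10. Totals are graded
   normal (≤ 55) / poor (56–64) / severe (≥ 65), and subscale scores ≥ 8
   flag a clear problem tendency.
2. **Network estimation.** The eight subscale scores are modelled as a
   Gaussian graphical model: nodes are symptoms, edges are partial
   correlations controlling for all other nodes,
   ρ<sub>ij</sub> = −κ<sub>ij</sub>/√(κ<sub>ii</sub>κ<sub>jj</sub>) from
   the precision matrix K. A sparse K is estimated with the graphical
   lasso, maximizing log det K − tr(SK) − λΣ<sub>i≠j</sub>|κ<sub>ij</sub>|
   over a 100-point log-spaced λ grid, with the penalty chosen by the
   extended Bayesian information criterion
   EBIC = −2ℓ + E log n + 4Eγ log p (γ = 0.5).
3. **Centrality and predictability.** Strength Σ|w<sub>ij</sub>|, expected
   influence Σw<sub>ij</sub>, closeness and betweenness over 1/|w| edge
   lengths (raw and z-scored), plus node predictability — the R² of each
   node regressed on all others.
4. **Accuracy and stability.** Nonparametric bootstrap edge-weight
   confidence intervals and difference tests, and case-dropping subsample
   correlation-stability (CS) coefficients: the largest fraction of
   participants that can be dropped while subsample centralities still
   correlate ≥ 0.7 with the full-sample values with 95% certainty
   (≥ 0.25 acceptable, ≥ 0.5 good).

Because raw survey data of this kind are rarely deposited, the package
ships a **synthetic-data generator** with known ground truth: a sparse SPD
precision matrix defines the true network, a Gaussian copula with
beta-binomial marginal quantile maps produces realistic bounded integer
subscale scores (and optionally item-level 0/1 responses with injected
missingness and lie-invalid protocols), so every stage — scoring,
exclusion, estimation, centrality, stability — can be validated end to end.

## Worked example

```r
library(mhtnet)
truth <- make_precision_matrix(8, seed = 1)        # ground-truth network
sim   <- simulate_subscale_scores(truth, n = 625, seed = 1)
net   <- estimate_network(sim$scores)
net
#> symptom network: 8 nodes, 17/28 edges (glasso lambda=0.02648, EBIC gamma=0.5, pearson, n=625)
#>   weight range [0.042, 0.366], 0 negative

centrality_table(net, sim$scores)[, c("node", "strength",
                                      "expected_influence_z", "predictability")]
#>   node strength expected_influence_z predictability
#> 1 MHT1    1.003                1.632          0.357
#> 2 MHT2    0.577               -0.547          0.216
#> 3 MHT3    0.464               -1.128          0.168
#> 4 MHT4    0.860                0.900          0.338
#> ...
```

The network recovered 17 of 28 possible edges (the true density of the
default fixture), the strongest edge MHT1–MHT6 at 0.366, and MHT1 has the
highest expected influence (z = 1.63): with these synthetic ground-truth
weights, learning anxiety is the most interconnected symptom, and about
17–37% of each node's variance is explained by its neighbours at n = 625.

For a one-shot run of every stage (exclusion report, descriptives, edge
CIs, difference matrices, CS coefficients, layout data, manifest):

```r
bundle <- run_pipeline(pipeline_config(synthetic = list(n = 625), seed = 1,
                                       outdir = "report"))
```

or from a shell: `inst/cli/symptomnet run --config cfg.yaml`.

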