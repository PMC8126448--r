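# metabodnm

Paired metabolomic network analysis and dynamic-network-marker (DNM)
detection for two-condition, within-subject designs.

## The problem

Short physiological perturbations — a 24-hour fast, for example — shift a
plasma metabolome in two ways: individual metabolites change abundance, and
the *co-variation structure* between metabolites re-arranges. The second
signal can precede an overt state shift: dynamic-network-marker theory
predicts that, ahead of a transition, a group of molecules emerges whose
members become tightly co-regulated, gain network centrality, and show
rising between-individual stochasticity. `metabodnm` implements the full
analysis chain for paired designs of the kind used in small-cohort animal
physiology (hundreds of metabolites, ~8 subjects, two conditions), together
with a synthetic data generator with planted ground truth so that every
stage can be validated end to end.

## The methods

For metabolite $g$ and subject $i$, with paired log2 differences
$d_{gi}$ and $s_g^2 = \mathrm{Var}_i(d_{gi})$:

* **Moderated paired t** — variances shrunk toward a scaled
  inverse-$\chi^2$ prior, $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$,
  $t_g = \bar d_g / \sqrt{\tilde s_g^2/n}$ on $d_0 + d$ df, with
  $(d_0, s_0^2)$ moment-matched from $\log s_g^2$; Benjamini–Hochberg
  adjustment, increase/decrease calls at adjusted $P < 0.05$.
* **Multilevel PLS-DA** — two-component NIPALS PLS on within-subject
  deviations with a ±1 condition response; 95% normal score ellipses.
* **HOSVD** — SVD of each mode unfolding of the metabolite × individual ×
  condition log2 tensor; per-metabolite contributions to total variance.
* **MI networks** — Gaussian-copula (rank) mutual information per
  condition, $\mathrm{MI} = -\tfrac12\log(1-r^2)$ with
  $r = 2\sin(\pi r_s/6)$, pruned by the ARACNE data-processing-inequality
  rule.
* **Topology** — leading-eigenvector modularity partitions ($Q$ and
  per-module contributions), per-component eigenvector centrality,
  cross-condition module matching by Jaccard overlap.
* **DNM ranking** — every non-singleton fasted module ranked on mean
  centrality, mean paired centrality change, mean fasted CV and modularity
  contribution; composite = mean rank; module GLMs
  (F-tests of `log(centrality) ~ module`, `Δcentrality ~ module`,
  `log(CV) ~ module`) with a significance gate on fasted CV heterogeneity.

See `vignettes/metabodnm-methods.Rmd` for the model details, parameter
choices and limitations.

## Worked example

Simulate a strong-effect dataset with a planted DNM module and run the full
pipeline:

```r
library(metabodnm)
demo <- demo_pipeline(seed = 2, config = strong_effect_config(seed = 2))
print(demo$analysis)
#> dnm_analysis
#>   322 metabolites x 8 individuals x 2 conditions
#>   differential expression: decrease=79, increase=85, no_change=158
#>   PLS-DA explained X-variance: 89.6%, 1.4%
#>   modularity: Q_post = 0.538 (16 modules), Q_fasted = 0.597 (7 modules)
#>   DNM: module 4
print(demo$analysis$dnm)
#> dnm_report
#>   selected DNM module: 4
#>   centrality ~ module:        F(6,315) = 49.25, p = 1.63e-42
#>   delta centrality ~ module:  F(6,315) = 48.18, p = 8.56e-42
#>   log fasted CV ~ module:     F(6,315) = 16.10, p = 3.71e-16
#>   log baseline CV ~ module:   F(14,306) = 1.56, p = 0.0905
str(demo$recovery)
#> List of 4
#>  $ de_sensitivity: num 0.994
#>  $ de_fdp        : num 0.0305
#>  $ module_ari    : num 0.11
#>  $ dnm_hit       : logi TRUE
```

Reading the output: 164 of 322 metabolites are called differentially
expressed (99.4% of the planted effects recovered, false discovery
proportion 3%); the two conditions separate cleanly in the multilevel
PLS-DA; the fasted network partitions into 7 modules at modularity
Q ≈ 0.60; module 4 is selected as the DNM — it leads all four rank
criteria, fasted CV heterogeneity between modules is highly significant
(F = 16.1) while baseline heterogeneity is not (p = 0.09), and the module
coincides with the planted one (`dnm_hit = TRUE`).

File-based workflows use `write_dataset()` / `load_dataset()` /
`run_pipeline(data_dir=, out_dir=)`, or the command-line wrapper:

```sh
Rscript inst/scripts/metabodnm.R simulate --seed 1 --out data/
Rscript inst/scripts/metabodnm.R run --data data/ --out results/
Rscript inst/scripts/metabodnm.R dnm-report results/
```

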