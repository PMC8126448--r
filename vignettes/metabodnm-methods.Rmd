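---
title: "Methods: paired metabolomic networks and dynamic network markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired metabolomic networks and dynamic network markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`metabodnm` analyses a paired two-condition metabolomics experiment: each of
a small number of subjects (the motivating design has 8) is profiled once in
a baseline, post-absorptive state and once after a short fast, over a few
hundred metabolite intensities. The package chains six stages:

1. paired differential expression with empirical-Bayes variance moderation,
2. multilevel PLS-DA,
3. higher-order SVD (HOSVD) of the metabolite x individual x condition tensor,
4. per-condition mutual-information (MI) networks with
   data-processing-inequality (DPI) pruning,
5. leading-eigenvector modularity partitioning and eigenvector centrality,
6. dynamic-network-marker (DNM) candidate ranking.

A synthetic paired-metabolome generator with planted ground truth
(`generate_paired_metabolome()`) backs every stage with recovery tests.

# Differential expression

Intensities are strictly positive and analysed on the log2 scale, taken once
(inputs are stored on the natural scale; zero intensities are an error, not
imputed). For metabolite $g$ and subject $i$ the within-subject difference is
$d_{gi} = \log_2 x_{gi,\mathrm{fasted}} - \log_2 x_{gi,\mathrm{post}}$, and
the log2 fold change is $\bar d_g$. The per-metabolite variances $s_g^2$ of
the $d_{gi}$ are shrunk toward a scaled inverse-$\chi^2$ prior with
hyperparameters $(d_0, s_0^2)$ fitted by moment-matching the mean and
variance of $\log s_g^2$ (Newton inversion of the trigamma function). The
moderated statistic is

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
   t_g = \frac{\bar d_g}{\sqrt{\tilde s_g^2 / n}}, $$

with $d = n - 1$ residual df and a two-sided $t_{d_0 + d}$ reference. With
$d_0 = 0$ this is exactly the classical paired $t$; with $d_0 = \infty$
(returned when the spread of $\log s_g^2$ does not exceed its
$\chi^2$ sampling floor) all metabolites share $s_0^2$, estimated from the
geometric mean of the $s_g^2$. P values are Benjamini–Hochberg adjusted
(`stats::p.adjust`); a metabolite is called an increase/decrease when its
adjusted P is strictly below $\alpha = 0.05$ and the fold change is
positive/negative. Volcano output flags metabolites outside the 2.5%/97.5%
fold-change quantiles (type-7 linear interpolation).

# Multilevel PLS-DA

The paired design is handled by the standard multilevel decomposition:
each sample's log2 profile minus its subject's mean over the two conditions
(`multilevel_center()`), so the supervised analysis acts on within-subject
variation only (per-subject sums are exactly zero). A two-component NIPALS
PLS is fit against a single ±1 dummy response (+1 = fasted). Reported
loadings are the unit-norm weight vectors; explained variance is the
fraction of the deviation matrix's total sum of squares captured by each
component's rank-1 approximation — PLS maximises covariance with the
response, not X-variance, so these fractions need not decrease.
Reproducibility conventions: component signs are fixed so the fasted
centroid is positive (component 1, and component 2 when distinguishable).
Group ellipses are 95% bivariate-normal ellipses from each group's score
covariance; the ellipse definition was an open choice and the
normal-quantile form was adopted as the most common convention.

# HOSVD

The (by default metabolite-centred) log2 tensor is decomposed by one SVD
per mode unfolding; the orthonormal factor matrices and the core tensor
reconstruct the input exactly when untruncated (relative Frobenius error at
machine precision; the acceptance suite checks $<10^{-10}$). Per-metabolite
contribution scores are the row norms of the metabolite-mode factor weighted
by the mode-1 singular values — the Euclidean contribution of each
metabolite to the tensor's total (centred) variance. Centering is exposed as
a flag because the analysis it imitates did not state it; metabolite
centering is the default so that contributions reflect variance, not
baseline abundance.

# MI networks and DPI pruning

Association between metabolites within one condition is measured by mutual
information across individuals. The default estimator is the Gaussian-copula
(rank) MI: the Spearman correlation $r_s$ is converted to the implied
Gaussian correlation $r = 2\sin(\pi r_s/6)$ and
$\mathrm{MI} = -\tfrac12\log(1-r^2)$ nats. With only 8 individuals a binned
plug-in estimator (retained as `binned_empirical`, equal-frequency
$\lceil\sqrt n\rceil$ bins) is extremely noisy; the rank-Gaussian form is
the defensible small-$n$ choice, and both are exactly invariant under
strictly monotone per-metabolite transforms. $r^2$ is clamped at
$1 - 10^{-12}$, so exactly rank-concordant pairs get a large finite weight
(about 13.8 nats) rather than an infinite one.

Indirect edges are removed ARACNE-style by the data-processing inequality:
edge $(i,j)$ is dropped when some third metabolite $k$ has
$\min(\mathrm{MI}_{ik}, \mathrm{MI}_{jk}) - \varepsilon > \mathrm{MI}_{ij}$
(default $\varepsilon = 0$). All decisions are evaluated against the
original MI matrix simultaneously, which makes pruning independent of node
order. Full conditional-MI estimation is out of scope.

At $n = 8$ the Spearman correlation is a coarse statistic: pairs that are
exactly rank-concordant saturate at the clamp, and the weighted network is
dominated by whichever metabolites reach that saturation. This is a genuine
small-sample property of rank-based networks, not an artifact of the
implementation, and it shapes both the generator design and the validation
configuration discussed below.

# Modularity, centrality, module matching

Partitioning uses the leading-eigenvector method on the weighted modularity
matrix $B = W - kk^\top/2m$: recursive spectral bisection by the sign of the
leading eigenvector of the generalised modularity matrix, accepting a split
only when it increases $Q$. Determinism conventions: eigenvector signs are
fixed so the first nonzero entry is positive, entries exactly zero join the
positive group, isolated nodes become singleton modules, and labels are
contiguous from 1 in order of first node appearance. Per-module
contributions $q_m = e_{mm} - a_m^2$ sum to $Q$. No Kernighan–Lin
fine-tuning is applied; on the small planted test graphs the spectral
optimum coincides with the exhaustive-search optimum, which is what the
test suite asserts.

Eigenvector centrality is the Perron vector of the weighted adjacency,
computed per connected component and max-normalised to 1 within each
analysed component (so every component with at least one edge carries a 1);
isolated nodes get 0. When the two stated conventions for disconnected
graphs conflicted — per-component maxima versus a single dominant-component
scale — the per-component form was chosen because the downstream
module GLMs compare within-network contrasts and a vector of near-zeros off
the dominant component would make the log transform degenerate everywhere.
Zeros are floored at $10^{-12}$ before any log-GLM.

Fasted modules are matched to baseline modules by maximal Jaccard overlap
(ties to the smaller baseline label), with a per-metabolite
membership-change flag.

# DNM identification

A forming DNM module is expected to show, ahead of a physiological state
shift: high eigenvector centrality, rising centrality (paired change),
elevated between-individual coefficient of variation
($\mathrm{CV} = \mathrm{sd}/\mathrm{mean}$ of natural-scale intensity, the
stochasticity proxy), and a leading modularity contribution. Each
non-singleton fasted module is ranked on those four statistics (rank 1 =
largest) and the composite score is the mean of the four ranks; the best
composite wins, with ties broken by larger size then smaller label. The
composite mean-rank rule is this package's own operationalisation of that
narrative — no formal selection rule exists in the literature it follows —
and is deliberately simple and auditable: the report carries all four ranks
plus module sizes and $q$ contributions so the selection can be re-derived
by eye.

Three one-way module GLMs accompany the report (log centrality, paired
centrality change, log fasted CV), plus the baseline log CV GLM as an
advisory check: weak baseline CV heterogeneity corroborates a forming DNM
but does not veto one. Singleton modules are excluded from all four GLMs
(with $N$ responses and $k$ retained modules the F df are
$(k-1,\ N'-k)$). If the fasted CV GLM is not significant at the 0.05 gate
the report is flagged "no DNM detected": stochasticity heterogeneity is a
requirement, not just a ranking input. Back-transformed per-module
predictions use the naive $\exp$ (no half-variance correction; the
correction choice was open and the naive form keeps predictions at the
geometric group means).

# The synthetic generator

Log2 intensities are simulated as

$$ y_{gic} = \mu_g + b_i + \delta_g \mathbf{1}[c = \mathrm{fasted}]
   + \sqrt{\rho_{m(g),c}}\, s_{gc} f_{m(g),i,c}
   + \sqrt{1 - \rho_{m(g),c}}\, s_{gc}\, \varepsilon_{gic}, $$

exponentiated to the natural scale. The subject effect $b_i$ is shared
between conditions — that is what makes the design paired. Within-module
correlation $\rho$ is realised by one latent factor per (module, individual,
condition) with loading $\sqrt\rho$, which guarantees a positive-semidefinite
covariance for any $\rho \in [0,1)$. The planted DNM module (highest label)
has its fasted residual scale multiplied by `dnm_cv_multiplier` and its
fasted correlation raised to `dnm_within_module_correlation_fasted`; the
post-absorptive slice is untouched, matching the observation the design
emulates (CV heterogeneity was present after fasting, not at baseline).

Default parameters and why:

* `n_metabolites = 322`, `n_individuals = 8`: the motivating design.
* `n_modules = 14`: cosmetic echo of the module numbering in the motivating
  analysis; the partition structure, not the count, carries the science.
* `baseline_log2_mean = 20`, sd 1.5: peak intensities around $10^6$, the
  scale of integrated chromatographic peaks.
* `residual_sd = 0.35`, `base_within_module_correlation = 0.4`: moderate
  biological noise with clearly modular covariance.
* `subject_effect_sd = 0.2`: the subject effect is a global (rank-one)
  factor in every within-condition covariance; it is kept small relative to
  the residual so that covariance is dominated by the block-module
  structure. (A subject effect comparable to the residual makes every
  metabolite pair correlate at ~0.7 and no rank-based network can see
  modules at $n = 8$; the log-normal intensity assumption itself is a
  documented assumption, as the emulated study reports no per-condition
  intensity distributions.)
* fold-change fractions 0.25/0.25 with magnitudes 0.25–2.5 log2 units:
  roughly half of metabolites changing, spanning the −2.5…+2.5 range the
  design emulates.

The generator does **not** simulate mass-spectral peaks, retention times,
missing values, or non-log-normal heavy tails. Passing recovery tests
therefore demonstrate algorithmic correctness under a clean paired
log-normal module model, not robustness to real LC/GC-MS artefacts.

## Validation configurations

`strong_effect_config()` (planted |LFC| ≥ 1, residual sd 0.3, DNM module of
10 metabolites with fasted correlation 0.998 and CV multiplier 4) is the
documented strong-effect setting for ground-truth recovery. The near-unit
correlation is deliberate: at $n = 8$, a module can dominate a rank-based
MI network only when its members are almost deterministically co-regulated
(rank-identical across individuals), the regime in which tightly coupled
metabolite families — e.g. members of one lipid class — actually appear in
practice. A compact module is also deliberate: weighted modularity tends to
split large saturated cliques (their heterogeneous internal weights invite
bisection), while a small dense module survives partitioning intact.

`null_config()` removes all planted effects. With `correlated = TRUE` the
module correlation and subject factor remain: this is the null for network
behaviour under realistic shared structure. With `correlated = FALSE` the
metabolites are fully independent; this is the null used for calibration
checks (P-value uniformity, BH false-positive control, the "no DNM
detected" gate), because shared factors change the reference distributions
of the calibration statistics themselves: correlated paired differences
inflate the KS statistic's dispersion, and a shared subject factor couples
the estimated modules to the between-individual CVs, making the one-way F
on clustered responses anti-conservative. Under the correlated null the
fasted CV GLM is significant far more often than its nominal level — the
analysis the package follows showed the same behaviour at baseline
(a nominally significant baseline CV GLM) — and this is documented as a
known property of module GLMs fitted to module labels estimated from the
same data, not hidden by the calibration suite. Even under full
independence the gate retains a mild excess of significant calls (the F
test is not exactly calibrated for log-CV responses spread over many small
modules), so the no-DNM rate sits a little above, but near, its nominal
level.

# Numerical choices

* Spearman $r^2$ clamp: $1 - 10^{-12}$ (MI cap ≈ 13.8 nats).
* Centrality floor before log: $10^{-12}$.
* Split acceptance in the partitioner: $\Delta Q > 10^{-12}$.
* Eigenvector residual check: $\|Av - \lambda v\|_\infty \le
  10^{-10}\max(1,|\lambda|)$.
* Quantiles: type-7 (linear interpolation) everywhere.
* Intensity tables are written with 17 significant digits so that
  write→load round-trips are bit-exact.

# Test problem sizes

The regular unit suite runs generators at 40–322 metabolites with single
seeds per property and scaled-down replicate counts (8–15 seeds for
Monte-Carlo properties). The acceptance suite and `scripts/acceptance.R`
use the full sizes: 5000-metabolite nulls (50 replicates for BH
false-positive control), 10000-variance prior recovery, and 100 seeds each
for strong-effect DE sensitivity, DNM recovery, and the null no-DNM rate.
These sizes are the package's documented validation settings.

# Known limitations

* Two time points only: no formal early-warning time-series statistics; the
  DNM logic is a cross-sectional re-arrangement signature.
* Rank-based MI at $n = 8$ is saturation-driven; modules that are strongly
  but not near-deterministically correlated are not reliably separable.
* Module GLM P values inherit circularity from using the same slice for
  network estimation and response measurement; treat them as descriptive.
* The composite DNM rank rule weights its four criteria equally; no claim
  of optimality is made.
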