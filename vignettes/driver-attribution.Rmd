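---
title: "Attributing soil biodiversity variation to pesticide residues and environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing soil biodiversity variation to pesticide residues and environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soildriver)
```

## The problem

Continental soil surveys measure, at each site, pesticide residue
concentrations (mg kg⁻¹, censored at a per-compound limit of quantification,
LOQ), soil properties, climate, an ecosystem type, and molecular biodiversity
data (taxon count tables per organism group, functional-gene summaries). The
scientific question is attribution: how much of the site-to-site variation in
soil biodiversity is associated with pesticide residues once soil, climate
and ecosystem type are accounted for, which individual compounds carry that
association, and in which direction?

`soildriver` implements that analysis as a reusable, testable pipeline:
response construction, predictor preparation, model fitting and selection,
attribution, and complementary rank-based analyses, together with a
synthetic-data generator whose ground truth makes every stage verifiable.

## The model

Every biodiversity metric $y$ is modelled with a Gaussian GLM with log link,

$$\mathbb{E}[y_i] = \exp\!\big(\beta_0 + \textstyle\sum_j \beta_j x_{ij}\big),
\qquad y_i = \mathbb{E}[y_i] + \varepsilon_i,\ \varepsilon_i \sim N(0,\sigma^2),$$

one model per metric. The log link captures multiplicative, outlier-prone
behaviour while leaving the response untransformed; because the link applies
to the mean, zero observations (e.g. richness 0) need no offset, and
`fit_driver_glm()` only floors the IRLS starting means at a small positive
value. The same family is used for all metric types (diversities, percentages,
pmOG values); this uniformity is a deliberate simplification.

Model performance is summarized by $r^2$ — the squared Pearson correlation of
predicted versus observed values — plus MAE, MSE and RMSE in response units.
This $r^2$ (not adjusted $R^2$) is also the currency of the variation
partitioning below.

## Two-stage scope-constrained selection

Pesticides co-occur with particular environments, so a naive joint selection
could let a residue stand in for the conditions it is applied under.
`two_stage_selection()` therefore:

1. runs bidirectional AIC stepwise selection over soil, climate and the
   ecosystem factor only (intercept-only start by default; configurable to a
   full-model start);
2. re-runs the selection with the stage-1 terms locked in (`scope_lower`) and
   the near-zero-variance-filtered pesticide concentrations as the only new
   candidates — a pesticide enters only if it lowers the AIC beyond what the
   retained environment already achieves.

Only the stage-2 model feeds the downstream analyses. AIC counts the
estimated Gaussian dispersion as a parameter. At each step every single-term
addition and deletion is evaluated and the largest AIC decrease is accepted;
exact ties are broken by preferring deletion, then lexicographic term name,
making the selected set deterministic. Candidate fits that fail to converge
are skipped with a warning, never silently accepted. The accepted path is
stored in `$path` and is strictly decreasing in AIC by construction.

With the identity link the same machinery reproduces the classical
least-squares stepwise path, which the test suite exploits as an independent
oracle (`stats::step()` on `lm` fits agrees exactly on the selected sets:
the two AIC definitions differ by a constant that cancels in comparisons).

## Variable importance and variation partitioning

`vip()` ranks the retained terms by $|\hat\beta_j / \mathrm{SE}_j|$, keeping
the coefficient's sign as the direction of association; a multi-level
ecosystem factor is summarized by its largest-$|t|$ level so each driver gets
one rank.

`variation_partition()` decomposes the full model's explained variance over
up to four driver groups (pesticides, soil, climate, ecosystem). One GLM is
fitted per non-empty subset of groups — the union of their selected terms,
with no re-selection — and the $2^k - 1$ Venn-region fractions are obtained
by Möbius (inclusion–exclusion) inversion of the subset $r^2$ values:

$$f_T \;=\; \sum_{W \subseteq T} (-1)^{|T|-|W|+1}\, r^2\!\big(U \setminus W\big),$$

with $r^2(\varnothing) = 0$. The residual is $1 - r^2(\text{full})$, and
fractions plus residual sum to 1 exactly. Shared fractions may be negative
(suppression); they are reported as computed, never clipped, matching the
convention of classical partitioning tools. Groups whose terms were never
selected contribute exactly 0 and are reported as dropped. The test suite
checks the inversion against a direct linear-system solution of the same
subset-$r^2$ equations to $10^{-10}$.

Two deliberate divergences from classical `vegan::varpart`: the performance
metric is the squared predicted–observed correlation of the log-link GLM
(the pipeline's stated metric) rather than adjusted $R^2$, and sub-models
reuse the final selected terms rather than re-running selection per subset.

## Biodiversity metrics

* **SRS normalization** (`srs_normalize()`): each site's counts are scaled to
  a common total $C_{min}$; integer parts are kept and the remaining deficit
  is distributed one unit each to taxa ranked by descending fractional part.
  Ties among equal fractional parts are broken by descending original
  abundance, then stable input order — a deterministic default that makes
  tests exact — with an optional seed for randomized tie-breaking. Every
  normalized site total equals $C_{min}$ exactly and subsampling can never
  create a taxon. $C_{min}$ defaults to the minimum site library size per
  organism group, the standard choice.
* **Richness and Shannon diversity** per organism group; Shannon in natural
  log (nats). Both can be computed on raw or normalized counts; normalized is
  the default.
* **Multidiversity** (`multidiversity()`): the mean of per-group min–max
  standardized richness ($1/6$ weighting for the default six groups:
  archaea, bacteria, fungi, protists, nematodes, arthropods).
  Standardization is computed over exactly the sites supplied, so each
  analysis scope (croplands only versus all ecosystems) gets its own scaling.
  A group with zero richness range is pegged at $z = 0.5$ to keep the equal
  weighting meaningful.
* **Functional-group relative abundance** (`functional_abundance()`): percent
  of total reads carried by taxa assigned to a group; unassigned taxa count
  in the denominator only.
* **pmOG** (`pmog()`): orthologous groups per million functionally annotated
  reads, $\mathrm{OGs} / \mathrm{reads} \times 10^6$.

## Predictor preparation

* **LOQ censoring** (`censor_loq()`): values strictly below the per-compound
  LOQ become exact zeros; values equal to the LOQ are kept. Detection is
  thereafter `value > 0`.
* **Near-zero-variance filter** (`near_zero_variance_filter()`): a pesticide
  column is removed when the most-common/second-most-common value frequency
  ratio exceeds 95/5 = 19 *and* the percentage of distinct values falls below
  5% — the joint condition of the near-zero-variance convention. The joint
  form matters with zero-inflated concentrations: zero is almost always the
  single most common value, so a ratio-only rule would discard even widely
  detected compounds, while the distinct-value condition separates
  rarely-detected residues (a handful of distinct values) from informative
  ones. An either-rule variant is available via `combine = "or"`. Constant
  columns are always removed, and removal reasons are recorded.
* **Environmental transforms**: pH is negatively exponentially transformed
  ($e^{-\mathrm{pH}}$), electrical conductivity log-transformed.
* **Risk metrics** (`risk_quotients()`): per compound,
  $RQ = \mathrm{conc} / \mathrm{NOEC}_{min} \times AF$ with assessment factor
  $AF = 5$; cumulative risk per site sums detected compounds, overall and by
  type. Compounds without a NOEC are excluded from sums and listed.

## Complementary analyses

For each pesticide retained in a final model, `presence_env_tests()` compares
each environmental variable from the same model between detection and
non-detection sites with a Kruskal–Wallis test (equivalent to a Wilcoxon
rank-sum test for two groups; the degenerate all-tied case is defined as
$H = 0$, $p = 1$). Raw and Benjamini–Hochberg adjusted p-values are reported
side by side, since it is a judgement call whether such screens should be
adjusted. `spearman_screen()` correlates biodiversity metrics with aggregate
pesticide metrics (occurrence counts by type, cumulative risks) using
Spearman's rank correlation with BH adjustment across the screen.
`ecosystem_residue_comparison()` compares per-site residue counts between
ecosystem pairs with two-sided Wilcoxon tests, BH adjustment, and a compact
letter display (insert-and-absorb algorithm). Asymptotic p-values with tie
corrections are used throughout.

## The synthetic-data generator

`simulate_soildriver()` emulates the survey's design so the whole pipeline is
testable without restricted data. Defaults are fixed at survey-like
conditions: 373 sites; ecosystem proportions 210/34/19/97/13 across annual
croplands, permanent croplands, former croplands, extensive grasslands and
woodlands; 11 soil + 7 climate covariates from a multivariate normal with
exchangeable correlation 0.2; 30 pesticide columns that are zero-inflated
(detection probability 0.3), lognormal when detected (median 0.02 mg kg⁻¹,
log-sd 1), rounded to the 0.001 mg kg⁻¹ reporting precision and censored at
LOQ 0.001; one nearly-always-zero column planted to exercise the filter;
multinomial count tables over Dirichlet taxon probabilities with library
sizes in [5000, 50000]; and a catalog with two NOEC-less compounds.

Responses are generated from the same family the pipeline fits:
$y = \exp(\eta) + \varepsilon$, with $\eta$ a linear combination of
unit-variance composite signals built from true predictors in each driver
group, orthogonalized across groups so the planted unique fractions carry no
shared component. Because analytic $r^2$ under a log link is intractable,
per-group coefficient scales are calibrated by a deterministic damped
fixed-point search on the realized design: the realized unique fractions are
re-measured exactly as the attribution module measures them (full-model $r^2$
minus leave-one-group-out $r^2$) and scales are updated proportionally until
the planted `group_r2` (default pesticides 0.30, soil 0.20, climate 0.10,
noise sd 25 around baseline 100) is met within 0.008, or an explicit
calibration-failure error is raised if the targets are unattainable. In the
noiseless limit the full model explains everything, so `group_r2` is read as
relative signal weights there. With `cropland_only_effect = TRUE` the
pesticide signal is restricted to cropland sites and the calibration targets
the cropland subset — the all-ecosystem fraction is then its dilution, which
is precisely the scope contrast the pipeline is meant to detect.

What the generator does *not* emulate: spatial autocorrelation and
coordinates, realistic pesticide co-application (mixture) structure beyond
optional covariate correlation, taxon-level responses to individual
compounds (responses are generated at the metric level), and raw sequence
data. Passing tests therefore demonstrate that the machinery recovers known
structure under the stated generative assumptions — not that real soil data
satisfy those assumptions.

## Numerical choices

* IRLS: maximum 100 iterations, deviance tolerance $10^{-8}$; non-converged
  candidate models are excluded from stepwise comparison with a warning.
* Stepwise AIC tie-break: deletion before addition, then lexicographic term
  name; improvements below $10^{-8}$ count as no improvement.
* VIFs are computed from the unweighted design-matrix correlation matrix via
  the determinant (generalized VIF) formula, with `GVIF^(1/(2 df))` reported
  for multi-column factor terms; exact collinearity yields an infinite,
  flagged VIF.
* Min–max standardization with zero range: $z = 0.5$, with a warning.
* BH adjustment preserves p-value ordering and never falls below the raw p;
  re-adjusting already-adjusted values is not a no-op, so adjustment is
  applied exactly once per screen.
* All generator randomness derives child seeds deterministically from one
  user seed, so identical configurations give bit-identical datasets.

## Problem sizes used in validation

The shipped validation exercises use n = 200 sites for the partition-oracle
comparisons (20 datasets, 2–4 groups), n = 300 with 50 replicates for
fraction recovery and the cropland scope contrast, n = 300 with 100
replicates for stepwise recovery, 20 instances for each cross-check oracle,
and 1000 replicates at n = 300 for the Spearman null calibration — sizes at
which the Monte-Carlo tolerances quoted in the tests are comfortably
attainable on a single CPU.

## Known limitations

Stepwise AIC selection admits spurious terms at a per-term rate near
$P(\chi^2_1 > 2) \approx 0.16$ under the null; the pipeline reports this
entry rate rather than pretending exact-set recovery. The GLM family is a
pragmatic approximation for percentage and index responses. Attribution is
associational: variation partitioning quantifies explained-variance
structure, not causal effects, and negative shared fractions signal
suppression rather than any physical quantity. Mixture toxicity, degradation
kinetics and spatial structure are out of scope.
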