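---
title: "Methods: rank-based gene-pair risk modelling and refined ISS staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based gene-pair risk modelling and refined ISS staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairstage)
```

# The model

`pairstage` builds prognostic models for overall survival in multiple
myeloma (and similar settings) from *within-sample gene orderings* rather
than from expression magnitudes. For an ordered pair of genes $(A, B)$ and a
sample $s$, the pair feature is

$$ x_{AB}(s) = \begin{cases} +1 & \text{if } e_A(s) > e_B(s) \\ -1 &
\text{otherwise,} \end{cases} $$

where $e_g(s)$ is the measured expression of gene $g$ in sample $s$. Ties
map to $-1$: the feature answers the single question "does the anchor
strictly exceed the partner?", so the non-strict case is its complement.
Because $x_{AB}$ depends only on the order of two values inside one sample,
it is *exactly* invariant under any strictly increasing per-sample
transformation of the measurements — rescaling, log-compression, power
distortion, per-sample affine shifts. That is the property that lets a model
trained on one expression platform be applied verbatim to another, and the
package tests assert bit-identical scores under such distortions rather than
approximate agreement.

The risk score is a sparse linear combination $\eta(s) = \sum_j \beta_j\,
x_{A_j B_j}(s)$ fitted by L1-penalized Cox regression, and a fixed cutoff
$c$ learned on the training cohort splits samples into low ($\eta \le c$)
and high ($\eta > c$) risk.

## The nested selection pipeline

`train_cell_death_model()` runs seven deterministic stages, each of which
fails with an informative error naming the stage if it empties the candidate
set:

1. **Gene screening.** Each candidate gene is tested twice against survival:
   a univariate Cox model on the continuous value, and a log-rank test at
   the gene's maximally selected cutpoint. A gene passes at `p_threshold`
   (default 0.01) under the *union* rule (either test suffices); an
   intersection rule is available.
2. **Gene-level LASSO.** Penalized Cox on the screened genes' expression;
   the active set at the chosen lambda becomes the *anchor* set.
3. **Pair construction.** All ordered anchor-partner pairs against the
   candidate universe (`build_pair_matrix()`), deduplicated as unordered
   pairs.
4. **Prevalence filter.** Pairs whose $+1$ frequency falls outside
   `[freq_low, freq_high]` (default $[0.20, 0.80]$, bounds inclusive) are
   removed: a pair that is nearly constant carries almost no information and
   its univariate test is unstable.
5. **Per-pair FDR.** Univariate Cox per pair, Benjamini-Hochberg adjusted;
   pairs with $q <$ `pair_fdr` (default 0.05) survive.
6. **Pair-level LASSO.** Penalized Cox on the surviving $\pm 1$ features
   with `standardize = FALSE` — the features already share a scale, and
   re-standardizing would silently reweight pairs by their prevalence.
7. **Cutpoint.** The maximally selected log-rank cutpoint on the training
   risk scores, constrained so each side holds at least `minprop` (default
   0.10) of the samples.

## Refined staging

Risk group and ISS stage cross into six strata, merged into three tiers:

| stratum | tier |
|---|---|
| low risk, ISS 1 or 2 | low |
| high risk, ISS 1; low risk, ISS 3 | medium |
| high risk, ISS 2 or 3 | high |

The merge keeps both axes informative: a high molecular risk lifts ISS 1
into the middle tier, and ISS 3 lifts a low molecular risk likewise.

# Statistical components and their numerical choices

**Maximally selected cutpoint** (`max_selected_cutpoint()`). Candidate
thresholds are midpoints between adjacent distinct score values with both
groups at least `minprop` of the sample. At each threshold the statistic is
the permutation-standardized sum of Nelson-Aalen log-rank scores
$a_i = \delta_i - \hat\Lambda(t_i)$ in the low group; ties in the maximum
resolve to the smallest threshold. The naive p-value of the best split does
not account for the maximization; `p_corrected` applies the
improved-Bonferroni approximation for the supremum of the standardized
process over the `minprop` range. The uncorrected value is the default
because downstream selection treats it only as a screening score under a
union rule, but any calibration claim about the cutpoint itself should use
`p_corrected` — the uncorrected test rejects a true null at roughly twice
the nominal rate, which the test suite demonstrates.

**Penalized Cox** (`lasso_cox_path()`). Cross-validation folds are
stratified by event status and fully determined by `seed`, so training is
reproducible. The default lambda rule is **1se** rather than **min**: with
hundreds of correlated candidate pairs and a few hundred events, the
deviance-minimizing lambda routinely admits dozens of near-duplicate pairs,
and the 1se rule buys sparsity at a negligible deviance cost. `min` remains
available via `lambda_rule`. The path floor `lambda_min_ratio` defaults to
0.01 rather than glmnet's 1e-4: on collinear discrete $\pm 1$ features the
near-unpenalized tail of the path costs minutes of coordinate-descent time
while the CV-selected lambdas sit an order of magnitude above either floor;
a warning fires if a selected lambda ever lands on the floor.

**Cox fitting** (`fit_cox()`) uses Efron tie handling with a tightened
convergence tolerance (`eps = 1e-11`) so coefficients agree with an
independent Newton maximizer to at least six digits, and detects monotone
likelihood (separation) rather than reporting a huge finite coefficient as
trustworthy.

**Harrell's C** (`harrell_cindex()`) counts risk-ordered usable pairs; ties
in score contribute 1/2. The asymptotic standard error is used for $n \ge
50$ and a bootstrap below that, where the asymptotic variance is
unreliable.

**Time-dependent AUC** (`time_dependent_auc()`) is the cumulative/dynamic
IPCW estimator: cases ($T \le t$, event) are weighted by $1/\hat G(T^-)$,
controls ($T > t$) by $1/\hat G(t)$, with $\hat G$ the Kaplan-Meier
estimate of the censoring distribution. Horizons with no prior events or no
one still at risk are skipped with a warning, never extrapolated.

**Meta-analysis** (`meta_cindex()`) pools per-cohort C-indices with
DerSimonian-Laird random effects; a single cohort passes through unchanged
with $\tau^2 = 0$.

# The synthetic-data generator

`sim_config()` / `simulate_study()` generate multi-cohort studies with a
known truth for validation. Genes are lognormal with per-gene `meanlog`
$\sim U(1, 4)$ and `sdlog` $\sim U(0.3, 0.8)$. Informative pairs are drawn
from disjoint genes that *share* their marginal parameters, so the $+1$
frequency of a true pair is near 0.5 — squarely inside the prevalence
filter. Survival is exponential proportional hazards with linear predictor
$\sum_j \beta_j x_j$; default `baseline_hazard = log(2)/60` gives a
60-month median for a baseline subject. Censoring is uniform $(0, C)$ with
$C$ solved numerically so the expected censoring fraction matches
`censoring_rate` (default 0.70, typical of myeloma trial follow-up). ISS is
drawn from a proportional-odds model tilted by the standardized true risk,
so staging and molecular risk correlate without being redundant. Per-cohort
`batch_transforms` apply strictly monotone distortions that emulate
platform differences.

Default cohort sizes `c(796, 415, 558, 55, 256)` span the range seen in
large public myeloma expression resources, from a small trial arm to a
registry-scale cohort, and are the sizes exercised by the `analysis/`
scripts.

**Scope and limitations.** The generator is a *validation harness*, not a
biological simulator: hazards are exactly proportional and exponential,
true effects are exactly pairwise rank signals, genes outside true pairs
are independent noise, and ISS depends on survival only through the same
linear predictor. Real expression data has correlated co-expression
modules, non-PH effects, and informative censoring, none of which are
modelled. Conclusions supported by the generator are therefore of the form
"the implementation recovers what it is designed to recover", not "the
method will attain C = 0.73 on clinical data".

# Design decisions on open questions

* **Pair FDR 0.05 vs 0.01.** Default `pair_fdr = 0.05`; 0.01 is one
  argument away. Stage 6's LASSO provides a second, stronger selection, so
  the FDR stage only needs to keep the multiplicity of the pair universe in
  check, and 0.05 keeps weaker true pairs alive for the penalized fit.
* **1se vs min.** 1se default for sparsity and cross-cohort stability (see
  above).
* **Uncorrected KM screening p.** Screening combines the cutpoint log-rank
  p with the Cox p under a union rule; the anti-conservativeness of the
  uncorrected p is deliberate permissiveness at the screening stage, and
  the corrected alternative (`km_p = "corrected"`) is available and tested.
* **Ties map to −1.** Expression data on a continuous scale makes exact
  ties rare; fixing them to the complement of "strictly greater" keeps the
  feature a deterministic function of the data with no third state.
* **ISS link in the generator.** Proportional odds on the standardized
  linear predictor with a fixed offset, verified numerically to produce
  stochastically ordered stage frequencies over the supported strength
  range.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_samples = c(600, 400), n_genes = 120,
                  n_informative_pairs = 8, seed = 42)
train <- simulate_cohort(cfg, 1)
test  <- simulate_cohort(cfg, 2)

model <- train_cell_death_model(train$expression, train$clinical,
                                candidate_genes = rownames(train$expression),
                                config = cd_config(seed = 1))
risk  <- compute_risk_scores(model, test$expression)
harrell_cindex(risk$risk_score, test$clinical$os_time,
               test$clinical$os_event)

staged <- stage_samples(risk, test$clinical)
table(staged$refined_iss)
```

The `analysis/` directory contains four numbered scripts that run this
workflow end to end at full cohort sizes and write every table under
`results/`.
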