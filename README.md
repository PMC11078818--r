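# pairstage

Rank-based gene-pair prognostic modelling and refined ISS staging for
multiple myeloma.

## The problem

Expression-based prognostic signatures usually fail to transfer across
cohorts because absolute expression values depend on platform,
normalization, and batch. `pairstage` sidesteps the problem by building
models from *within-sample gene orderings*: for an ordered gene pair
(A, B), the feature is **+1 when A is expressed above B in that sample and
−1 otherwise**. This coding is exactly invariant to any strictly
increasing per-sample transformation of the measurements, so a trained
model applies verbatim to data from a different platform — no
renormalization, no recalibration.

On top of the pair features the package implements a complete prognostic
workflow:

1. **Training** (`train_cell_death_model()`): a nested pipeline — gene
   screening (Cox and maximally-selected-cutpoint log-rank, p < 0.01,
   union rule) → gene-level LASSO-Cox (anchors) → pair construction →
   prevalence filter (+1 frequency in [0.20, 0.80]) → per-pair Cox with
   Benjamini–Hochberg FDR → pair-level LASSO-Cox → maximally selected
   risk cutpoint. The risk score is a sparse sum
   η(s) = Σⱼ βⱼ·xⱼ(s) over selected pairs, dichotomized at the learned
   cutoff.
2. **Staging** (`combine_strata()`, `refine_iss()`, `stage_samples()`):
   risk group × International Staging System (ISS) gives six strata,
   merged into three refined tiers — low = {low-risk ISS 1/2},
   medium = {high-risk ISS 1, low-risk ISS 3}, high = {high-risk ISS 2/3}.
3. **Evaluation** (`harrell_cindex()`, `time_dependent_auc()`,
   `meta_cindex()`, `compare_models()`): Harrell's concordance,
   censoring-weighted (IPCW) time-dependent AUC, and DerSimonian–Laird
   random-effects pooling of concordance across cohorts.
4. **Validation harness** (`sim_config()`, `simulate_study()`): a
   multi-cohort survival simulator with known true pairs, tunable
   censoring, ISS linked to the true hazard, and per-cohort strictly
   monotone "platform" distortions.

## Worked example

Train on one synthetic cohort, evaluate on a second drawn from the same
generating process but never seen during training:

```r
library(pairstage)

cfg <- sim_config(n_samples = c(600, 400), n_genes = 120,
                  n_informative_pairs = 8, seed = 42)
train <- simulate_cohort(cfg, 1)
test  <- simulate_cohort(cfg, 2)

model <- train_cell_death_model(train$expression, train$clinical,
                                candidate_genes = rownames(train$expression),
                                config = cd_config(seed = 1))
#> screen_genes: 20 of 120 genes passed (p < 0.01, union rule)
#> lasso_cox_path: 11 of 20 features active at lambda.1se = 0.049394
#> filter_pairs_by_frequency: kept 509 of 1199 pairs in [0.20, 0.80]
#> lasso_cox_path: 42 of 202 features active at lambda.1se = 0.049917
#> train_cell_death_model: candidates=120, screened=20, anchors=11,
#>   pairs_built=1199, pairs_prevalent=509, pairs_fdr=202, pairs_final=42,
#>   n_train=600

risk <- compute_risk_scores(model, test$expression)
harrell_cindex(risk$risk_score, test$clinical$os_time, test$clinical$os_event)
#> C-index 0.8006 (SE 0.0184, 95% CI 0.7646-0.8366, 31390 usable pairs)

staged <- stage_samples(risk, test$clinical)
table(staged$refined_iss)
#>    low medium   high
#>    171    129    100

time_dependent_auc(risk$risk_score, test$clinical$os_time,
                   test$clinical$os_event, horizons = c(6, 12, 24))
#>   horizon       auc n_cases n_controls
#> 1       6 0.8634811      65        268
#> 2      12 0.8301913      94        182
#> 3      24 0.8037296     115         77
```

Because the model compares genes only within a sample, distorting the test
cohort with any strictly increasing per-sample transform leaves every score
bit-identical:

```r
distorted <- apply_batch_transform(test$expression,
                                   list(type = "affine", a = 3, b = 50))
identical(compute_risk_scores(model, distorted)$risk_score, risk$risk_score)
#> [1] TRUE
```

## The full analysis

The `analysis/` directory runs the workflow at realistic scale — five
cohorts (796, 415, 558, 55, 256 samples) on five simulated "platforms",
training on a 2/3 split of the largest cohort:

```sh
Rscript analysis/01_simulate_cohorts.R   # writes results/data/
Rscript analysis/02_train_model.R        # writes results/model.json
Rscript analysis/03_stage_cohorts.R      # per-cohort staging tables
Rscript analysis/04_evaluate.R           # C, AUC(t), meta-analysis
```

On the default seeds this yields an internal-validation C of 0.747,
external-cohort Cs of 0.70–0.73 with a random-effects pooled
C = 0.726 (95% CI 0.700–0.752), 100% recovery of the true pair genes, and
the ranking risk score > refined staging > raw ISS (pooled C 0.726 /
0.711 / 0.659).

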