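test_that("lasso path selects nothing at the heavy-penalty end and is seed-reproducible", {
  set.seed(21)
  n <- 150
  X <- matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("f", 1:20)))
  tm <- rexp(n); ev <- rbinom(n, 1, 0.8)
  # noise-only features: the 1se rule yields an empty active set, with a warning
  expect_warning(fit <- suppressMessages(lasso_cox_path(X, tm, ev, seed = 3)),
                 "empty active set")
  # heaviest lambda on the path: empty model
  b_max <- as.matrix(coef(fit$cv, s = max(fit$cv$lambda)))[, 1]
  expect_true(all(b_max == 0))
  fit2 <- suppressMessages(suppressWarnings(lasso_cox_path(X, tm, ev, seed = 3)))
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$foldid, fit2$foldid)
  fit3 <- suppressMessages(suppressWarnings(lasso_cox_path(X, tm, ev, seed = 4)))
  expect_false(identical(fit$foldid, fit3$foldid))
})

test_that("lasso recovers a strong feature among noise and stays quiet under permuted labels", {
  set.seed(31)
  picked <- logical(15); null_empty <- logical(12)
  for (r in 1:15) {
    n <- 400
    X <- matrix(rnorm(n * 51), n, dimnames = list(NULL, c("true", paste0("n", 1:50))))
    t_ev <- rexp(n, 0.05 * exp(2 * X[, "true"]))
    cens <- runif(n, 0, quantile(t_ev, 0.8) * 2)
    tm <- pmin(t_ev, cens); ev <- as.integer(t_ev <= cens)
    fit <- suppressMessages(suppressWarnings(
      lasso_cox_path(X, tm, ev, lambda_rule = "1se", seed = r)))
    picked[r] <- "true" %in% fit$features &&
      fit$coefficients["true"] > 0
    if (r <= 12) {
      perm <- sample(n)
      fitp <- suppressMessages(suppressWarnings(
        lasso_cox_path(X, tm[perm], ev[perm], lambda_rule = "1se", seed = r)))
      null_empty[r] <- length(fitp$features) == 0
    }
  }
  expect_gte(mean(picked), 0.8)
  expect_gte(mean(null_empty), 0.75)
})

test_that("training recovers true pairs and generalizes; stages fail loudly when empty", {
  cfg <- sim_config(n_samples = c(600, 400), n_genes = 120,
                    n_informative_pairs = 8,
                    pair_coefficients = c(1, -0.9, 1.1, 0.8, -1, 0.95, 1.05, -0.85),
                    seed = 42)
  tr <- simulate_cohort(cfg, 1)
  te <- simulate_cohort(cfg, 2)
  truth_genes <- unique(c(tr$truth$anchor, tr$truth$partner))
  set.seed(5)
  cands <- union(truth_genes,
                 sample(setdiff(rownames(tr$expression), truth_genes), 30))
  model <- suppressMessages(suppressWarnings(
    train_cell_death_model(tr$expression, tr$clinical, cands,
                           cd_config(seed = 9))))
  model_genes <- unique(c(model$pairs$anchor, model$pairs$partner))
  recovery <- mean(tr$truth$anchor %in% model_genes |
                     tr$truth$partner %in% model_genes)
  expect_gte(recovery, 0.6)
  rk <- compute_risk_scores(model, te$expression)
  cc <- harrell_cindex(rk$risk_score, te$clinical$os_time, te$clinical$os_event)
  expect_gt(cc$c_index, 0.65)

  # identical seed reproduces the identical model
  model2 <- suppressMessages(suppressWarnings(
    train_cell_death_model(tr$expression, tr$clinical, cands,
                           cd_config(seed = 9))))
  expect_identical(model$pairs, model2$pairs)
  expect_identical(model$risk_cutoff, model2$risk_cutoff)

  # degenerate configs fail at the named stage
  expect_error(suppressMessages(
    train_cell_death_model(tr$expression, tr$clinical, c("NOT_A_GENE"),
                           cd_config())),
    "stage 1")
  expect_error(suppressMessages(suppressWarnings(
    train_cell_death_model(tr$expression, tr$clinical, cands,
                           cd_config(pair_fdr = 0, seed = 9)))),
    "stage 5")
})

test_that("risk scores follow the coefficient-weighted pair sum and the fixed cutoff", {
  model <- small_model()  # coefficients (0.5, -0.2), cutoff 0.15
  # sample S1: both pairs +1 -> score 0.5 - 0.2 = 0.3 -> high
  # sample S2: both pairs -1 -> score -0.3 -> low
  expr <- matrix(c(5, 9, 3, 7,    # S1: GA>GX, GB>GY
                   1, 2, 4, 8),   # S2: GA<GX, GB<GY
                 nrow = 4,
                 dimnames = list(c("GA", "GB", "GX", "GY"), c("S1", "S2")))
  rk <- compute_risk_scores(model, expr)
  expect_equal(rk$risk_score, c(0.3, -0.3))
  expect_identical(rk$risk_group, c("high", "low"))

  # negating every pair value negates the score
  expect_equal(rk$risk_score[1], -rk$risk_score[2])

  # missing model gene is an error listing the gene
  expect_error(compute_risk_scores(model, expr[1:3, ]), "GY")
})

test_that("risk scores are exactly invariant to strictly increasing per-sample transforms", {
  cfg <- sim_config(n_samples = c(250, 200), n_genes = 50, n_informative_pairs = 4,
                    pair_coefficients = c(1, 1, -1, 1), seed = 77)
  tr <- simulate_cohort(cfg, 1)
  te <- simulate_cohort(cfg, 2)
  cands <- unique(c(tr$truth$anchor, tr$truth$partner))
  model <- suppressMessages(suppressWarnings(
    train_cell_death_model(tr$expression, tr$clinical, cands,
                           cd_config(seed = 2, n_folds = 5))))
  base <- compute_risk_scores(model, te$expression)
  n <- ncol(te$expression)
  set.seed(3)
  distorted <- apply_batch_transform(
    te$expression, list(type = "affine", a = runif(n, 0.5, 5), b = rnorm(n, 10)))
  distorted <- apply_batch_transform(distorted, list(type = "power", p = 1.7))
  after <- compute_risk_scores(model, distorted)
  expect_identical(base$risk_score, after$risk_score)
  expect_identical(base$risk_group, after$risk_group)

  # a raw-expression linear predictor has no such invariance
  genes <- unique(model$pairs$anchor)
  raw_lp_base <- colSums(te$expression[genes, , drop = FALSE])
  raw_lp_dist <- colSums(distorted[genes, , drop = FALSE])
  expect_gt(max(abs(raw_lp_base - raw_lp_dist)), 1)
})

test_that("pair-score distributions are more stable across distorted cohorts than raw-expression scores", {
  transforms <- list(list(type = "identity"),
                     list(type = "affine", a = 3, b = 50),
                     list(type = "power", p = 0.5))
  cfg <- sim_config(n_samples = c(450, 450, 450), n_genes = 50,
                    n_informative_pairs = 5,
                    pair_coefficients = c(1.2, 1, -1, 1.1, 0.9),
                    batch_transforms = transforms, seed = 123)
  study <- simulate_study(cfg)
  truth <- study[[1]]$truth
  cands <- unique(c(truth$anchor, truth$partner))
  model <- suppressMessages(suppressWarnings(
    train_cell_death_model(study[[1]]$expression, study[[1]]$clinical, cands,
                           cd_config(seed = 4, n_folds = 5))))
  pair_medians <- vapply(study, function(co)
    median(compute_risk_scores(model, co$expression)$risk_score), numeric(1))
  genes <- unique(model$pairs$anchor)
  raw_medians <- vapply(study, function(co) {
    lp <- colSums(scale(t(co$expression[genes, , drop = FALSE]),
                        center = FALSE, scale = FALSE))
    median(lp)
  }, numeric(1))
  # compare on a common scale: coefficient of variation of cohort medians
  rel_spread <- function(m) stats::var(m) / (mean(abs(m))^2 + 1e-12)
  expect_lt(rel_spread(pair_medians), rel_spread(raw_medians))
})
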