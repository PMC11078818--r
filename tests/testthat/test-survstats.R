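test_that("Cox coefficient matches a brute-force partial-likelihood maximizer on a worked dataset", {
  # 6 observations, distinct times, mixed censoring
  time <- c(2, 5, 7, 11, 14, 20)
  event <- c(1, 0, 1, 1, 0, 1)
  x <- c(1.2, -0.4, 0.8, -1.1, 0.3, -0.7)
  fit <- fit_cox(x, time, event)
  oracle <- oracle_cox_coef(x, time, event)
  expect_false(oracle$at_boundary)
  expect_equal(fit$coef, oracle$coef, tolerance = 1e-8)
})

test_that("Cox fit matches the brute-force optimizer over exhaustive small event patterns", {
  set.seed(301)
  time <- c(1.3, 2.9, 4.1, 6.7, 8.2, 9.5)  # distinct: Efron == Breslow
  x <- c(0.5, -1.2, 0.9, 0.1, -0.6, 1.4)
  n_checked <- 0
  for (pattern in 1:63) {
    event <- as.integer(intToBits(pattern)[1:6])
    oracle <- oracle_cox_coef(x, time, event)
    if (oracle$at_boundary || abs(oracle$coef) > 5) next  # monotone likelihood
    fit <- suppressWarnings(fit_cox(x, time, event))
    expect_equal(fit$coef, oracle$coef, tolerance = 1e-6,
                 label = sprintf("pattern %d", pattern))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
})

test_that("Cox null case is unbiased and the true log-HR is covered by its CI", {
  # null: covariate independent of survival
  set.seed(77)
  hrs <- replicate(40, {
    n <- 1000
    x <- rnorm(n)
    sv <- list(time = rexp(n), event = rbinom(n, 1, 0.7))
    fit_cox(x, sv$time, sv$event)$hazard_ratio
  })
  expect_true(all(hrs > 0.85 & hrs < 1.18))

  # two-group data with log-HR = 1: CI coverage over seeded replicates
  set.seed(177)
  covered <- replicate(200, {
    n <- 500
    g <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, rate = 0.05 * exp(1 * g))
    cens <- runif(n, 0, 40)
    fit <- fit_cox(g, pmin(t_ev, cens), as.integer(t_ev <= cens))
    abs(fit$coef - 1) <= 1.96 * fit$se
  })
  expect_gte(mean(covered), 0.93)
})

test_that("fit_cox rejects constant covariates and reports separation", {
  expect_error(fit_cox(rep(1, 20), rexp(20), rep(1, 20)), "constant")
  # perfectly separating covariate -> monotone likelihood flagged
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- fit_cox(x, time, event), "separation")
  expect_true(attr(fit, "separation"))
})

test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  # times (1, 2+, 3), events (1,0,1): S = 1 before 1, 2/3 on [1,3), 0 at 3
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$sfun(0), 1)
  expect_equal(km$sfun(0.99), 1)
  expect_equal(km$sfun(1), 2 / 3)
  expect_equal(km$sfun(2.5), 2 / 3)
  expect_equal(km$sfun(3), 0)

  # no censoring: S equals the empirical survival function
  set.seed(12)
  t <- sort(sample(1:100, 30))
  km2 <- km_estimate(t, rep(1, 30))
  for (u in c(0, 5.5, 33, 99, 200)) {
    expect_equal(km2$sfun(u), mean(t > u))
  }

  # all censored: S is identically 1
  km3 <- km_estimate(c(4, 8, 15), c(0, 0, 0))
  expect_equal(km3$sfun(c(0, 10, 100)), c(1, 1, 1))
})

test_that("log-rank statistic matches direct observed-minus-expected accumulation", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 40
    groups <- sample(c("a", "b"), n, replace = TRUE)
    time <- round(rexp(n, 0.1), 1)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) next
    got <- logrank_test(groups, time, event)
    want <- oracle_logrank(groups, time, event)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
  # three groups
  groups3 <- sample(c("a", "b", "c"), 60, replace = TRUE)
  time3 <- round(rexp(60, 0.1), 1)
  event3 <- rbinom(60, 1, 0.8)
  got3 <- logrank_test(groups3, time3, event3)
  want3 <- oracle_logrank(groups3, time3, event3)
  expect_equal(got3$statistic, want3$statistic, tolerance = 1e-8)
  expect_equal(got3$df, 2L)
})

test_that("log-rank test is zero for identical groups and powerful under a strong effect", {
  time <- c(3, 6, 9, 12, 15)
  event <- c(1, 1, 0, 1, 0)
  got <- logrank_test(rep(c("a", "b"), each = 5), rep(time, 2), rep(event, 2))
  expect_lt(got$statistic, 1e-10)

  set.seed(404)
  rejections <- replicate(300, {
    n <- 200
    g <- rep(0:1, each = n / 2)
    t_ev <- rexp(n, rate = 0.05 * exp(log(3) * g))
    cens <- rexp(n, rate = 0.014)
    logrank_test(g, pmin(t_ev, cens), as.integer(t_ev <= cens))$p < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})

test_that("maximally selected cutpoint equals a naive exhaustive scan", {
  set.seed(55)
  for (rep in 1:8) {
    n <- 35
    score <- round(rnorm(n), 2)
    time <- round(rexp(n, 0.1), 1)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 3 || length(unique(score)) < 4) next
    got <- max_selected_cutpoint(score, time, event)
    want <- oracle_cutpoint(score, time, event)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-10)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  }
})

test_that("cutpoint lands between well-separated risk clusters and honors minprop", {
  set.seed(66)
  n <- 200
  cluster <- rep(0:1, each = n / 2)
  score <- cluster * 4 + runif(n)          # clusters in [0,1] and [4,5]
  t_ev <- rexp(n, rate = 0.05 * exp(2 * cluster))
  cp <- max_selected_cutpoint(score, t_ev, rep(1, n))
  expect_gt(cp$threshold, 1)
  expect_lt(cp$threshold, 4)

  for (rep in 1:10) {
    score <- rnorm(50)
    t <- rexp(50)
    cp <- max_selected_cutpoint(score, t, rbinom(50, 1, 0.8), minprop = 0.10)
    expect_gte(cp$n_low, ceiling(0.10 * 50))
    expect_gte(cp$n_high, ceiling(0.10 * 50))
  }
  expect_error(max_selected_cutpoint(rep(1, 30), rexp(30), rep(1, 30)),
               "no admissible cutpoint")
})

test_that("BH adjustment matches the step-up formula and its order/monotonicity properties", {
  expect_equal(bh_fdr(rep(1, 7)), rep(1, 7))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(88)
  p <- runif(50)^2
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  expect_true(all(bh_fdr(p) >= p))

  perm <- sample(50)
  q <- bh_fdr(p)
  expect_equal(bh_fdr(p[perm])[order(perm)], q, tolerance = 1e-12)

  # discovery count is monotone in alpha
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5), function(a) sum(q < a), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("gene screening detects strong effects, skips constant genes, and respects the threshold", {
  # strong prognostic gene: detected in (nearly) all replicates
  set.seed(99)
  hits <- replicate(10, {
    n <- 500
    expr <- random_expression(3, n, seed = sample.int(1e6, 1))
    eta <- 1.5 * scale(log(expr["G001", ]))[, 1]
    sv <- list(time = rexp(n, 0.05 * exp(eta)), event = rbinom(n, 1, 1))
    res <- screen_genes(expr, sv$time, sv$event)
    res$passed[res$gene == "G001"]
  })
  expect_gte(mean(hits), 0.95)

  # null gene, selection-corrected KM p: union pass rate stays near the
  # nominal level; the uncorrected default is visibly anti-conservative
  set.seed(111)
  null_hits <- t(replicate(300, {
    n <- 150
    expr <- matrix(rlnorm(2 * n), nrow = 2,
                   dimnames = list(c("GX", "GY"), sprintf("S%03d", 1:n)))
    tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
    corr <- suppressMessages(screen_genes(expr, tm, ev, km_p = "corrected"))
    unc <- suppressMessages(screen_genes(expr, tm, ev))
    c(corrected = corr$passed[1], uncorrected = unc$passed[1])
  }))
  expect_lt(mean(null_hits[, "corrected"]), 0.05)
  expect_gt(mean(null_hits[, "uncorrected"]), mean(null_hits[, "corrected"]))

  # degenerate threshold: nothing passes
  expr <- random_expression(4, 100, seed = 7)
  res0 <- suppressMessages(screen_genes(expr, rexp(100), rbinom(100, 1, 0.8),
                                        p_threshold = 0))
  expect_false(any(res0$passed))

  # constant gene skipped with a warning
  expr["G002", ] <- 5
  expect_warning(res <- suppressMessages(
    screen_genes(expr, rexp(100), rbinom(100, 1, 0.8))), "constant")
  expect_false("G002" %in% res$gene)
})
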