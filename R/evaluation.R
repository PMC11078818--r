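#' Harrell's concordance index
#'
#' Fraction of usable (censoring-comparable) sample pairs in which the
#' higher-scoring sample fails earlier; score ties count 0.5. Computed via
#' [survival::concordance()] with the risk-score orientation (higher score =
#' shorter survival). The standard error is the asymptotic estimator from the
#' same machinery; for small cohorts (n < 50 under `se_method = "auto"`) a
#' bootstrap standard error is used instead.
#'
#' @param scores Numeric risk scores (higher = worse prognosis).
#' @param time,event Survival data.
#' @param se_method `"auto"` (default), `"asymptotic"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List of class `concordance_result`: `c_index`, `se`, `ci95`
#'   (length-2), `n_usable_pairs`, `n`.
#' @export
harrell_cindex <- function(scores, time, event,
                           se_method = c("auto", "asymptotic", "bootstrap"),
                           n_boot = 1000L, seed = 1L) {
  se_method <- match.arg(se_method)
  validate_survival(time, event)
  n <- length(scores)
  if (n != length(time)) stopf("scores and survival data differ in length")
  if (n < 2L) stopf("need at least two samples")
  fit <- survival::concordance(survival::Surv(time, event) ~ scores,
                               reverse = TRUE)
  counts <- fit$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stopf("no usable (comparable) pairs")
  c_index <- unname(fit$concordance)
  if (se_method == "auto") se_method <- if (n < 50) "bootstrap" else "asymptotic"
  se <- if (se_method == "bootstrap") {
    with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(event[idx]) == 0) return(NA_real_)
        f <- tryCatch(survival::concordance(
          survival::Surv(time[idx], event[idx]) ~ scores[idx], reverse = TRUE),
          error = function(e) NULL)
        if (is.null(f)) NA_real_ else unname(f$concordance)
      }, numeric(1))
      stats::sd(reps, na.rm = TRUE)
    })
  } else {
    unname(sqrt(fit$var))
  }
  structure(list(c_index = c_index, se = se,
                 ci95 = c(c_index - 1.96 * se, c_index + 1.96 * se),
                 n_usable_pairs = unname(usable), n = n,
                 se_method = se_method),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (SE %.4f, 95%% CI %.4f-%.4f, %d usable pairs)\n",
              x$c_index, x$se, x$ci95[1], x$ci95[2], x$n_usable_pairs))
  invisible(x)
}

# Censoring survival function G(t) = KM of the censoring distribution,
# returned as a function with a left-limit option for weights at event times.
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tms <- sf$time[sf$n.event > 0]
  srv <- sf$surv[sf$n.event > 0]
  function(t, left = FALSE) {
    if (!length(tms)) return(rep(1, length(t)))
    vapply(t, function(u) {
      idx <- if (left) which(tms < u) else which(tms <= u)
      if (!length(idx)) 1 else srv[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent cumulative/dynamic AUC with censoring weights
#'
#' Discrimination between samples failing by horizon `t` (cases) and samples
#' still at risk beyond `t` (controls), weighted by inverse probability of
#' censoring: cases are weighted by `1/G(T_i-)` and controls by `1/G(t)`,
#' where `G` is the Kaplan-Meier estimate of the censoring distribution on
#' the evaluation cohort itself. Without censoring this reduces exactly to
#' the Mann-Whitney rank-sum AUC of the status at `t`. Horizons with no
#' prior events or no samples at risk beyond them are skipped with a warning.
#'
#' @param scores Numeric risk scores (higher = worse prognosis).
#' @param time,event Survival data.
#' @param horizons Numeric vector of evaluation times (e.g. `c(12, 24, 36)`
#'   months).
#' @return data.frame with `horizon`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(scores, time, event, horizons = c(12, 24, 36)) {
  validate_survival(time, event)
  if (length(scores) != length(time)) stopf("scores and survival data differ in length")
  G <- censoring_km(time, event)
  rows <- lapply(horizons, function(h) {
    cases <- which(time <= h & event == 1)
    controls <- which(time > h)
    if (!length(cases) || !length(controls)) {
      warnf("horizon %g skipped: needs events before it and samples at risk after it", h)
      return(NULL)
    }
    w_case <- 1 / G(time[cases], left = TRUE)
    w_ctrl <- rep(1 / G(h), length(controls))
    conc <- outer(scores[cases], scores[controls],
                  function(a, b) (a > b) + 0.5 * (a == b))
    wmat <- outer(w_case, w_ctrl)
    data.frame(horizon = h, auc = sum(wmat * conc) / sum(wmat),
               n_cases = length(cases), n_controls = length(controls))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no admissible horizon")
  out
}

#' Random-effects meta-analysis of concordance indices
#'
#' DerSimonian-Laird pooling: the between-study variance `tau2` is the
#' method-of-moments estimate from Cochran's Q, and studies are combined with
#' inverse-variance weights `1/(se^2 + tau2)` (via
#' [metafor::rma()] with `method = "DL"`). With `tau2 = 0` the pooled value
#' equals the fixed-effect inverse-variance estimate; a single study is
#' returned as its own pooled result.
#'
#' @param estimates Numeric vector of per-study C-indices.
#' @param ses Positive standard errors, same length.
#' @return List of class `meta_result`: `pooled`, `se`, `ci95`, `tau2`,
#'   `weights` (normalized to sum 1), `k`.
#' @export
meta_cindex <- function(estimates, ses) {
  if (length(estimates) != length(ses)) stopf("estimates and ses differ in length")
  if (!length(estimates)) stopf("need at least one study")
  if (any(!is.finite(estimates)) || any(!is.finite(ses)) || any(ses <= 0)) {
    stopf("estimates must be finite and ses positive")
  }
  if (length(estimates) == 1L) {
    return(structure(list(pooled = estimates, se = ses,
                          ci95 = c(estimates - 1.96 * ses, estimates + 1.96 * ses),
                          tau2 = 0, weights = 1, k = 1L),
                     class = "meta_result"))
  }
  fit <- metafor::rma(yi = estimates, sei = ses, method = "DL")
  w <- 1 / (ses^2 + fit$tau2)
  structure(list(pooled = as.numeric(fit$beta), se = fit$se,
                 ci95 = c(fit$ci.lb, fit$ci.ub), tau2 = fit$tau2,
                 weights = w / sum(w), k = length(estimates)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("pooled C %.4f (SE %.4f, 95%% CI %.4f-%.4f, tau2 %.5f, k = %d)\n",
              x$pooled, x$se, x$ci95[1], x$ci95[2], x$tau2, x$k))
  invisible(x)
}

#' Compare prognostic models across cohorts
#'
#' Computes Harrell's C per model per cohort on identical sample sets
#' (pairwise-complete comparisons are refused: within a cohort every model
#' must score exactly the same samples) and pools each model across cohorts
#' by DerSimonian-Laird random-effects meta-analysis. Staging systems enter
#' as ordinal scores (ISS 1/2/3, refined tiers 1/2/3), which is sufficient
#' for a rank-based index.
#'
#' @param model_scores Named list (one element per model) of named lists
#'   (one element per cohort) of numeric score vectors.
#' @param cohort_surv Named list (per cohort) of lists with `time` and
#'   `event` vectors aligned with the score vectors.
#' @return List with `per_cohort` (data.frame: `model`, `cohort`, `c_index`,
#'   `se`, `lo`, `hi`, `n`), `meta` (named list of `meta_result` per model;
#'   models missing a cohort are excluded from the meta with a message) and
#'   `ranking` (model names by decreasing pooled C).
#' @export
compare_models <- function(model_scores, cohort_surv) {
  if (is.null(names(model_scores)) || is.null(names(cohort_surv))) {
    stopf("model_scores and cohort_surv must be named")
  }
  cohorts <- names(cohort_surv)
  for (co in cohorts) {
    ns <- vapply(model_scores, function(m)
      if (co %in% names(m)) length(m[[co]]) else NA_integer_, integer(1))
    ns <- ns[!is.na(ns)]
    if (length(unique(ns)) > 1L) {
      stopf("cohort '%s': models score different sample sets (%s)",
            co, paste(ns, collapse = ", "))
    }
    if (length(ns) && ns[1] != length(cohort_surv[[co]]$time)) {
      stopf("cohort '%s': scores and survival data differ in length", co)
    }
  }
  per <- list()
  meta <- list()
  for (mod in names(model_scores)) {
    have <- intersect(cohorts, names(model_scores[[mod]]))
    if (length(have) < length(cohorts)) {
      msgf("compare_models: model '%s' missing cohort(s) %s; excluded from its meta",
           mod, paste(setdiff(cohorts, have), collapse = ", "))
    }
    res <- lapply(have, function(co) {
      s <- cohort_surv[[co]]
      cc <- harrell_cindex(model_scores[[mod]][[co]], s$time, s$event)
      data.frame(model = mod, cohort = co, c_index = cc$c_index, se = cc$se,
                 lo = cc$ci95[1], hi = cc$ci95[2], n = cc$n,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    per[[mod]] <- res
    meta[[mod]] <- meta_cindex(res$c_index, res$se)
  }
  per_cohort <- do.call(rbind, per)
  rownames(per_cohort) <- NULL
  pooled <- vapply(meta, function(m) m$pooled, numeric(1))
  list(per_cohort = per_cohort, meta = meta,
       ranking = names(sort(pooled, decreasing = TRUE)))
}
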