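#' Fit a Cox proportional-hazards model
#'
#' Thin, validated interface to [survival::coxph()] with Efron handling of
#' tied event times and a tightened convergence tolerance. Used for the
#' univariate screening fits and for the multivariable independence analysis
#' (risk group adjusted for age, gender and ISS).
#'
#' @param x Numeric vector, matrix or data.frame of covariates.
#' @param time,event Survival time (months) and event indicator (1 = death).
#' @return A data.frame with one row per covariate: `term`, `coef`,
#'   `hazard_ratio`, `se`, `z`, `p`. Attributes `converged` and `separation`
#'   flag fitting trouble (monotone likelihood / infinite coefficients are
#'   reported, never hidden).
#' @export
fit_cox <- function(x, time, event) {
  validate_survival(time, event)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1,
                                   dimnames = list(NULL, "x"))
  x <- as.data.frame(x)
  if (nrow(x) != length(time)) stopf("covariates and survival data differ in length")
  const <- vapply(x, function(col) {
    v <- if (is.numeric(col)) col else as.integer(factor(col))
    length(unique(v)) < 2L
  }, logical(1))
  if (any(const)) {
    stopf("constant covariate(s): %s", paste(names(x)[const], collapse = ", "))
  }
  dat <- cbind(x, .time = time, .event = event)
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-11,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w),
                ignore.case = TRUE)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s),
                    coef = s[, "coef"],
                    hazard_ratio = s[, "exp(coef)"],
                    se = s[, "se(coef)"],
                    z = s[, "z"],
                    p = s[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "converged") <- fit$iter < 100
  attr(out, "separation") <- separation
  if (separation) warnf("fit_cox: possible separation (monotone likelihood)")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event Survival time and event indicator.
#' @return A list of class `km_estimate` with `time` (event times), `surv`
#'   (the estimate just after each event time), `n_risk`, `n_event`, and
#'   `sfun`, a right-continuous step function with `sfun(0) == 1`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stopf("empty survival data")
  if (length(time) != length(event)) stopf("time/event length mismatch")
  if (any(time < 0)) stopf("negative survival time(s)")
  if (!all(event %in% c(0, 1))) stopf("event indicator must be 0 or 1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  times <- sf$time[keep]
  surv <- sf$surv[keep]
  sfun <- if (length(times)) {
    stats::stepfun(times, c(1, surv), right = FALSE)
  } else {
    function(t) rep(1, length(t))
  }
  structure(list(time = times, surv = surv,
                 n_risk = sf$n.risk[keep], n_event = sf$n.event[keep],
                 sfun = sfun),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: %d event time(s), S(max) = %.4f\n",
              length(x$time),
              if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected chi-square test via
#' [survival::survdiff()]; supports more than two groups, as needed when
#' comparing the three refined staging tiers.
#'
#' @param groups Group labels (factor/character/numeric), one per sample.
#' @param time,event Survival time and event indicator.
#' @return List with `statistic` (chi-square), `df` and `p`.
#' @export
logrank_test <- function(groups, time, event) {
  validate_survival(time, event)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("log-rank test needs at least 2 groups")
  if (any(table(groups) == 0)) stopf("empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

# Log-rank (Nelson-Aalen) scores: a_i = event_i - cumulative hazard at time_i.
# Sum of scores is the martingale residual at beta = 0.
logrank_scores <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_sorted <- time[ord]
  d_sorted <- event[ord]
  # at-risk count just before each time; tied times share one risk set
  n_risk <- n - rank(t_sorted, ties.method = "min") + 1
  grp <- cumsum(!duplicated(t_sorted))
  d_at <- tapply(d_sorted, grp, sum)
  r_at <- tapply(n_risk, grp, max)
  haz <- cumsum(d_at / r_at)
  a <- numeric(n)
  a[ord] <- d_sorted - haz[grp]
  a
}

#' Maximally selected log-rank cutpoint
#'
#' Finds the threshold on a continuous score that best separates survival,
#' in the sense of the maximally selected standardized log-rank statistic.
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' score values whose induced split leaves at least `ceiling(minprop * n)`
#' samples on each side. For each candidate the statistic is the permutation-
#' standardized sum of log-rank scores in the low group; the smallest
#' threshold attaining the maximum is returned.
#'
#' @param score Numeric vector (e.g. risk scores or a gene's expression).
#' @param time,event Survival time and event indicator.
#' @param minprop Minimum fraction of samples in each group (default 0.10).
#' @return A list of class `cutpoint`: `threshold`, `statistic` (standardized
#'   maximal statistic), `n_low`, `n_high`.
#' @export
max_selected_cutpoint <- function(score, time, event, minprop = 0.10) {
  validate_survival(time, event)
  n <- length(score)
  if (n != length(time)) stopf("score and survival data differ in length")
  if (anyNA(score)) stopf("missing score values")
  if (length(unique(score)) < 2L) stopf("no admissible cutpoint: score is constant")
  if (!(minprop > 0 && minprop < 0.5)) stopf("minprop must be in (0, 0.5)")

  a <- logrank_scores(time, event)
  ord <- order(score)
  s_sorted <- score[ord]
  a_sorted <- a[ord]
  abar <- mean(a)
  ss <- sum((a - abar)^2)
  if (ss <= 0) stopf("degenerate log-rank scores (no events?)")

  min_n <- ceiling(minprop * n)
  cum_a <- cumsum(a_sorted)
  # candidate split after position k: low group = first k sorted samples
  k <- seq_len(n - 1)
  distinct <- s_sorted[k] < s_sorted[k + 1]
  admissible <- distinct & k >= min_n & (n - k) >= min_n
  if (!any(admissible)) stopf("no admissible cutpoint within the minprop window")
  k_adm <- k[admissible]
  n1 <- k_adm
  stat <- abs(cum_a[k_adm] - n1 * abar) /
    sqrt(n1 * (n - n1) / (n * (n - 1)) * ss)
  best <- which.max(stat)  # which.max takes the first (smallest threshold) on ties
  kb <- k_adm[best]
  structure(list(threshold = (s_sorted[kb] + s_sorted[kb + 1]) / 2,
                 statistic = stat[best],
                 p_corrected = p_lausen(stat[best], minprop, 1 - minprop),
                 n_low = kb, n_high = n - kb),
            class = "cutpoint")
}

# Lausen-Schumacher (1992) approximation to the null tail probability of the
# maximally selected standardized statistic over split quantiles
# [minprop, maxprop]; corrects the p-value for threshold selection.
p_lausen <- function(b, minprop, maxprop) {
  if (b <= 0) return(1)
  db <- stats::dnorm(b)
  p <- 4 * db / b +
    db * (b - 1 / b) * log((maxprop * (1 - minprop)) / ((1 - maxprop) * minprop))
  min(max(p, 0), 1)
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf("cutpoint: threshold %.6g (standardized statistic %.3f; %d low / %d high)\n",
              x$threshold, x$statistic, x$n_low, x$n_high))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wrapper over
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\]; `NA` is an error.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues)) stopf("NA p-value")
  if (any(pvalues < 0 | pvalues > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen candidate genes for prognostic association
#'
#' For each candidate gene, fits a univariate Cox model on its expression and
#' a Kaplan-Meier / log-rank comparison of the two groups split at the gene's
#' maximally selected cutpoint. A gene passes when either test falls below
#' `p_threshold` (the union rule; set `rule = "intersection"` to require
#' both). No multiplicity adjustment is applied to the screening decisions —
#' BH q-values are reported for information only. By default the
#' cutpoint-based log-rank p is the plain two-group test at the selected
#' threshold, uncorrected for the threshold search — a deliberately
#' anti-conservative screening choice whose null pass rate well exceeds the
#' nominal level; `km_p = "corrected"` switches to the Lausen-Schumacher
#' selection-adjusted p-value of the maximal statistic.
#'
#' @param expr Genes-x-samples matrix.
#' @param time,event Survival data aligned with `expr`'s columns.
#' @param genes Candidate genes (default: all rows of `expr`).
#' @param p_threshold Screening threshold (default 0.01).
#' @param minprop Minimum group proportion for the cutpoint (default 0.10).
#' @param rule `"union"` (default) or `"intersection"` of the two tests.
#' @param km_p `"uncorrected"` (default) or `"corrected"` for the cutpoint
#'   selection.
#' @return data.frame per gene: `gene`, `coef`, `hazard_ratio`, `p_cox`,
#'   `cutpoint`, `p_km`, `q_cox`, `q_km`, `passed`. Constant genes are
#'   skipped with a warning.
#' @export
screen_genes <- function(expr, time, event, genes = rownames(expr),
                         p_threshold = 0.01, minprop = 0.10,
                         rule = c("union", "intersection"),
                         km_p = c("uncorrected", "corrected")) {
  rule <- match.arg(rule)
  km_p <- match.arg(km_p)
  validate_expression(expr)
  validate_survival(time, event)
  if (ncol(expr) != length(time)) stopf("expression and survival data differ in samples")
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stopf("candidate gene(s) not in expression matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  const <- genes[apply(expr[genes, , drop = FALSE], 1,
                       function(v) length(unique(v)) < 2L)]
  if (length(const)) {
    warnf("skipping constant gene(s): %s", paste(utils::head(const, 5), collapse = ", "))
    genes <- setdiff(genes, const)
  }
  if (!length(genes)) stopf("no screenable genes")

  rows <- lapply(genes, function(g) {
    x <- expr[g, ]
    cx <- fit_cox(x, time, event)
    cp <- tryCatch(max_selected_cutpoint(x, time, event, minprop = minprop),
                   error = function(e) NULL)
    if (is.null(cp)) {
      thr <- NA_real_; pkm <- NA_real_
    } else {
      thr <- cp$threshold
      pkm <- if (km_p == "corrected") cp$p_corrected
             else logrank_test(x > thr, time, event)$p
    }
    data.frame(gene = g, coef = cx$coef, hazard_ratio = cx$hazard_ratio,
               p_cox = cx$p, cutpoint = thr, p_km = pkm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_cox <- bh_fdr(out$p_cox)
  out$q_km <- ifelse(is.na(out$p_km), NA_real_,
                     bh_fdr(ifelse(is.na(out$p_km), 1, out$p_km)))
  km_pass <- !is.na(out$p_km) & out$p_km < p_threshold
  cox_pass <- out$p_cox < p_threshold
  out$passed <- if (rule == "union") cox_pass | km_pass else cox_pass & km_pass
  msgf("screen_genes: %d of %d genes passed (p < %g, %s rule)",
       sum(out$passed), nrow(out), p_threshold, rule)
  out
}
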