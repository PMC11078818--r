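#' Combine cell-death risk group with ISS stage
#'
#' Crosses the binary cell-death risk group (high/low) with the ISS stage
#' (1/2/3) into six strata labelled `"low_1"` ... `"high_3"`. Samples with a
#' missing ISS stage get `NA` and are reported; they are excluded from
#' staging, never imputed.
#'
#' @param risk_group Character/factor vector of `"high"`/`"low"`.
#' @param iss Integer vector with values 1, 2, 3 or `NA`.
#' @return Factor with the six levels `low_1, low_2, low_3, high_1, high_2,
#'   high_3` (and `NA` where ISS is missing).
#' @export
combine_strata <- function(risk_group, iss) {
  if (length(risk_group) != length(iss)) stopf("risk_group and iss differ in length")
  risk_group <- as.character(risk_group)
  if (!all(risk_group %in% c("high", "low"))) {
    stopf("risk_group values must be 'high' or 'low'")
  }
  if (!all(is.na(iss) | iss %in% 1:3)) stopf("iss must be 1, 2, 3 or NA")
  n_missing <- sum(is.na(iss))
  if (n_missing) {
    msgf("combine_strata: %d sample(s) excluded for missing ISS", n_missing)
  }
  labels <- ifelse(is.na(iss), NA_character_, paste(risk_group, iss, sep = "_"))
  factor(labels, levels = c("low_1", "low_2", "low_3",
                            "high_1", "high_2", "high_3"))
}

# The published six-to-three merge:
#   low_1, low_2          -> low
#   high_1, low_3         -> medium
#   high_2, high_3        -> high
.refined_iss_map <- c(low_1 = "low", low_2 = "low",
                      high_1 = "medium", low_3 = "medium",
                      high_2 = "high", high_3 = "high")

#' Collapse the six risk-by-ISS strata to the refined three-tier staging
#'
#' Applies the fixed published merge: `low_1`/`low_2` form the low tier,
#' `high_1`/`low_3` the medium tier, and `high_2`/`high_3` the high tier. The
#' map is a total function of the stratum and is deliberately hard-coded
#' rather than re-derived per dataset; use [stratum_logrank_table()] to check
#' whether the merge is supported by your own data.
#'
#' @param stratum Factor/character vector of the six stratum labels (as from
#'   [combine_strata()]); `NA` passes through.
#' @return Ordered factor with levels `low < medium < high`.
#' @export
refine_iss <- function(stratum) {
  stratum <- as.character(stratum)
  known <- !is.na(stratum)
  bad <- known & !(stratum %in% names(.refined_iss_map))
  if (any(bad)) {
    stopf("unknown stratum label(s): %s",
          paste(utils::head(unique(stratum[bad]), 5), collapse = ", "))
  }
  out <- rep(NA_character_, length(stratum))
  out[known] <- .refined_iss_map[stratum[known]]
  factor(out, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Pairwise log-rank comparisons between the six risk-by-ISS strata
#'
#' Exploratory check of whether the fixed six-to-three merge is supported by
#' a dataset: reports the log-rank p-value for every pair of strata, so that
#' merged strata can be seen to have similar survival and non-merged ones
#' not.
#'
#' @param stratum Factor of six-stratum labels (as from [combine_strata()]).
#' @param time,event Survival data aligned with `stratum`.
#' @return data.frame with `stratum_a`, `stratum_b`, `n_a`, `n_b`,
#'   `statistic`, `p` (strata absent from the data are skipped).
#' @export
stratum_logrank_table <- function(stratum, time, event) {
  keep <- !is.na(stratum)
  stratum <- factor(stratum[keep])
  time <- time[keep]; event <- event[keep]
  present <- levels(droplevels(stratum))
  if (length(present) < 2L) stopf("need at least two occupied strata")
  combos <- utils::combn(present, 2)
  rows <- apply(combos, 2, function(ab) {
    sel <- stratum %in% ab
    res <- tryCatch(logrank_test(droplevels(stratum[sel]), time[sel], event[sel]),
                    error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.frame(stratum_a = ab[1], stratum_b = ab[2],
               n_a = sum(stratum == ab[1]), n_b = sum(stratum == ab[2]),
               statistic = res$statistic, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stage samples end-to-end
#'
#' Convenience wrapper joining per-sample risk results with a clinical table
#' and returning the six-stratum and refined three-tier assignments.
#'
#' @param risk data.frame from [compute_risk_scores()].
#' @param clinical Clinical data.frame with `sample_id` and `iss`.
#' @return data.frame with `sample_id`, `risk_score`, `risk_group`, `iss`,
#'   `stratum`, `refined_iss` (samples without ISS carry `NA` in the last
#'   two columns).
#' @export
stage_samples <- function(risk, clinical) {
  idx <- match(risk$sample_id, clinical$sample_id)
  if (anyNA(idx)) stopf("risk table contains sample(s) absent from the clinical table")
  iss <- clinical$iss[idx]
  stratum <- combine_strata(risk$risk_group, iss)
  data.frame(sample_id = risk$sample_id,
             risk_score = risk$risk_score,
             risk_group = risk$risk_group,
             iss = iss,
             stratum = stratum,
             refined_iss = refine_iss(stratum),
             stringsAsFactors = FALSE)
}
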