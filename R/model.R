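#' Construct a pair model object
#'
#' The fitted signature: an ordered list of gene pairs with nonzero Cox
#' coefficients plus the training risk cutoff. The per-sample risk score is
#' `sum(coefficient * pair_value)` where each pair value is +1/-1 recomputed
#' from the scoring cohort's expression, and `risk_group` is `"high"` exactly
#' when the score exceeds `risk_cutoff`.
#'
#' @param pairs data.frame with columns `anchor`, `partner`, `coefficient`.
#' @param risk_cutoff Finite numeric threshold.
#' @param provenance Optional list of training parameters (thresholds, lambda
#'   rules, seed, stage counts).
#' @return A validated object of class `pair_model`.
#' @export
pair_model <- function(pairs, risk_cutoff, provenance = list()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  model <- structure(list(pairs = pairs, risk_cutoff = as.numeric(risk_cutoff),
                          provenance = provenance),
                     class = "pair_model")
  validate_pair_model(model)
  model
}

validate_pair_model <- function(model) {
  if (!inherits(model, "pair_model")) stopf("not a pair_model")
  p <- model$pairs
  if (!all(c("anchor", "partner", "coefficient") %in% names(p))) {
    stopf("model pairs need columns anchor, partner, coefficient")
  }
  if (!nrow(p)) stopf("pair model must contain at least one pair")
  if (any(p$anchor == p$partner)) stopf("self-pair in model")
  key <- ifelse(p$anchor < p$partner, paste(p$anchor, p$partner, sep = "\r"),
                paste(p$partner, p$anchor, sep = "\r"))
  if (anyDuplicated(key)) stopf("duplicate unordered pair in model")
  if (any(!is.finite(p$coefficient)) || any(p$coefficient == 0)) {
    stopf("model coefficients must be finite and nonzero")
  }
  if (!is.finite(model$risk_cutoff)) stopf("risk cutoff must be finite")
  invisible(model)
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf("pair_model: %d gene pairs, risk cutoff %.6g\n",
              nrow(x$pairs), x$risk_cutoff))
  print(utils::head(x$pairs, 10), row.names = FALSE)
  if (nrow(x$pairs) > 10) cat(sprintf("... and %d more\n", nrow(x$pairs) - 10))
  invisible(x)
}

#' Cross-validated LASSO Cox path
#'
#' Fits an L1-penalized Cox model over a log-spaced lambda path with
#' cross-validated partial-likelihood deviance ([glmnet::cv.glmnet()]) and
#' returns the active set at the lambda chosen by the stated rule. Fold
#' assignment is stratified by event status and fully determined by `seed`.
#'
#' @param X Samples-x-features numeric matrix (column names required).
#' @param time,event Survival data aligned with `X`'s rows.
#' @param lambda_rule `"1se"` (deviance minimum plus one standard error, the
#'   default) or `"min"`.
#' @param n_folds Number of CV folds (default 10; reduced with a message when
#'   there are fewer than 2 events per fold).
#' @param seed Integer seed for the fold assignment.
#' @param standardize Standardize columns internally before penalization
#'   (default TRUE; use FALSE for +1/-1 pair features, which are already on a
#'   common scale).
#' @param lambda_min_ratio Smallest path lambda as a fraction of the largest
#'   (default 0.01). glmnet's own default (1e-4 when samples outnumber
#'   features) extends the path into near-unpenalized territory, where
#'   coordinate descent over many collinear discrete features converges very
#'   slowly; a floor of 0.01 keeps the path far below any lambda the CV rules
#'   select in practice. A warning is raised if the chosen lambda lands on the
#'   path floor, signalling that the floor may be binding.
#' @return List with `features` (selected column names), `coefficients`
#'   (named, nonzero), `lambda`, `lambda_rule`, `cv` (the cv.glmnet object)
#'   and `foldid`. An empty active set is allowed with a warning.
#' @export
lasso_cox_path <- function(X, time, event, lambda_rule = c("1se", "min"),
                           n_folds = 10L, seed = 1L, standardize = TRUE,
                           lambda_min_ratio = 0.01) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopf("X must have column names")
  n_events <- validate_survival(time, event, min_events = 2L)
  if (nrow(X) != length(time)) stopf("X and survival data differ in samples")
  if (n_events < 2L * n_folds) {
    n_folds <- max(3L, n_events %/% 2L)
    msgf("lasso_cox_path: reducing to %d folds (%d events)", n_folds, n_events)
  }
  foldid <- with_seed(seed, {
    f <- integer(length(time))
    for (grp in unique(event)) {
      idx <- which(event == grp)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  y <- survival::Surv(time, event)
  if (!is.numeric(lambda_min_ratio) || length(lambda_min_ratio) != 1 ||
      !is.finite(lambda_min_ratio) || lambda_min_ratio <= 0 ||
      lambda_min_ratio >= 1) {
    stopf("lambda_min_ratio must be a single number in (0, 1)")
  }
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                          foldid = foldid, standardize = standardize,
                          lambda.min.ratio = lambda_min_ratio)
  lambda <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  if (lambda <= min(cv$lambda) * (1 + 1e-8)) {
    warnf(paste("lasso_cox_path: lambda.%s sits at the bottom of the path;",
                "consider a smaller lambda_min_ratio"), lambda_rule)
  }
  beta <- as.matrix(stats::coef(cv, s = lambda))[, 1]
  active <- beta[beta != 0]
  if (!length(active)) warnf("lasso_cox_path: empty active set at lambda %s", lambda_rule)
  msgf("lasso_cox_path: %d of %d features active at lambda.%s = %.5g",
       length(active), ncol(X), lambda_rule, lambda)
  list(features = names(active), coefficients = active, lambda = lambda,
       lambda_rule = lambda_rule, cv = cv, foldid = foldid)
}

#' Default configuration for signature training
#'
#' @param p_threshold Gene-screening p-value threshold (default 0.01).
#' @param freq_low,freq_high Pair prevalence retention bounds (default
#'   0.20/0.80, inclusive).
#' @param pair_fdr BH false-discovery-rate threshold for pair retention
#'   (default 0.05; 0.01 is the stricter published alternative).
#' @param lambda_rule_genes,lambda_rule_pairs Lambda rule for the two
#'   penalized stages (`"1se"` default for both; `"min"` available).
#' @param minprop Minimum group proportion for maximally selected cutpoints.
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @param partner_genes Optional partner gene universe for pairing (default:
#'   all expressed genes minus the anchors).
#' @return A list of class `cd_config`.
#' @export
cd_config <- function(p_threshold = 0.01, freq_low = 0.20, freq_high = 0.80,
                      pair_fdr = 0.05, lambda_rule_genes = "1se",
                      lambda_rule_pairs = "1se", minprop = 0.10,
                      n_folds = 10L, seed = 1L, partner_genes = NULL) {
  structure(list(p_threshold = p_threshold, freq_low = freq_low,
                 freq_high = freq_high, pair_fdr = pair_fdr,
                 lambda_rule_genes = match.arg(lambda_rule_genes, c("1se", "min")),
                 lambda_rule_pairs = match.arg(lambda_rule_pairs, c("1se", "min")),
                 minprop = minprop, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), partner_genes = partner_genes),
            class = "cd_config")
}

#' Train the cell-death gene-pair prognostic signature
#'
#' Runs the nested selection pipeline on a training cohort, in order:
#' \enumerate{
#'   \item screen candidate genes by univariate Cox / optimal-cutpoint
#'     log-rank (union rule, `p_threshold`);
#'   \item stage-1 cross-validated LASSO Cox on the screened genes'
#'     expression — the surviving genes are the anchors;
#'   \item build the +1/-1 pair matrix, anchors against the partner universe;
#'   \item drop pairs with +1 prevalence outside `[freq_low, freq_high]`;
#'   \item per-pair univariate Cox with BH-FDR retention at `pair_fdr`;
#'   \item stage-2 cross-validated LASSO Cox on the retained pair features
#'     (unstandardized) — the active pairs and coefficients are the model;
#'   \item maximally selected log-rank cutpoint on the training risk scores.
#' }
#' Any stage that leaves zero features aborts with an error naming the
#' stage. Feature counts per stage are logged and stored in the model's
#' provenance, and the whole run is reproducible from `config$seed`.
#'
#' @param expr Genes-x-samples training expression matrix.
#' @param clinical Clinical data.frame (needs `sample_id`, `os_time`,
#'   `os_event`) or `NULL` if `time`/`event` are given.
#' @param candidate_genes Candidate (cell-death) gene symbols.
#' @param config A [cd_config()].
#' @param time,event Optional explicit survival vectors aligned with
#'   `expr`'s columns (alternative to `clinical`).
#' @return A fitted [pair_model].
#' @export
train_cell_death_model <- function(expr, clinical = NULL, candidate_genes,
                                   config = cd_config(),
                                   time = NULL, event = NULL) {
  validate_expression(expr)
  if (is.null(time)) {
    aligned <- align_samples(expr, clinical)
    expr <- aligned$expression
    time <- aligned$clinical$os_time
    event <- aligned$clinical$os_event
  }
  validate_survival(time, event, min_events = 2L)
  candidate_genes <- intersect(unique(as.character(candidate_genes)), rownames(expr))
  if (!length(candidate_genes)) {
    stopf("stage 1 (screening): no candidate genes present in the expression matrix")
  }

  counts <- list(candidates = length(candidate_genes))

  # stage 1: univariate screening
  screen <- screen_genes(expr, time, event, genes = candidate_genes,
                         p_threshold = config$p_threshold,
                         minprop = config$minprop)
  screened <- screen$gene[screen$passed]
  counts$screened <- length(screened)
  if (!length(screened)) stopf("stage 1 (screening): zero genes passed p < %g",
                               config$p_threshold)

  # stage 2: LASSO on screened gene expression -> anchors
  anchors <- if (length(screened) == 1L) {
    screened
  } else {
    fit1 <- lasso_cox_path(t(expr[screened, , drop = FALSE]), time, event,
                           lambda_rule = config$lambda_rule_genes,
                           n_folds = config$n_folds, seed = config$seed,
                           standardize = TRUE)
    fit1$features
  }
  counts$anchors <- length(anchors)
  if (!length(anchors)) stopf("stage 2 (gene LASSO): zero anchor genes selected")

  # stage 3: pair matrix
  gpm <- build_pair_matrix(expr, anchors, partner_genes = config$partner_genes)
  counts$pairs_built <- nrow(gpm$pairs)

  # stage 4: prevalence filter
  gpm <- filter_pairs_by_frequency(gpm, config$freq_low, config$freq_high)
  counts$pairs_prevalent <- nrow(gpm$pairs)
  if (!nrow(gpm$pairs)) stopf("stage 4 (prevalence filter): zero pairs retained")

  # stage 5: per-pair univariate Cox + BH-FDR
  p_pair <- apply(gpm$values, 1, function(v) fit_cox(v, time, event)$p)
  q_pair <- bh_fdr(p_pair)
  keep <- q_pair < config$pair_fdr
  counts$pairs_fdr <- sum(keep)
  if (!any(keep)) stopf("stage 5 (pair FDR): zero pairs at q < %g", config$pair_fdr)
  gpm <- structure(list(pairs = gpm$pairs[keep, , drop = FALSE],
                        values = gpm$values[keep, , drop = FALSE]),
                   class = "gene_pair_matrix")

  # stage 6: LASSO on pair features -> final signature
  final <- if (nrow(gpm$pairs) == 1L) {
    cf <- fit_cox(gpm$values[1, ], time, event)$coef
    stats::setNames(cf, rownames(gpm$values))
  } else {
    fit2 <- lasso_cox_path(t(gpm$values), time, event,
                           lambda_rule = config$lambda_rule_pairs,
                           n_folds = config$n_folds, seed = config$seed,
                           standardize = FALSE)
    fit2$coefficients
  }
  counts$pairs_final <- length(final)
  if (!length(final)) stopf("stage 6 (pair LASSO): zero pairs selected")
  sel <- match(names(final), rownames(gpm$values))
  pairs <- data.frame(anchor = gpm$pairs$anchor[sel],
                      partner = gpm$pairs$partner[sel],
                      coefficient = unname(final),
                      stringsAsFactors = FALSE)

  # stage 7: risk cutoff on training scores
  scores <- as.numeric(crossprod(gpm$values[sel, , drop = FALSE], pairs$coefficient))
  cut <- max_selected_cutpoint(scores, time, event, minprop = config$minprop)
  counts$n_train <- length(time)

  msgf(paste0("train_cell_death_model: ", paste(names(counts), unlist(counts),
                                                sep = "=", collapse = ", ")))
  pair_model(pairs, risk_cutoff = cut$threshold,
             provenance = c(config[setdiff(names(config), "partner_genes")],
                            list(stage_counts = counts)))
}

#' Compute risk scores and risk groups from a fitted pair model
#'
#' Recomputes each model pair's +1/-1 value from the scoring cohort's own
#' expression, takes the coefficient-weighted sum, and assigns `"high"` risk
#' exactly when the score exceeds the model's training cutoff — the cutoff is
#' applied unchanged to every cohort, never re-estimated. Because only
#' within-sample gene order enters, scores are identical under any strictly
#' increasing per-sample transformation of the input.
#'
#' @param model A [pair_model].
#' @param expr Genes-x-samples matrix containing every model gene (missing
#'   genes are an error; no imputation).
#' @return data.frame with `sample_id`, `risk_score`, `risk_group`.
#' @export
compute_risk_scores <- function(model, expr) {
  validate_pair_model(model)
  validate_expression(expr)
  needed <- unique(c(model$pairs$anchor, model$pairs$partner))
  missing <- setdiff(needed, rownames(expr))
  if (length(missing)) {
    stopf("model gene(s) absent from expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  pv <- ifelse(expr[model$pairs$anchor, , drop = FALSE] >
                 expr[model$pairs$partner, , drop = FALSE], 1, -1)
  scores <- as.numeric(crossprod(pv, model$pairs$coefficient))
  data.frame(sample_id = colnames(expr),
             risk_score = scores,
             risk_group = ifelse(scores > model$risk_cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}
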