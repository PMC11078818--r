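#' Simulation configuration for multi-cohort survival cohorts
#'
#' Describes a synthetic multi-cohort study with the structure the pair-based
#' workflow assumes: heterogeneous continuous gene expression, a latent
#' linear predictor built from designated informative gene pairs, right-
#' censored exponential proportional-hazards survival, ISS stages whose
#' distribution shifts with the hazard, and per-cohort strictly monotone
#' platform/batch distortions.
#'
#' Defaults emulate a five-cohort multiple-myeloma study: cohort sizes
#' (796, 415, 558, 55, 256), ~70% censoring (most patients alive at last
#' follow-up), exponential baseline with median overall survival of 60
#' months, and pair effect magnitudes drawn uniformly from \[0.3, 1\].
#' `n_genes = 200` keeps the transcriptome at desk scale while leaving a
#' large universe of uninformative pairs.
#'
#' @param n_samples Integer vector of per-cohort sample sizes.
#' @param n_genes Number of genes.
#' @param n_informative_pairs Number of truly prognostic gene pairs; built
#'   from disjoint genes so recovery is unambiguous.
#' @param pair_coefficients Optional numeric vector of true log-hazard
#'   coefficients (one per informative pair); by default magnitudes are drawn
#'   uniformly from \[0.3, 1\] with random signs.
#' @param baseline_hazard Exponential baseline hazard rate per month.
#' @param censoring_rate Target fraction censored, in \[0, 1).
#' @param iss_association_strength Non-negative coupling between the latent
#'   predictor and the ISS stage distribution (0 = independent).
#' @param batch_transforms Optional list (one element per cohort) of monotone
#'   transform specs as accepted by [apply_batch_transform()]; default is the
#'   identity for every cohort.
#' @param seed Integer seed; all randomness flows from it, and cohort `i`
#'   deterministically perturbs it by `i`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(796L, 415L, 558L, 55L, 256L),
                       n_genes = 200L,
                       n_informative_pairs = 10L,
                       pair_coefficients = NULL,
                       baseline_hazard = log(2) / 60,
                       censoring_rate = 0.70,
                       iss_association_strength = 1,
                       batch_transforms = NULL,
                       seed = 1L) {
  if (!length(n_samples) || any(n_samples < 2)) stopf("each cohort needs >= 2 samples")
  if (!is_count(n_genes) || n_genes < 4) stopf("n_genes must be an integer >= 4")
  if (!is_count(n_informative_pairs)) stopf("n_informative_pairs must be a positive integer")
  if (n_informative_pairs > n_genes * (n_genes - 1) / 2) {
    stopf("n_informative_pairs exceeds the number of possible pairs")
  }
  if (2 * n_informative_pairs > n_genes) {
    stopf("disjoint informative pairs need 2 * n_informative_pairs <= n_genes")
  }
  if (!is.null(pair_coefficients) &&
      length(pair_coefficients) != n_informative_pairs) {
    stopf("pair_coefficients must have length n_informative_pairs")
  }
  if (!(censoring_rate >= 0 && censoring_rate < 1)) {
    stopf("censoring_rate must lie in [0, 1)")
  }
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (iss_association_strength < 0) stopf("iss_association_strength must be >= 0")
  if (!is.null(batch_transforms) && length(batch_transforms) != length(n_samples)) {
    stopf("batch_transforms must have one element per cohort")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_informative_pairs = as.integer(n_informative_pairs),
                 pair_coefficients = pair_coefficients,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 iss_association_strength = iss_association_strength,
                 batch_transforms = batch_transforms,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gene panel shared across cohorts: per-gene lognormal parameters plus the
# informative pairs and their coefficients. Drawn under the base seed so all
# cohorts of a study share one truth.
sim_gene_panel <- function(config) {
  with_seed(config$seed, {
    p <- config$n_genes
    k <- config$n_informative_pairs
    genes <- sprintf("G%04d", seq_len(p))
    meanlog <- stats::runif(p, 1, 4)
    sdlog <- stats::runif(p, 0.3, 0.8)
    names(meanlog) <- names(sdlog) <- genes
    idx <- sample.int(p, 2L * k)
    anchor <- genes[idx[seq_len(k)]]
    partner <- genes[idx[k + seq_len(k)]]
    # members of a true pair share marginal parameters, so either gene wins
    # in roughly half the samples and the pair survives the prevalence filter
    meanlog[partner] <- meanlog[anchor]
    sdlog[partner] <- sdlog[anchor]
    beta <- config$pair_coefficients %||%
      (stats::runif(k, 0.3, 1.0) * sample(c(-1, 1), k, replace = TRUE))
    list(genes = genes, meanlog = meanlog, sdlog = sdlog,
         truth = data.frame(anchor = anchor, partner = partner, beta = beta,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate one cohort
#'
#' Draws gene expression gene-wise from heterogeneous lognormal
#' distributions, computes the latent linear predictor
#' `eta = sum(beta * pair_value)` over the designated informative pairs,
#' draws survival times from an exponential proportional-hazards model by
#' inverse-transform sampling, applies independent uniform censoring with the
#' upper bound solved numerically for the target censoring fraction, samples
#' ISS stages from a proportional-odds model shifted by the standardized
#' predictor, and finally applies the cohort's monotone batch distortion to
#' the expression values.
#'
#' @param config A [sim_config()].
#' @param cohort_index Which cohort of the study to generate (perturbs the
#'   seed deterministically; the gene panel and truth are shared).
#' @return List with `expression` (genes x samples matrix, after the
#'   cohort's batch transform), `clinical` (data.frame `sample_id`,
#'   `os_time`, `os_event`, `iss`, `age`, `gender`), `truth` (data.frame
#'   `anchor`, `partner`, `beta`), and `eta` (the latent predictor, for
#'   calibration checks).
#' @export
simulate_cohort <- function(config, cohort_index = 1L) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  if (!is_count(cohort_index) || cohort_index > length(config$n_samples)) {
    stopf("cohort_index out of range")
  }
  panel <- sim_gene_panel(config)
  n <- config$n_samples[cohort_index]
  p <- config$n_genes

  out <- with_seed(config$seed + cohort_index, {
    expr <- matrix(stats::rlnorm(p * n, meanlog = panel$meanlog,
                                 sdlog = panel$sdlog),
                   nrow = p,
                   dimnames = list(panel$genes,
                                   sprintf("C%d_S%04d", cohort_index, seq_len(n))))
    if (any(apply(expr, 1, function(v) length(unique(v)) < 2L)) && n > 1) {
      stopf("degenerate (constant) simulated gene")
    }
    pv <- ifelse(expr[panel$truth$anchor, , drop = FALSE] >
                   expr[panel$truth$partner, , drop = FALSE], 1, -1)
    eta <- as.numeric(crossprod(pv, panel$truth$beta))

    t_event <- -log(stats::runif(n)) / (config$baseline_hazard * exp(eta))
    if (config$censoring_rate == 0) {
      os_time <- t_event
      os_event <- rep(1L, n)
    } else {
      target <- config$censoring_rate
      g <- function(C) mean(pmin(t_event / C, 1)) - target
      upper <- max(t_event) / target * 10
      root <- tryCatch(stats::uniroot(g, lower = min(t_event) * 1e-6,
                                      upper = upper, tol = 1e-10),
                       error = function(e) stopf("infeasible censoring target %.2f", target))
      cens <- stats::runif(n, 0, root$root)
      os_event <- as.integer(t_event <= cens)
      os_time <- pmin(t_event, cens)
    }

    s <- config$iss_association_strength
    z <- if (stats::sd(eta) > 0) as.numeric(scale(eta)) else rep(0, n)
    p_le1 <- stats::plogis(stats::qlogis(1 / 3) - s * (z + 0.5))
    p_le2 <- stats::plogis(stats::qlogis(2 / 3) - s * (z + 0.5))
    u <- stats::runif(n)
    iss <- 1L + (u > p_le1) + (u > p_le2)

    clinical <- data.frame(
      sample_id = colnames(expr),
      os_time = os_time,
      os_event = os_event,
      iss = iss,
      age = round(pmax(25, stats::rnorm(n, 65, 10))),
      gender = sample(c("female", "male"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    list(expression = expr, clinical = clinical, eta = eta)
  })

  transform <- if (!is.null(config$batch_transforms)) {
    config$batch_transforms[[cohort_index]]
  } else {
    list(type = "identity")
  }
  out$expression <- apply_batch_transform(out$expression, transform)
  out$truth <- panel$truth
  out
}

#' Simulate a full multi-cohort study
#'
#' @param config A [sim_config()].
#' @return Named list (`cohort_1`, ...) of [simulate_cohort()] results that
#'   share one gene panel, truth and coefficient vector.
#' @export
simulate_study <- function(config) {
  cohorts <- lapply(seq_along(config$n_samples),
                    function(i) simulate_cohort(config, i))
  names(cohorts) <- paste0("cohort_", seq_along(cohorts))
  cohorts
}

#' Apply a strictly monotone per-sample distortion to expression values
#'
#' Emulates platform and batch effects that change the measurement scale but
#' not the within-sample ordering of genes. Supported specs:
#' `list(type = "identity")`, `list(type = "affine", a = , b = )` with
#' `a > 0`, `list(type = "power", p = )` with `p > 0` on non-negative data,
#' `list(type = "log_shift", s = )` with `x + s > 0`. Each element of `a`,
#' `b`, `p`, `s` may be a scalar or one value per sample. A plain function is
#' also accepted and checked empirically for strict monotonicity on the
#' data's values.
#'
#' @param expr Genes-x-samples matrix.
#' @param transform A transform spec (see above).
#' @return Matrix of the same shape and dimnames with the transform applied
#'   column-wise (per sample).
#' @export
apply_batch_transform <- function(expr, transform) {
  validate_expression(expr)
  if (is.function(transform)) {
    out <- apply(expr, 2, transform)
    dimnames(out) <- dimnames(expr)
    probe <- sort(unique(as.numeric(expr)))
    if (length(probe) > 1 && any(diff(transform(probe)) <= 0)) {
      stopf("transform is not strictly increasing on the data's range")
    }
    return(out)
  }
  if (!is.list(transform) || is.null(transform$type)) {
    stopf("transform must be a function or a list with a 'type' field")
  }
  per_sample <- function(v, name) {
    if (is.null(v)) stopf("transform '%s' missing parameter '%s'", transform$type, name)
    if (!length(v) %in% c(1L, ncol(expr))) {
      stopf("parameter '%s' must be scalar or one value per sample", name)
    }
    rep(v, length.out = ncol(expr))
  }
  out <- switch(
    transform$type,
    identity = expr,
    affine = {
      a <- per_sample(transform$a, "a")
      b <- per_sample(transform$b %||% 0, "b")
      if (any(a <= 0)) stopf("affine transform needs slope a > 0")
      sweep(sweep(expr, 2, a, "*"), 2, b, "+")
    },
    power = {
      p <- per_sample(transform$p, "p")
      if (any(p <= 0)) stopf("power transform needs exponent p > 0")
      if (any(expr < 0)) stopf("power transform requires non-negative expression")
      sweep(expr, 2, p, "^")
    },
    log_shift = {
      s <- per_sample(transform$s %||% 0, "s")
      shifted <- sweep(expr, 2, s, "+")
      if (any(shifted <= 0)) stopf("log_shift transform needs x + s > 0")
      log(shifted)
    },
    stopf("unknown transform type '%s'", transform$type)
  )
  dimnames(out) <- dimnames(expr)
  out
}
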