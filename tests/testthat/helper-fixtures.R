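# Small programmatic fixtures shared across test files.

toy_expression <- function(n_genes = 3, n_samples = 4) {
  m <- matrix(seq_len(n_genes * n_samples), nrow = n_genes, byrow = TRUE,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m + 0  # numeric, deterministic values 1..n laid out row-wise
}

random_expression <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rlnorm(n_genes * n_samples, meanlog = 2, sdlog = 0.7),
         nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# Exponential PH survival given a linear predictor.
random_survival <- function(eta, censor_frac = 0.3, rate = 0.02, seed = 1) {
  set.seed(seed)
  n <- length(eta)
  t_event <- -log(runif(n)) / (rate * exp(eta))
  if (censor_frac == 0) {
    list(time = t_event, event = rep(1L, n))
  } else {
    cens <- runif(n, 0, quantile(t_event, 1 - censor_frac) * 2)
    list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
  }
}

small_model <- function() {
  pair_model(pairs = data.frame(anchor = c("GA", "GB"),
                                partner = c("GX", "GY"),
                                coefficient = c(0.5, -0.2),
                                stringsAsFactors = FALSE),
             risk_cutoff = 0.15,
             provenance = list(seed = 1, lambda_rule = "1se"))
}
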