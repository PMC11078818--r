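# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf <- function(fmt, ...) message(sprintf(fmt, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopf("seed must be a single finite number, got %s", deparse(seed))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a genes-x-samples expression matrix.
validate_expression <- function(expr, min_genes = 1L, min_samples = 1L,
                                what = "expression matrix") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stopf("%s must be a numeric matrix (genes x samples)", what)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stopf("%s must carry gene ids as rownames and sample ids as colnames", what)
  }
  dup_g <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup_g)) {
    stopf("duplicate gene id(s) in %s: %s", what,
          paste(utils::head(dup_g, 5), collapse = ", "))
  }
  dup_s <- unique(colnames(expr)[duplicated(colnames(expr))])
  if (length(dup_s)) {
    stopf("duplicate sample id(s) in %s: %s", what,
          paste(utils::head(dup_s, 5), collapse = ", "))
  }
  if (anyNA(expr)) stopf("%s contains missing values", what)
  if (nrow(expr) < min_genes || ncol(expr) < min_samples) {
    stopf("%s must have at least %d genes and %d samples (got %d x %d)",
          what, min_genes, min_samples, nrow(expr), ncol(expr))
  }
  invisible(expr)
}

# Validate aligned survival vectors; returns number of events.
validate_survival <- function(time, event, min_events = 1L) {
  if (length(time) != length(event)) {
    stopf("time and event have different lengths (%d vs %d)",
          length(time), length(event))
  }
  if (anyNA(time) || anyNA(event)) stopf("time/event contain missing values")
  if (any(time < 0)) stopf("negative survival time(s)")
  if (!all(event %in% c(0, 1))) stopf("event indicator must be 0 or 1")
  n_events <- sum(event == 1)
  if (n_events < min_events) {
    stopf("need at least %d observed event(s), got %d", min_events, n_events)
  }
  invisible(n_events)
}
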