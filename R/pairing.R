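#' Build the binary gene-pair feature matrix
#'
#' For every (anchor, partner) gene pair, each sample is coded `+1` when the
#' anchor's expression strictly exceeds the partner's in that sample and `-1`
#' otherwise (ties code `-1`; the comparison is strict). Because the coding
#' depends only on the within-sample ordering of two genes, it is exactly
#' invariant to any strictly increasing per-sample transformation of the
#' expression values — the property that makes pair signatures portable
#' across platforms and batches.
#'
#' @param expr Numeric genes-x-samples matrix with dimnames.
#' @param anchor_genes Character vector of anchor genes (e.g. the screened
#'   prognostic genes). Must be present in `expr`.
#' @param partner_genes Character vector of partner genes; defaults to every
#'   gene in `expr` that is not an anchor. Self-pairs are excluded; duplicate
#'   unordered pairs (possible when anchors appear among partners) are kept
#'   once, oriented on the lexicographically first anchor.
#' @return A `gene_pair_matrix`: list with `pairs` (data.frame of `anchor`,
#'   `partner`) and `values` (integer matrix in \{+1, -1\}, pairs x samples,
#'   rownames `"anchor|partner"`), sorted lexicographically by (anchor,
#'   partner).
#' @export
build_pair_matrix <- function(expr, anchor_genes, partner_genes = NULL) {
  validate_expression(expr)
  anchor_genes <- unique(as.character(anchor_genes))
  if (!length(anchor_genes)) stopf("anchor gene set is empty")
  partner_genes <- unique(as.character(
    partner_genes %||% setdiff(rownames(expr), anchor_genes)))
  missing <- setdiff(c(anchor_genes, partner_genes), rownames(expr))
  if (length(missing)) {
    stopf("gene(s) not in expression matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  if (!length(partner_genes)) stopf("partner gene set is empty")

  pairs <- expand.grid(partner = partner_genes, anchor = anchor_genes,
                       stringsAsFactors = FALSE)[, c("anchor", "partner")]
  pairs <- pairs[pairs$anchor != pairs$partner, , drop = FALSE]
  pairs <- pairs[order(pairs$anchor, pairs$partner), , drop = FALSE]
  key <- ifelse(pairs$anchor < pairs$partner,
                paste(pairs$anchor, pairs$partner, sep = "\r"),
                paste(pairs$partner, pairs$anchor, sep = "\r"))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  if (!nrow(pairs)) stopf("no admissible gene pairs (anchors equal partners?)")
  rownames(pairs) <- NULL

  a <- expr[pairs$anchor, , drop = FALSE]
  b <- expr[pairs$partner, , drop = FALSE]
  values <- matrix(ifelse(a > b, 1L, -1L), nrow = nrow(pairs),
                   dimnames = list(paste(pairs$anchor, pairs$partner, sep = "|"),
                                   colnames(expr)))
  storage.mode(values) <- "integer"
  structure(list(pairs = pairs, values = values), class = "gene_pair_matrix")
}

#' @export
print.gene_pair_matrix <- function(x, ...) {
  cat(sprintf("gene_pair_matrix: %d pairs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

validate_gene_pair_matrix <- function(gpm) {
  if (!inherits(gpm, "gene_pair_matrix")) stopf("not a gene_pair_matrix")
  if (!all(gpm$values %in% c(-1L, 1L))) stopf("pair values must be +1 or -1")
  if (any(gpm$pairs$anchor == gpm$pairs$partner)) stopf("self-pair present")
  key <- ifelse(gpm$pairs$anchor < gpm$pairs$partner,
                paste(gpm$pairs$anchor, gpm$pairs$partner, sep = "\r"),
                paste(gpm$pairs$partner, gpm$pairs$anchor, sep = "\r"))
  if (anyDuplicated(key)) stopf("duplicate unordered pair present")
  invisible(gpm)
}

#' Filter gene pairs by +1 prevalence
#'
#' The frequency of a pair is the fraction of samples coded `+1`. Pairs whose
#' frequency exceeds `high` or falls below `low` carry little variability
#' (the same gene wins in almost every sample) and are removed; bounds are
#' inclusive, so a pair at exactly `low` or `high` is retained.
#'
#' @param gpm A `gene_pair_matrix`.
#' @param low,high Retention bounds on the +1 frequency; defaults 0.20/0.80.
#' @return The filtered `gene_pair_matrix`, with a `filter_report` attribute
#'   (data.frame of `pair`, `frequency`, `kept`). An empty result is allowed
#'   with a warning.
#' @export
filter_pairs_by_frequency <- function(gpm, low = 0.20, high = 0.80) {
  validate_gene_pair_matrix(gpm)
  if (!(low >= 0 && low < high && high <= 1)) {
    stopf("need 0 <= low < high <= 1 (got low=%g, high=%g)", low, high)
  }
  f <- rowMeans(gpm$values == 1L)
  eps <- 1e-9
  keep <- f >= low - eps & f <= high + eps
  report <- data.frame(pair = rownames(gpm$values), frequency = f,
                       kept = keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  if (!any(keep)) warnf("frequency filter removed every pair")
  out <- structure(list(pairs = gpm$pairs[keep, , drop = FALSE],
                        values = gpm$values[keep, , drop = FALSE]),
                   class = "gene_pair_matrix")
  rownames(out$pairs) <- NULL
  attr(out, "filter_report") <- report
  msgf("filter_pairs_by_frequency: kept %d of %d pairs in [%.2f, %.2f]",
       sum(keep), length(keep), low, high)
  out
}

#' Export a gene-pair matrix as tab-delimited text
#'
#' @param gpm A `gene_pair_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pair_matrix <- function(gpm, path) {
  validate_gene_pair_matrix(gpm)
  df <- data.frame(pair = rownames(gpm$values), gpm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
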