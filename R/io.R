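#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-delimited text file whose first column holds gene symbols and
#' whose header row holds sample identifiers. Orientation is fixed as genes in
#' rows, samples in columns; a transposed file is never guessed at — re-export
#' it the right way round instead.
#'
#' @param path Path to a tab-delimited text file.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames. Duplicate gene rows, missing values, non-numeric
#'   cells and ragged rows are errors, never silently repaired.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    stopf("ragged expression file: rows have %s fields",
          paste(unique(nf), collapse = ", "))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stopf("expression file must have a gene column plus samples")
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stopf("duplicate gene row(s) in %s: %s", path,
          paste(utils::head(dup, 5), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num)) {
    stopf("non-numeric expression column(s): %s",
          paste(utils::head(names(vals)[not_num], 5), collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  validate_expression(m, min_genes = 2L, min_samples = 2L)
  msgf("read_expression: %d genes x %d samples from %s", nrow(m), ncol(m), path)
  m
}

#' Write an expression matrix to tab-delimited text
#'
#' @param expr Numeric genes-x-samples matrix with dimnames.
#' @param path Output path.
#' @param digits Significant digits written (default 15, enough to round-trip
#'   doubles to formatting precision).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, digits = 15) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr),
                   signif(expr, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  msgf("write_expression: %d genes x %d samples to %s", nrow(expr), ncol(expr), path)
  invisible(path)
}

# Accepted spellings for ISS stages.
.iss_alias <- c("1" = 1L, "2" = 2L, "3" = 3L,
                "I" = 1L, "II" = 2L, "III" = 3L,
                "i" = 1L, "ii" = 2L, "iii" = 3L)

parse_iss <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  known <- !is.na(x) & nzchar(x) & x != "NA"
  bad <- known & !(x %in% names(.iss_alias))
  if (any(bad)) {
    stopf("unrecognized ISS value(s): %s (accepted: 1/2/3 or roman I/II/III)",
          paste(utils::head(unique(x[bad]), 5), collapse = ", "))
  }
  out[known] <- .iss_alias[x[known]]
  out
}

#' Read a clinical table with survival outcomes
#'
#' Reads a comma- or tab-delimited table of per-sample clinical data. Column
#' names are configurable through `columns`; ISS stages may be written as
#' integers 1-3 or roman numerals I-III. Rows missing the survival time or the
#' event indicator are dropped with a report; invalid values (negative time,
#' event outside 0/1, unrecognized ISS) are errors.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named list mapping canonical names (`sample_id`, `os_time`,
#'   `os_event`, `iss`, `age`, `gender`) to the file's column names. `iss`,
#'   `age` and `gender` are optional.
#' @param sep Field separator; `NULL` (default) picks comma for `.csv`, tab
#'   otherwise.
#' @return A `data.frame` with columns `sample_id`, `os_time` (months),
#'   `os_event` (0/1), `iss` (integer 1-3 or `NA`), `age`, `gender`. The
#'   number of dropped rows is attached as attribute `n_dropped`.
#' @export
read_clinical <- function(path,
                          columns = list(sample_id = "sample_id",
                                         os_time = "os_time",
                                         os_event = "os_event",
                                         iss = "iss",
                                         age = "age",
                                         gender = "gender"),
                          sep = NULL) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  for (req in c("sample_id", "os_time", "os_event")) {
    col <- columns[[req]]
    if (is.null(col) || !col %in% names(df)) {
      stopf("required column '%s' (mapped from '%s') not found in %s",
            col %||% req, req, path)
    }
  }
  out <- data.frame(sample_id = as.character(df[[columns$sample_id]]),
                    os_time = as.numeric(df[[columns$os_time]]),
                    os_event = as.numeric(df[[columns$os_event]]),
                    stringsAsFactors = FALSE)
  opt <- function(name, parser = identity) {
    col <- columns[[name]]
    if (!is.null(col) && col %in% names(df)) parser(df[[col]]) else NA
  }
  out$iss <- opt("iss", parse_iss)
  out$age <- opt("age", as.numeric)
  out$gender <- opt("gender", as.character)

  incomplete <- is.na(out$os_time) | is.na(out$os_event)
  if (any(incomplete)) {
    msgf("read_clinical: dropped %d row(s) with missing os_time/os_event (rows: %s)",
         sum(incomplete), paste(utils::head(which(incomplete), 10), collapse = ", "))
    out <- out[!incomplete, , drop = FALSE]
  }
  if (any(dup <- duplicated(out$sample_id))) {
    stopf("duplicate sample id(s) in clinical table: %s",
          paste(utils::head(unique(out$sample_id[dup]), 5), collapse = ", "))
  }
  if (any(bad <- out$os_time < 0)) {
    stopf("negative os_time at row(s): %s",
          paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (!all(out$os_event %in% c(0, 1))) {
    stopf("os_event must be 0 or 1; offending row(s): %s",
          paste(utils::head(which(!out$os_event %in% c(0, 1)), 5), collapse = ", "))
  }
  if (!is.na(out$age[1]) && any(out$age <= 0, na.rm = TRUE)) {
    stopf("age must be positive")
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(incomplete)
  msgf("read_clinical: %d samples from %s", nrow(out), path)
  out
}

#' Write a clinical table
#'
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path; comma-separated for `.csv`, tab otherwise.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(clinical, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(clinical, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with a clinical table
#'
#' Restricts both objects to the intersection of their sample ids (expression
#' column order wins) and reports how many samples were dropped from each
#' side. No imputation ever happens here.
#'
#' @param expr Genes-x-samples matrix.
#' @param clinical Clinical `data.frame` with a `sample_id` column.
#' @return A list with elements `expression`, `clinical` (now in identical
#'   sample order), `n_dropped_expression` and `n_dropped_clinical`.
#' @export
align_samples <- function(expr, clinical) {
  validate_expression(expr)
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (!length(shared)) stopf("no shared sample ids between expression and clinical data")
  n_de <- ncol(expr) - length(shared)
  n_dc <- nrow(clinical) - length(shared)
  msgf("align_samples: %d shared samples (dropped %d expression-only, %d clinical-only)",
       length(shared), n_de, n_dc)
  list(expression = expr[, shared, drop = FALSE],
       clinical = clinical[match(shared, clinical$sample_id), , drop = FALSE],
       n_dropped_expression = n_de,
       n_dropped_clinical = n_dc)
}

.model_schema_version <- 1L

#' Serialize a fitted pair model
#'
#' Writes a [pair_model] to a versioned, human-readable JSON file.
#' Coefficients and the risk cutoff are stored at full double precision so a
#' round-trip reproduces risk scores exactly.
#'
#' @param model A `pair_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  validate_pair_model(model)
  payload <- list(
    schema = "pairstage/pair_model",
    schema_version = .model_schema_version,
    pairs = data.frame(anchor = model$pairs$anchor,
                       partner = model$pairs$partner,
                       coefficient = model$pairs$coefficient,
                       stringsAsFactors = FALSE),
    risk_cutoff = model$risk_cutoff,
    provenance = model$provenance
  )
  # digits = 17 keeps the double -> decimal -> double round-trip exact
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 17,
                       pretty = TRUE)
  msgf("write_model: %d pairs, cutoff %.6g to %s",
       nrow(model$pairs), model$risk_cutoff, path)
  invisible(path)
}

#' Read a serialized pair model
#'
#' @param path Path to a file written by [write_model()].
#' @return A validated `pair_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stopf("malformed model file %s: %s",
                                                path, conditionMessage(e)))
  if (!identical(payload$schema, "pairstage/pair_model")) {
    stopf("not a pair model file: %s", path)
  }
  if (!identical(as.integer(payload$schema_version), .model_schema_version)) {
    stopf("model schema version %s not supported (expected %d)",
          payload$schema_version, .model_schema_version)
  }
  model <- pair_model(pairs = payload$pairs,
                      risk_cutoff = payload$risk_cutoff,
                      provenance = payload$provenance)
  msgf("read_model: %d pairs, cutoff %.6g from %s",
       nrow(model$pairs), model$risk_cutoff, path)
  model
}
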