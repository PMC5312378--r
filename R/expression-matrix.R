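#' Construct an expression matrix container
#'
#' Holds a subjects-by-miRNAs matrix of array signal together with its tissue
#' label, processing state, and per-cell bookkeeping masks.  Detection is
#' recorded explicitly: a raw cell is detected when its signal is strictly
#' positive, and the mask is carried unchanged through normalization and the
#' log2 transform (so a detected cell whose log2 value happens to be negative
#' or zero is never confused with an undetected one).  Subjects with no
#' measurement at all (e.g. unpaired normal mucosa) are encoded as all-`NA`
#' rows and can later be filled by [impute_missing_normals()].
#'
#' @param values numeric matrix, subjects in rows (rownames = subject ids),
#'   miRNAs in columns (colnames = miRNA ids).  In the `"raw"` state all
#'   non-missing values must be >= 0; undetected cells are exactly 0.
#' @param tissue `"carcinoma"` or `"normal"`.
#' @param state processing state: `"raw"`, `"normalized"`, or
#'   `"normalized-log2"`.  State may only advance raw -> normalized ->
#'   normalized-log2.
#' @param detected optional logical matrix marking detected cells; defaults
#'   to `values > 0` (the raw-state convention).
#' @param imputed optional logical matrix marking imputed cells; defaults to
#'   all `FALSE`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              tissue = c("carcinoma", "normal"),
                              state = c("raw", "normalized", "normalized-log2"),
                              detected = NULL, imputed = NULL) {
  tissue <- match.arg(tissue)
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    input_error("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    input_error("'values' must have subject rownames and miRNA colnames")
  if (state == "raw" && any(values < 0, na.rm = TRUE))
    state_error("raw expression values must be non-negative")
  if (is.null(detected)) {
    detected <- !is.na(values) & values > 0
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  if (!identical(dim(detected), dim(values)) ||
      !identical(dim(imputed), dim(values)))
    alignment_error("detected/imputed masks must match the value matrix")
  structure(list(values = values, tissue = tissue, state = state,
                 detected = detected, imputed = imputed),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d subjects x %d miRNAs, tissue = %s, state = %s\n",
              nrow(x$values), ncol(x$values), x$tissue, x$state))
  n_missing <- sum(apply(x$values, 1L, function(r) all(is.na(r))))
  cat(sprintf("  detected cells: %d; imputed cells: %d; all-missing rows: %d\n",
              sum(x$detected, na.rm = TRUE), sum(x$imputed), n_missing))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
em_subjects <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
em_mirnas <- function(x) colnames(x$values)

# rows with no observation at all (unpaired samples)
em_missing_rows <- function(x) apply(x$values, 1L, function(r) all(is.na(r)))

#' Read / write expression matrices as tab-separated text
#'
#' The on-disk format is a TSV with a one-line header; the first column
#' (`subject_id`) holds subject identifiers, remaining columns are miRNAs.
#'
#' @param x an `expression_matrix`.
#' @param path file path.
#' @return `read_expression_matrix` returns an `expression_matrix`.
#' @inheritParams expression_matrix
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(subject_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path,
                                   tissue = c("carcinoma", "normal"),
                                   state = c("raw", "normalized",
                                             "normalized-log2")) {
  tissue <- match.arg(tissue)
  state <- match.arg(state)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  expression_matrix(values, tissue = tissue, state = state)
}
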