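#' Paired carcinoma minus normal differential expression
#'
#' Cell-wise difference of log2 carcinoma signal minus log2 normal signal
#' under the undetected-as-zero convention, with a per-cell provenance flag:
#' `both` (detected in both tissues), `tumor-only`, `normal-only`, `neither`,
#' or `normal-imputed` (the normal value was imputed).
#'
#' @param tumor,normal aligned `expression_matrix` objects in state
#'   `"normalized-log2"` with identical subject and miRNA ids.
#' @return a `differential_matrix`: list with `values` (subjects x miRNAs)
#'   and `provenance` (character matrix of the same shape).
#' @export
compute_differential <- function(tumor, normal) {
  if (!inherits(tumor, "expression_matrix") ||
      !inherits(normal, "expression_matrix"))
    input_error("inputs must be expression_matrix objects")
  if (tumor$state != normal$state)
    state_error("tumor and normal matrices must be in the same state")
  if (tumor$state != "normalized-log2")
    state_error("differential expression requires normalized-log2 matrices")
  if (!identical(rownames(tumor$values), rownames(normal$values))) {
    off <- union(setdiff(rownames(tumor$values), rownames(normal$values)),
                 setdiff(rownames(normal$values), rownames(tumor$values)))
    alignment_error(paste0("subject ids differ between tumor and normal",
                           if (length(off)) paste0(": ", paste(utils::head(off, 10), collapse = ", "))))
  }
  if (!identical(colnames(tumor$values), colnames(normal$values)))
    alignment_error("miRNA ids differ between tumor and normal matrices")
  if (anyNA(normal$values))
    input_error("normal matrix still contains missing rows; impute first")

  values <- tumor$values - normal$values
  prov <- matrix("neither", nrow(values), ncol(values),
                 dimnames = dimnames(values))
  prov[tumor$detected & normal$detected] <- "both"
  prov[tumor$detected & !normal$detected] <- "tumor-only"
  prov[!tumor$detected & normal$detected] <- "normal-only"
  prov[normal$imputed] <- "normal-imputed"
  structure(list(values = values, provenance = prov),
            class = "differential_matrix")
}

#' Per-miRNA expression prevalence
#'
#' Percentage of subjects whose carcinoma tissue shows detected (positive)
#' signal for each miRNA.  Detection is taken from the matrix's detected
#' mask, so prevalence is invariant under normalization and the log2
#' transform.
#'
#' @param x an `expression_matrix` (any state).
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
compute_prevalence <- function(x) {
  if (!inherits(x, "expression_matrix"))
    input_error("'x' must be an expression_matrix")
  if (nrow(x$values) == 0L || ncol(x$values) == 0L)
    input_error("empty expression matrix")
  100 * colMeans(x$detected)
}

#' Classify miRNAs by expression prevalence
#'
#' Applies the two-group analysis rule: miRNAs expressed in fewer than
#' `min_expressors` eligible subjects are excluded; of the rest, those
#' expressed in at least `common_threshold` percent of the population are
#' analyzed on their continuous differential expression (`common`), the
#' remainder as any-versus-no expression (`rare`).
#'
#' @param prevalence named percentage vector from [compute_prevalence()],
#'   computed on subjects with both survival and stage information.
#' @param n_expressors integer vector, number of eligible expressors per
#'   miRNA (same order/names as `prevalence`).
#' @param common_threshold prevalence cut in percent (default 50).
#' @param min_expressors minimum expressor count (default 5).
#' @return data frame with `mirna_id`, `pct_expressing`, `n_expressors`,
#'   and `analysis_class` (`common` / `rare` / `excluded`).
#' @export
classify_mirnas <- function(prevalence, n_expressors,
                            common_threshold = 50, min_expressors = 5) {
  if (length(prevalence) != length(n_expressors))
    alignment_error("prevalence and expressor counts differ in length")
  cls <- ifelse(n_expressors < min_expressors, "excluded",
                ifelse(prevalence >= common_threshold, "common", "rare"))
  data.frame(mirna_id = names(prevalence), pct_expressing = unname(prevalence),
             n_expressors = unname(n_expressors),
             analysis_class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Quartiles of differential expression
#'
#' 25th and 75th percentiles of the per-subject differential values for each
#' miRNA within an analysis subset (linear-interpolation quantile, matching
#' the normalization module's convention).
#'
#' @param diff a `differential_matrix`.
#' @param subset logical or integer subject index; default all subjects.
#' @return data frame with `mirna_id`, `q1`, `q3`.
#' @export
differential_quartiles <- function(diff, subset = NULL) {
  if (!inherits(diff, "differential_matrix"))
    input_error("'diff' must be a differential_matrix")
  v <- diff$values
  if (!is.null(subset)) v <- v[subset, , drop = FALSE]
  if (nrow(v) == 0L) input_error("empty analysis subset")
  q <- apply(v, 2L, quantile, probs = c(0.25, 0.75), names = FALSE)
  data.frame(mirna_id = colnames(v), q1 = q[1L, ], q3 = q[2L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}
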