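#' Normalize raw counts to quantile-normalized log2 counts-per-million
#'
#' RNA-seq counts are put on the scale the metagene score expects: per sample,
#' log2((count + 0.5) / (library size + 1) * 1e6), then quantile normalization
#' across samples to the mean empirical distribution (ties within a sample
#' receive the mean of their tied reference values). Within-sample gene
#' ranking is preserved up to ties. Already-normalized inputs (state
#' `log_quantile`, e.g. microarray data) should skip this step and go straight
#' to [median_center()].
#'
#' @param counts an `expression_table` with state `raw_counts` (non-negative
#'   integers).
#' @return an `expression_table` with state `log_quantile`.
#' @export
normalize_counts <- function(counts) {
  if (expr_state(counts) != "raw_counts")
    stop("`counts` must have state 'raw_counts'; got '", expr_state(counts), "'")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  lib <- colSums(counts, na.rm = TRUE)
  if (any(lib == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  logcpm <- log2(t((t(counts) + 0.5) / (lib + 1)) * 1e6)
  if (ncol(logcpm) > 1)
    logcpm <- limma::normalizeQuantiles(logcpm, ties = TRUE)
  out <- expression_table(as.matrix(logcpm), "log_quantile")
  attr(out, "id_column") <- attr(counts, "id_column")
  out
}

#' Median-centre each gene across samples
#'
#' Subtracts every gene's across-sample median (computed over all loaded
#' samples, tumours and normals together). After centering each gene's median
#' is zero, so a metagene score of zero means "at the dataset-typical
#' expression for every signature gene". Centering is per analysis dataset:
#' scores from separately centred datasets are not comparable.
#'
#' @param expr an `expression_table` with state `log_quantile`.
#' @param by optional factor/character of length `ncol(expr)` giving a
#'   centering group per sample (e.g. cohort) for per-group centering;
#'   default is global centering over the whole loaded matrix.
#' @return an `expression_table` with state `median_centred`.
#' @export
median_center <- function(expr, by = NULL) {
  if (expr_state(expr) != "log_quantile")
    stop("`expr` must have state 'log_quantile'; got '", expr_state(expr), "'")
  all_missing <- rowSums(!is.na(expr)) == 0
  if (any(all_missing))
    stop("gene(s) with all values missing: ",
         paste(rownames(expr)[all_missing], collapse = ", "))
  vals <- unclass(expr)
  if (is.null(by)) {
    vals <- vals - apply(vals, 1, stats::median, na.rm = TRUE)
  } else {
    if (length(by) != ncol(vals))
      stop("`by` must have one entry per sample")
    for (g in split(seq_len(ncol(vals)), by)) {
      vals[, g] <- vals[, g, drop = FALSE] -
        apply(vals[, g, drop = FALSE], 1, stats::median, na.rm = TRUE)
    }
  }
  out <- expression_table(vals, "median_centred")
  attr(out, "id_column") <- attr(expr, "id_column")
  out
}

#' Metagene signature score
#'
#' The per-sample score is the sum of median-centred log2 expression over the
#' signature genes present in the table (the CA20 definition; the same
#' operation serves any signature, e.g. a hypoxia metagene). Signature genes
#' absent from the table are skipped with a warning and the coverage is
#' recorded; a score is computed whenever at least one signature gene is
#' measured.
#'
#' @param expr an `expression_table` with state `median_centred`.
#' @param signature a `gene_signature`.
#' @return a named numeric vector of per-sample scores (class `score_vector`)
#'   with attributes `signature`, `n_genes_used` and `n_genes_signature`.
#' @export
metagene_score <- function(expr, signature) {
  if (expr_state(expr) != "median_centred")
    stop("`expr` must have state 'median_centred'; got '", expr_state(expr), "'")
  present <- signature$genes[signature$genes %in% rownames(expr)]
  absent <- setdiff(signature$genes, present)
  if (!length(present))
    stop("no gene of signature '", signature$name, "' is present in the table")
  if (length(absent))
    warning(sprintf("signature '%s': %d of %d genes not measured (%s)",
                    signature$name, length(absent), length(signature$genes),
                    paste(absent, collapse = ", ")))
  scores <- colSums(expr[present, , drop = FALSE], na.rm = TRUE)
  structure(scores,
            signature = signature$name,
            n_genes_used = length(present),
            n_genes_signature = length(signature$genes),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector '%s': %d samples, %d/%d signature genes used\n",
              attr(x, "signature"), length(x), attr(x, "n_genes_used"),
              attr(x, "n_genes_signature")))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}

#' Call arm-level copy-number alterations from continuous scores
#'
#' GISTIC-style arm scores are thresholded into calls: strictly below `low`
#' is a loss (-1), strictly above `high` a gain (+1), anything else --
#' including exact boundary values -- no alteration (0).
#'
#' @param arm_scores arm-by-sample numeric matrix.
#' @param low loss threshold (default -1).
#' @param high gain threshold (default +1).
#' @return integer matrix in \{-1, 0, +1\}, same dimnames; `NA` preserved.
#' @export
call_arm_alterations <- function(arm_scores, low = -1, high = 1) {
  if (!(low < high)) stop("`low` must be less than `high`")
  calls <- array(0L, dim = dim(arm_scores), dimnames = dimnames(arm_scores))
  calls[arm_scores < low] <- -1L
  calls[arm_scores > high] <- 1L
  calls[is.na(arm_scores)] <- NA_integer_
  calls
}
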