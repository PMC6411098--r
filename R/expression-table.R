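#' Expression tables
#'
#' An `expression_table` is a gene-by-sample numeric matrix carrying a
#' normalization `state` flag. The state records where the table sits in the
#' scoring pipeline and only ever moves forward:
#' `raw_counts` -> `log_quantile` (log2 counts-per-million, quantile
#' normalized) -> `median_centred` (per-gene across-sample median subtracted).
#'
#' @param values numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames. Missing values (`NA`) are allowed and mean
#'   "not measured", never zero.
#' @param state one of `"raw_counts"`, `"log_quantile"`, `"median_centred"`.
#' @return an `expression_table`: the matrix with a `state` attribute.
#' @export
expression_table <- function(values,
                             state = c("raw_counts", "log_quantile",
                                       "median_centred")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite where present")
  structure(values, state = state, class = c("expression_table", "matrix", "array"))
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_state(x)))
  invisible(x)
}

#' Normalization state of an expression table
#' @param x an `expression_table`.
#' @return the state flag, a character scalar.
#' @export
expr_state <- function(x) {
  s <- attr(x, "state")
  if (is.null(s)) stop("not an expression_table: no state attribute")
  s
}

#' Read a gene-by-sample expression table from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers,
#' the body is numeric. Empty cells are read as missing. The state is set to
#' `raw_counts` when every non-missing value is an integer, `log_quantile`
#' otherwise (already-normalized inputs, e.g. microarray intensities, skip the
#' count-normalization step).
#'
#' @param path path to a tab-separated file.
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2) stop("expected gene-id column plus at least one sample")
  id_col <- colnames(raw)[1]
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(body == "" | body == "NA"), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]],
                 body[bad[1, 1], bad[1, 2]]))
  num[body == "" | body == "NA"] <- NA_real_
  rownames(num) <- genes
  colnames(num) <- samples
  obs <- num[!is.na(num)]
  state <- if (length(obs) && all(obs == round(obs))) "raw_counts" else "log_quantile"
  out <- expression_table(num, state)
  attr(out, "id_column") <- id_col
  out
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]: first column gene identifiers, header
#' row sample identifiers, missing values written as empty cells. Integer-valued
#' matrices are written without decimal points so count tables round-trip
#' byte-identically.
#'
#' @param x an `expression_table` (or plain named matrix).
#' @param path output path.
#' @param id_column header for the gene-id column (defaults to the one recorded
#'   at read time, else `"gene"`).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = NULL) {
  if (is.null(id_column))
    id_column <- attr(x, "id_column") %||% "gene"
  obs <- x[!is.na(x)]
  fmt <- function(v) {
    out <- if (length(obs) && all(obs == round(obs)))
      formatC(v, format = "d") else as.character(v)
    out[is.na(v)] <- ""
    out
  }
  lines <- c(paste(c(id_column, colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], fmt(x[i, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
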