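#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment as used by every association scan in the package:
#' q-values are computed per scan, over exactly the features that scan
#' retained. Missing p-values pass through as missing and do not count
#' towards the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` allowed.
#' @return q-values, same length and order as `p`, `NA` where `p` is `NA`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  obs <- !is.na(p)
  if (any(p[obs] < 0 | p[obs] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[obs] <- stats::p.adjust(p[obs], method = "BH")
  q
}

#' Assemble an association-scan result table
#'
#' Standard container for one scan: one row per feature with effect estimate,
#' p-value, BH q-value (computed here over exactly the rows supplied), number
#' of samples used and the direction of effect.
#'
#' @param feature feature identifiers.
#' @param estimate effect estimates (regression coefficient or correlation).
#' @param p p-values.
#' @param n_used samples used per feature.
#' @param scan scan name stored as an attribute.
#' @param filter description of any feature filter applied, stored as an
#'   attribute.
#' @return a data.frame with columns `feature`, `estimate`, `p`, `q`,
#'   `n`, `direction`.
#' @export
association_table <- function(feature, estimate, p, n_used,
                              scan = "scan", filter = NULL) {
  out <- data.frame(feature = as.character(feature),
                    estimate = as.numeric(estimate),
                    p = as.numeric(p),
                    q = bh_adjust(as.numeric(p)),
                    n = as.integer(n_used),
                    direction = ifelse(is.na(estimate), NA_character_,
                                       ifelse(estimate >= 0, "+", "-")),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scan") <- scan
  attr(out, "filter") <- filter
  out
}

#' Write an association table as TSV
#' @param x a data.frame from [association_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an association table written by [write_association_table()]
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_association_table <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "")
}
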