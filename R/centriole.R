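#' Fraction of cells with centrosome amplification
#'
#' A cell is counted as amplified when it carries strictly more than
#' `threshold` centrioles (default 4: a normal cell has at most two
#' centrosomes, i.e. four centrioles). The patient-level readout is the
#' percentage of amplified cells.
#'
#' @param counts per-cell centriole counts for one patient (positive
#'   integers).
#' @param threshold amplification threshold; a count equal to the threshold
#'   is *not* amplified.
#' @return percentage in \[0, 100\].
#' @export
ca_fraction <- function(counts, threshold = 4) {
  counts <- counts[!is.na(counts)]
  if (!length(counts)) stop("no cells: CA fraction undefined")
  if (any(counts < 1)) stop("centriole counts must be >= 1")
  100 * mean(counts > threshold)
}

#' Per-subtype summary of patient CA fractions
#'
#' Subtype means are unweighted means of per-patient percentages (every
#' patient contributes equally, regardless of how many cells were scored),
#' with pairwise two-sided rank-sum tests between subtypes.
#'
#' @param fractions per-patient CA percentages.
#' @param subtypes subtype label per patient.
#' @return list with `means` (named vector of subtype mean percentages,
#'   with attribute `n_patients`) and `pairwise` (data.frame `subtype_a`,
#'   `subtype_b`, `p`).
#' @export
subtype_summary <- function(fractions, subtypes) {
  subtypes <- as.character(subtypes)
  keep <- !is.na(fractions) & !is.na(subtypes)
  fractions <- fractions[keep]; subtypes <- subtypes[keep]
  tab <- table(subtypes)
  if (any(tab == 0) || !length(tab)) stop("no patients")
  levels_used <- names(tab)
  means <- vapply(levels_used, function(s) mean(fractions[subtypes == s]), 0)
  attr(means, "n_patients") <- as.integer(tab[levels_used])
  pairs <- utils::combn(levels_used, 2)
  pairwise <- data.frame(
    subtype_a = pairs[1, ], subtype_b = pairs[2, ],
    p = apply(pairs, 2, function(pr)
      rank_sum_compare(fractions[subtypes == pr[1]],
                       fractions[subtypes == pr[2]])$p),
    stringsAsFactors = FALSE)
  list(means = means, pairwise = pairwise)
}

#' Read a per-cell centriole count table
#'
#' TSV with columns `patient`, `subtype`, `centrioles` (one row per cell) or
#' the histogram dialect `patient`, `subtype`, `centrioles`, `n_cells`
#' (expanded on read).
#'
#' @param path path to the TSV.
#' @return data.frame with one row per cell: `patient`, `subtype`,
#'   `centrioles`.
#' @export
read_centriole_table <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient", "subtype", "centrioles")
  if (!all(need %in% colnames(d)))
    stop("expected columns: ", paste(need, collapse = ", "))
  if ("n_cells" %in% colnames(d))
    d <- d[rep(seq_len(nrow(d)), d$n_cells), need]
  rownames(d) <- NULL
  d[, need]
}
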