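#' Generate a synthetic cell-line pharmacology panel
#'
#' Builds a `pharmacology_bundle` with the structure of a drug-sensitivity /
#' perturbation-connectivity screen: per-cell-line scores, a
#' compound-by-cell-line AUC matrix in which designated sensitive compounds
#' have AUC decreasing with the cell line's score (`delta` > 0 means
#' high-score lines are more sensitive, i.e. lower AUC), a
#' perturbation-by-cell-line connectivity matrix in \[-100, 100\] with
#' planted strongly negative means for designated perturbations, and a
#' compound-to-perturbation id map. By default each sensitive compound's
#' mapped perturbation is one of the planted-negative perturbations, so the
#' sensitivity and connectivity analyses agree on the same compounds.
#'
#' @param n_cell_lines number of cell lines in the AUC screen.
#' @param n_compounds number of compounds.
#' @param n_perturbations number of perturbations in the connectivity screen.
#' @param sensitive_compounds compound ids (or indices) with planted
#'   score-coupled sensitivity; must be a subset of the compounds.
#' @param delta planted AUC decrease per score unit for sensitive compounds
#'   (must be >= 0).
#' @param missingness per-compound fraction of missing AUC cells: scalar or
#'   vector of length `n_compounds` (missing counts are exact, so filter
#'   outcomes are deterministic).
#' @param negative_perturbations perturbation ids with planted strongly
#'   negative connectivity (default: those mapped to the sensitive
#'   compounds).
#' @param n_cmap_lines number of connectivity cell lines (default 9).
#' @param sd_auc AUC noise standard deviation.
#' @param seed integer seed; mandatory.
#' @return a `pharmacology_bundle`: list with `auc`, `cellline_scores`,
#'   `connectivity`, `id_map`, `sensitive_compounds`,
#'   `negative_perturbations`.
#' @export
generate_cellline_panel <- function(n_cell_lines = 300,
                                    n_compounds = 50,
                                    n_perturbations = 40,
                                    sensitive_compounds = character(),
                                    delta = 1,
                                    missingness = 0,
                                    negative_perturbations = NULL,
                                    n_cmap_lines = 9,
                                    sd_auc = 1,
                                    seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (delta < 0)
    stop("`delta` must be >= 0 (positive delta = high-score lines more sensitive)")
  lines <- sprintf("CL%04d", seq_len(n_cell_lines))
  compounds <- sprintf("CMP%04d", seq_len(n_compounds))
  perts <- sprintf("PERT%04d", seq_len(n_perturbations))
  if (is.numeric(sensitive_compounds))
    sensitive_compounds <- compounds[sensitive_compounds]
  if (!all(sensitive_compounds %in% compounds))
    stop("`sensitive_compounds` must be a subset of the compounds")
  missingness <- rep_len(missingness, n_compounds)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  scores <- stats::setNames(stats::rnorm(n_cell_lines), lines)
  baseline <- stats::rnorm(n_compounds, 10, 1)
  auc <- matrix(stats::rnorm(n_compounds * n_cell_lines, 0, sd_auc),
                n_compounds, n_cell_lines,
                dimnames = list(compounds, lines)) + baseline
  sens <- compounds %in% sensitive_compounds
  if (any(sens))
    auc[sens, ] <- auc[sens, , drop = FALSE] -
      delta * matrix(scores, sum(sens), n_cell_lines, byrow = TRUE)
  for (i in seq_len(n_compounds)) {
    n_miss <- round(missingness[i] * n_cell_lines)
    if (n_miss > 0) auc[i, sample.int(n_cell_lines, n_miss)] <- NA_real_
  }

  n_shared <- min(n_compounds, n_perturbations)
  id_map <- data.frame(compound = compounds[seq_len(n_shared)],
                       perturbation = perts[seq_len(n_shared)],
                       stringsAsFactors = FALSE)
  if (is.null(negative_perturbations))
    negative_perturbations <-
      id_map$perturbation[id_map$compound %in% sensitive_compounds]
  cmap_lines <- c("PC3", "VCAP", "A375", "A549", "HA1E", "HCC515", "HT29",
                  "MCF7", "HEPG2")[seq_len(min(n_cmap_lines, 9))]
  if (n_cmap_lines > 9)
    cmap_lines <- c(cmap_lines, sprintf("CXL%02d", seq_len(n_cmap_lines - 9)))
  connectivity <- matrix(stats::rnorm(n_perturbations * n_cmap_lines, 0, 40),
                         n_perturbations, n_cmap_lines,
                         dimnames = list(perts, cmap_lines))
  neg <- perts %in% negative_perturbations
  connectivity[neg, ] <- stats::rnorm(sum(neg) * n_cmap_lines, -95, 3)
  connectivity <- pmin(pmax(connectivity, -100), 100)

  structure(list(auc = auc, cellline_scores = scores,
                 connectivity = connectivity, id_map = id_map,
                 sensitive_compounds = sensitive_compounds,
                 negative_perturbations = negative_perturbations,
                 seed = seed),
            class = "pharmacology_bundle")
}

#' @export
print.pharmacology_bundle <- function(x, ...) {
  cat(sprintf("pharmacology_bundle: %d compounds x %d cell lines (AUC), %d perturbations x %d lines (connectivity)\n",
              nrow(x$auc), ncol(x$auc), nrow(x$connectivity),
              ncol(x$connectivity)))
  invisible(x)
}

#' Generate per-cell centriole counts for a patient series
#'
#' Per patient, a number of scored cells is drawn uniformly from
#' `cells_range`; each cell is amplified with its subtype's prevalence.
#' Amplified cells get 5-14 centrioles, unamplified cells 1-4, so the
#' amplification call (strictly more than 4 centrioles) recovers the planted
#' prevalence exactly in expectation. Defaults reproduce a breast-carcinoma
#' series: 29 luminal A, 3 luminal B, 3 HER2 and 13 basal-like patients with
#' 5-107 cells each and subtype prevalences 7%, 27%, 15% and 25%.
#'
#' @param patients_per_subtype named integer vector: subtype -> number of
#'   patients (all entries >= 1).
#' @param prevalence named numeric vector in \[0, 1\]: subtype -> per-cell
#'   amplification probability.
#' @param cells_range integer range (min, max) of cells scored per patient.
#' @param seed integer seed; mandatory.
#' @return data.frame with one row per cell: `patient`, `subtype`,
#'   `centrioles`.
#' @export
generate_centriole_counts <- function(
    patients_per_subtype = c("luminal A" = 29, "luminal B" = 3,
                             "HER2" = 3, "basal-like" = 13),
    prevalence = c("luminal A" = 0.07, "luminal B" = 0.27,
                   "HER2" = 0.15, "basal-like" = 0.25),
    cells_range = c(5, 107),
    seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (any(patients_per_subtype < 1))
    stop("every subtype needs at least one patient")
  if (!all(names(patients_per_subtype) %in% names(prevalence)))
    stop("`prevalence` must cover every subtype")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (s in names(patients_per_subtype)) {
    for (i in seq_len(patients_per_subtype[[s]])) {
      pid <- pid + 1
      n_cells <- sample(seq(cells_range[1], cells_range[2]), 1)
      amplified <- stats::rbinom(n_cells, 1, prevalence[[s]]) == 1
      counts <- integer(n_cells)
      counts[amplified] <- sample(5:14, sum(amplified), replace = TRUE)
      counts[!amplified] <- sample(1:4, sum(!amplified), replace = TRUE)
      rows[[pid]] <- data.frame(patient = sprintf("P%03d", pid),
                                subtype = s, centrioles = counts,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
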