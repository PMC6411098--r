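#' Filter compounds by missing-data fraction
#'
#' Compounds (rows) with strictly more than `max_missing_fraction` of their
#' cell-line AUC values missing are removed before any correlation analysis;
#' exactly at the threshold is retained. The removal list is recorded as an
#' attribute.
#'
#' @param auc compound-by-cell-line AUC matrix, `NA` = not measured.
#' @param max_missing_fraction maximum tolerated missing fraction (default
#'   0.20).
#' @return the filtered matrix with attribute `removed` (compound ids).
#' @export
filter_compounds <- function(auc, max_missing_fraction = 0.20) {
  frac <- rowMeans(is.na(auc))
  drop <- frac > max_missing_fraction
  if (all(drop)) stop("every compound exceeds the missing-data threshold")
  out <- auc[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(auc)[drop]
  out
}

.spearman_t_p_vec <- function(rho, n) {
  p <- numeric(length(rho))
  sat <- abs(rho) >= 1
  p[sat] <- 0
  r <- rho[!sat]
  p[!sat] <- 2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                           lower.tail = FALSE)
  p
}

#' Drug-sensitivity correlation scan
#'
#' Per compound, pairwise-complete Spearman correlation between cell-line
#' scores and AUC, with BH across compounds. AUC is an inverse activity
#' measure, so negative rho means the compound is more active in high-score
#' cell lines -- the sign of interest for candidate killers of high-score
#' cells.
#'
#' @param cellline_scores named score vector (names = cell-line ids).
#' @param auc compound-by-cell-line AUC matrix.
#' @param min_pairs compounds with fewer complete pairs are skipped with a
#'   warning (default 4).
#' @return an [association_table()] (estimate = rho).
#' @export
sensitivity_scan <- function(cellline_scores, auc, min_pairs = 4) {
  lines <- intersect(names(cellline_scores), colnames(auc))
  sc <- as.numeric(cellline_scores[lines])
  a <- auc[, lines, drop = FALSE]
  rows <- list()
  for (cmp in rownames(a)) {
    ok <- !is.na(a[cmp, ]) & !is.na(sc)
    if (sum(ok) < min_pairs) {
      warning("compound '", cmp, "': fewer than ", min_pairs,
              " complete pairs; skipped")
      next
    }
    ct <- spearman_corr(sc[ok], a[cmp, ok])
    rows[[cmp]] <- data.frame(feature = cmp, estimate = ct$rho, p = ct$p,
                              n = ct$n)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(association_table(character(), numeric(), numeric(), integer(),
                             scan = "sensitivity_scan"))
  association_table(res$feature, res$estimate, res$p, res$n,
                    scan = "sensitivity_scan",
                    filter = sprintf("min %d complete pairs", min_pairs))
}

#' Permutation null for the sensitivity scan (Q-Q calibration)
#'
#' Each permutation independently shuffles every compound's AUC values
#' across cell lines (preserving each compound's AUC marginal), recomputes
#' all score-AUC Spearman correlations and their signed -log10 p-values
#' (sign = sign of rho), and sorts them. The expected value at rank k is the
#' median over permutations of the k-th sorted value; plotting observed
#' against expected sorted values gives the Q-Q calibration of the scan.
#'
#' @inheritParams sensitivity_scan
#' @param n_perm number of permutations (>= 2; 1000 typical).
#' @param seed integer seed, required.
#' @return data.frame with `rank`, `expected` and `observed` signed -log10
#'   p-values (both sorted ascending).
#' @export
permutation_qq <- function(cellline_scores, auc, n_perm = 1000, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (n_perm < 2) stop("`n_perm` must be at least 2")
  lines <- intersect(names(cellline_scores), colnames(auc))
  sc <- as.numeric(cellline_scores[lines])
  a <- auc[, lines, drop = FALSE]
  obs_tab <- suppressWarnings(sensitivity_scan(cellline_scores, auc))
  observed <- sort(-log10(obs_tab$p) * sign(obs_tab$estimate))
  m <- nrow(a); n <- ncol(a)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!anyNA(a) && !anyNA(sc)) {
    # complete panel: vectorized rank algebra
    zs <- scale(rank(sc))[, 1]
    za <- apply(a, 1, function(v) scale(rank(v))[, 1])   # n x m
    perm_stats <- matrix(NA_real_, n_perm, m)
    for (b in seq_len(n_perm)) {
      idx <- vapply(seq_len(m), function(j) sample.int(n), integer(n))
      rho <- colSums(matrix(zs[idx], n, m) * za) / (n - 1)
      perm_stats[b, ] <- sort(-log10(.spearman_t_p_vec(rho, n)) * sign(rho))
    }
  } else {
    perm_stats <- matrix(NA_real_, n_perm, length(observed))
    for (b in seq_len(n_perm)) {
      shuffled <- t(apply(a, 1, sample))
      colnames(shuffled) <- colnames(a)
      tab <- suppressWarnings(sensitivity_scan(
        stats::setNames(sc, lines), shuffled))
      perm_stats[b, ] <- sort(-log10(tab$p) * sign(tab$estimate))
    }
  }
  expected <- apply(perm_stats, 2, stats::median)
  data.frame(rank = seq_along(expected), expected = expected,
             observed = observed)
}

#' Average connectivity score per perturbation
#'
#' Perturbation-vs-query connectivity scores (in \[-100, 100\]; negative
#' means the perturbation down-regulates the query gene set) are averaged
#' over the profiled cell lines to give one robust score per perturbation;
#' the number of contributing cell lines is recorded.
#'
#' @param connectivity perturbation-by-cell-line score matrix, `NA` = not
#'   profiled.
#' @return data.frame with `perturbation`, `average_score`, `n_cell_lines`.
#' @export
average_connectivity <- function(connectivity) {
  if (any(abs(connectivity) > 100, na.rm = TRUE))
    stop("connectivity scores must lie in [-100, 100]")
  n_obs <- rowSums(!is.na(connectivity))
  if (any(n_obs == 0))
    stop("perturbation(s) with no cell-line score: ",
         paste(rownames(connectivity)[n_obs == 0], collapse = ", "))
  data.frame(perturbation = rownames(connectivity),
             average_score = rowMeans(connectivity, na.rm = TRUE),
             n_cell_lines = as.integer(n_obs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Integrate drug-sensitivity and perturbation-connectivity results
#'
#' Joins the sensitivity scan (per-compound rho, q) with per-perturbation
#' average connectivity scores through a compound-to-perturbation id map,
#' correlates the two effect measures across shared compounds (Spearman),
#' and flags candidate compounds: significant sensitivity correlation
#' (q < 0.05) together with strong query down-regulation (average score
#' < -90).
#'
#' @param sensitivity result of [sensitivity_scan()].
#' @param connectivity_avg result of [average_connectivity()].
#' @param id_map data.frame with columns `compound` and `perturbation`.
#' @param q_threshold,score_threshold the candidate rule (defaults 0.05 and
#'   -90).
#' @return list with `table` (joined per-compound data.frame including a
#'   logical `candidate` column), `rho` and `p` (correlation between the two
#'   measures), `n` (shared compounds).
#' @export
integrate_ctrp_cmap <- function(sensitivity, connectivity_avg, id_map,
                                q_threshold = 0.05, score_threshold = -90) {
  joined <- merge(
    merge(id_map, sensitivity, by.x = "compound", by.y = "feature"),
    connectivity_avg, by = "perturbation")
  if (!nrow(joined)) stop("no compound shared between the two datasets")
  ct <- spearman_corr(joined$estimate, joined$average_score)
  joined$candidate <- joined$q < q_threshold &
    joined$average_score < score_threshold
  joined <- joined[order(joined$average_score), ]
  rownames(joined) <- NULL
  list(table = joined, rho = ct$rho, p = ct$p, n = nrow(joined))
}

#' Association between compound-target expression and proliferation
#'
#' For every predicted target gene, fits
#' `expression ~ proliferation_rate + cohort` and joins the proliferation
#' coefficient back onto compounds via a compound-to-target map, so
#' candidate compounds can be checked for merely targeting
#' proliferation-coupled genes. Compounds without an annotated target are
#' carried with missing coefficients.
#'
#' @param target_expr gene-by-sample expression matrix restricted to (or
#'   containing) target genes.
#' @param proliferation named per-sample proliferation rates.
#' @param cohort named per-sample cohort labels.
#' @param compound_targets data.frame with columns `compound` and `target`
#'   (`NA` target = no annotation).
#' @return data.frame with `compound`, `target`, `estimate`, `p`.
#' @export
target_proliferation_assoc <- function(target_expr, proliferation, cohort,
                                       compound_targets) {
  samples <- Reduce(intersect, list(colnames(target_expr),
                                    names(proliferation), names(cohort)))
  covs <- c(proliferation = "numeric")
  d0 <- data.frame(proliferation = as.numeric(proliferation[samples]),
                   row.names = samples)
  if (length(unique(cohort[samples])) > 1) {
    d0$cohort <- cohort[samples]
    covs <- c(covs, cohort = "categorical")
  }
  targets <- unique(stats::na.omit(compound_targets$target))
  fits <- lapply(targets, function(g) {
    if (!g %in% rownames(target_expr))
      return(data.frame(target = g, estimate = NA_real_, p = NA_real_))
    d <- d0
    d$expr <- as.numeric(target_expr[g, samples])
    fit <- fit_linear_model(d, "expr", covs)
    fr <- fit[fit$covariate == "proliferation", ]
    data.frame(target = g, estimate = fr$estimate, p = fr$p)
  })
  fits <- do.call(rbind, fits)
  out <- merge(compound_targets, fits, by = "target", all.x = TRUE)
  out[order(out$compound), c("compound", "target", "estimate", "p")]
}
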