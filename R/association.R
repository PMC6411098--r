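#' Two-group rank-sum comparison
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test, the workhorse for all
#' group-wise score comparisons (tumour vs normal, subtypes, stages). Small
#' untied samples use the exact distribution; larger or tied samples the
#' normal approximation with tie correction (the `stats::wilcox.test`
#' defaults).
#'
#' @param values_a,values_b numeric vectors, each with at least one value.
#' @return list with `statistic` (W) and `p`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b))
    stop("both groups must contain at least one value")
  if (length(unique(c(values_a, values_b))) == 1)
    return(list(statistic = length(values_a) * length(values_b) / 2, p = 1))
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = min(1, ht$p.value))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average-ranked data; the two-sided
#' p-value comes from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' with n-2 degrees of freedom, used at every sample size for consistency
#' across scans. Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p` and `n` (complete pairs used).
#' @export
spearman_corr <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs; got ", n)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks: correlation undefined")
  rho <- stats::cor(rx, ry)
  p <- .spearman_t_p(rho, n)
  list(rho = rho, p = p, n = n)
}

.spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Williams test for two dependent correlations sharing one variable
#'
#' Compares r(x,y) against r(x,z) measured on the same n subjects, accounting
#' for r(y,z) (used e.g. to ask whether a score correlates more strongly with
#' deletions than with amplifications). The statistic is
#' `t = (r_xy - r_xz) * sqrt((n-1)(1+r_yz)) /
#'      sqrt(2 |R| (n-1)/(n-3) + rbar^2 (1-r_yz)^3)`
#' with `|R| = 1 - r_xy^2 - r_xz^2 - r_yz^2 + 2 r_xy r_xz r_yz` and
#' `rbar = (r_xy + r_xz)/2`, on n-3 degrees of freedom, two-sided.
#'
#' @param r_xy,r_xz,r_yz correlations, each in (-1, 1).
#' @param n number of paired observations (> 3).
#' @return list with `t` and `p`.
#' @export
dependent_correlation_test <- function(r_xy, r_xz, r_yz, n) {
  rs <- c(r_xy, r_xz, r_yz)
  if (any(abs(rs) >= 1)) stop("correlations must lie strictly in (-1, 1)")
  if (n <= 3) stop("`n` must exceed 3")
  detR <- 1 - r_xy^2 - r_xz^2 - r_yz^2 + 2 * r_xy * r_xz * r_yz
  if (detR < -1e-8)
    stop("inconsistent correlation triple: |R| = ", signif(detR, 3), " < 0")
  detR <- max(detR, 0)
  rbar <- (r_xy + r_xz) / 2
  denom <- sqrt(2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_yz)^3)
  tstat <- (r_xy - r_xz) * sqrt((n - 1) * (1 + r_yz)) / denom
  list(t = tstat, p = 2 * stats::pt(abs(tstat), df = n - 3, lower.tail = FALSE))
}

#' Ordinary least-squares fit with covariate roles
#'
#' The regression engine behind all volcano scans. Covariates are declared
#' with a role: `numeric` (used as-is), `z_scored_numeric` (standardized on
#' the analysis subset before fitting -- genomic-instability covariates are
#' z-scored to make their coefficients comparable across cohorts) or
#' `categorical` (expanded to indicator contrasts against the first level).
#' Complete-case analysis; the number of rows used is recorded.
#'
#' @param data a data.frame.
#' @param response name of the response column.
#' @param covariates named character vector mapping covariate names to roles,
#'   e.g. `c(aneuploidy = "z_scored_numeric", cohort = "categorical")`.
#' @return data.frame with one row per fitted coefficient (intercept
#'   excluded): `term`, `covariate`, `estimate`, `se`, `p`; attribute
#'   `n_used`.
#' @export
fit_linear_model <- function(data, response, covariates) {
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    stop("`covariates` must be a named vector of roles")
  if (response %in% names(covariates))
    stop("response must not appear among covariates")
  vars <- c(response, names(covariates))
  missing_cols <- setdiff(vars, colnames(data))
  if (length(missing_cols))
    stop("columns not in `data`: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  if (nrow(d) < length(covariates) + 2)
    stop("too few complete cases (", nrow(d), ") for ", length(covariates),
         " covariates")
  for (v in names(covariates)) {
    role <- match.arg(covariates[[v]],
                      c("numeric", "z_scored_numeric", "categorical"))
    if (role == "z_scored_numeric") {
      s <- stats::sd(d[[v]])
      if (s == 0) stop("covariate '", v, "' is constant; cannot z-score")
      d[[v]] <- (d[[v]] - mean(d[[v]])) / s
    } else if (role == "categorical") {
      d[[v]] <- factor(d[[v]])
      if (nlevels(d[[v]]) < 2)
        stop("categorical covariate '", v, "' has a single level")
    }
  }
  fml <- stats::reformulate(names(covariates), response = response)
  fit <- stats::lm(fml, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  term <- rownames(sm)[keep]
  cov_of_term <- vapply(term, function(tn) {
    hit <- names(covariates)[startsWith(tn, names(covariates))]
    hit[which.max(nchar(hit))]
  }, "")
  out <- data.frame(term = term, covariate = unname(cov_of_term),
                    estimate = sm[keep, 1], se = sm[keep, 2], p = sm[keep, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_used") <- nrow(d)
  out
}

#' Variance inflation factors
#'
#' Collinearity diagnostic for a covariate set: `VIF_j = 1 / (1 - R^2_j)`
#' from regressing covariate j on the remaining covariates. Perfectly
#' collinear covariates are reported as `Inf`, not an error, so scan runners
#' can warn (the regressions here are only trusted when every VIF stays below
#' 2).
#'
#' @param data a data.frame.
#' @param covariates names of at least two numeric columns.
#' @return named numeric vector of VIFs.
#' @export
variance_inflation <- function(data, covariates) {
  if (length(covariates) < 2) stop("need at least 2 covariates")
  d <- data[stats::complete.cases(data[, covariates, drop = FALSE]),
            covariates, drop = FALSE]
  vif <- vapply(covariates, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(covariates, v), response = v),
                     data = d)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  vif
}

.warn_vif <- function(data, covariates, scan) {
  if (length(covariates) < 2) return(invisible(NULL))
  numeric_covs <- covariates[vapply(covariates,
                                    function(v) is.numeric(data[[v]]), TRUE)]
  if (length(numeric_covs) < 2) return(invisible(NULL))
  vif <- variance_inflation(data, numeric_covs)
  if (any(vif >= 2))
    warning(sprintf("%s: covariate VIF >= 2 (%s)", scan,
                    paste(sprintf("%s=%.2f", names(vif)[vif >= 2],
                                  vif[vif >= 2]), collapse = ", ")))
  invisible(vif)
}

.adjust_roles <- function(data, adjust_for) {
  if (is.null(adjust_for) || !length(adjust_for)) return(character())
  if (is.null(names(adjust_for)) && is.character(adjust_for)) {
    roles <- vapply(adjust_for, function(v)
      if (is.numeric(data[[v]])) "numeric" else "categorical", "")
    stats::setNames(roles, adjust_for)
  } else adjust_for
}

#' Mutation (binary feature) volcano scan
#'
#' For every binary feature (e.g. gene mutated yes/no) with at least
#' `min_positive` positive samples, regress the score on the feature
#' indicator plus adjustment covariates (cohort is included as a categorical
#' covariate in pan-cancer scans); BH adjustment over the retained features.
#' The conventional filters are 20 mutated samples for all somatic mutations
#' and 10 for driver-mutation scans.
#'
#' @param score named `score_vector` (names = sample ids).
#' @param features feature-by-sample matrix in \{0, 1\}.
#' @param min_positive minimum positive samples for a feature to be tested.
#' @param adjust_for adjustment covariates: a data.frame column subset of
#'   `covariate_data` named by role (see [fit_linear_model()]), or a character
#'   vector of column names (roles inferred).
#' @param covariate_data data.frame of adjustment covariates, rownames =
#'   sample ids.
#' @return an [association_table()] over retained features (empty, with a
#'   warning, when none survives the filter).
#' @export
feature_scan <- function(score, features, min_positive = 20,
                         adjust_for = NULL, covariate_data = NULL) {
  if (min_positive < 1) stop("`min_positive` must be >= 1")
  samples <- intersect(names(score), colnames(features))
  if (!is.null(covariate_data))
    samples <- intersect(samples, rownames(covariate_data))
  feats <- features[, samples, drop = FALSE]
  npos <- rowSums(feats == 1, na.rm = TRUE)
  nlev <- apply(feats, 1, function(z) length(unique(z[!is.na(z)])))
  keep <- npos >= min_positive & nlev > 1
  filter_desc <- sprintf("min %d positive samples", min_positive)
  if (!any(keep)) {
    warning("no feature survives the filter (", filter_desc, ")")
    return(association_table(character(), numeric(), numeric(), integer(),
                             scan = "feature_scan", filter = filter_desc))
  }
  d0 <- data.frame(score = as.numeric(score[samples]), row.names = samples)
  roles <- .adjust_roles(covariate_data, adjust_for)
  for (v in names(roles)) d0[[v]] <- covariate_data[samples, v]
  .warn_vif(d0, names(roles), "feature_scan")
  rows <- lapply(rownames(feats)[keep], function(f) {
    d <- d0
    d$feature <- as.numeric(feats[f, ])
    fit <- fit_linear_model(d, "score",
                            c(c(feature = "numeric"), roles))
    fr <- fit[fit$covariate == "feature", ]
    data.frame(feature = f, estimate = fr$estimate, p = fr$p,
               n = attr(fit, "n_used"))
  })
  res <- do.call(rbind, rows)
  association_table(res$feature, res$estimate, res$p, res$n,
                    scan = "feature_scan", filter = filter_desc)
}

#' Chromosome-arm volcano scan
#'
#' Per arm, the score is regressed on two indicators -- deletion vs no
#' alteration and amplification vs no alteration -- plus adjustment
#' covariates. The arm's record keeps whichever indicator has the smaller
#' p-value; the direction label is `deletion-high` when the evidence says
#' deleted samples carry higher scores (deletion indicator with positive
#' coefficient, or amplification indicator with negative coefficient) and
#' `amplification-high` otherwise. BH over arms.
#'
#' @param score named `score_vector`.
#' @param arm_calls arm-by-sample matrix in \{-1, 0, +1\}.
#' @inheritParams feature_scan
#' @return an [association_table()] with an extra `direction_label` column;
#'   arms with a single call level are skipped with a warning.
#' @export
arm_scan <- function(score, arm_calls, adjust_for = NULL,
                     covariate_data = NULL) {
  stopifnot(all(arm_calls %in% c(-1L, 0L, 1L) | is.na(arm_calls)))
  samples <- intersect(names(score), colnames(arm_calls))
  if (!is.null(covariate_data))
    samples <- intersect(samples, rownames(covariate_data))
  calls <- arm_calls[, samples, drop = FALSE]
  d0 <- data.frame(score = as.numeric(score[samples]), row.names = samples)
  roles <- .adjust_roles(covariate_data, adjust_for)
  for (v in names(roles)) d0[[v]] <- covariate_data[samples, v]
  rows <- list()
  for (a in rownames(calls)) {
    lev <- unique(calls[a, ][!is.na(calls[a, ])])
    if (length(lev) < 2) {
      warning("arm '", a, "' has a single call level; skipped")
      next
    }
    d <- d0
    d$del <- as.numeric(calls[a, ] == -1)
    d$amp <- as.numeric(calls[a, ] == 1)
    covs <- c(del = "numeric", amp = "numeric")
    if (all(d$del == 0, na.rm = TRUE)) covs <- covs[-1]
    if (all(d$amp == 0, na.rm = TRUE)) covs <- covs[-length(covs)]
    fit <- fit_linear_model(d, "score", c(covs, roles))
    fr <- fit[fit$covariate %in% c("del", "amp"), ]
    pick <- fr[which.min(fr$p), ]
    label <- if ((pick$covariate == "del") == (pick$estimate > 0))
      "deletion-high" else "amplification-high"
    rows[[a]] <- data.frame(feature = a, estimate = pick$estimate, p = pick$p,
                            n = attr(fit, "n_used"),
                            indicator = pick$covariate,
                            direction_label = label)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(association_table(character(), numeric(), numeric(), integer(),
                             scan = "arm_scan"))
  out <- association_table(res$feature, res$estimate, res$p, res$n,
                           scan = "arm_scan")
  out$indicator <- res$indicator
  out$direction_label <- res$direction_label
  out
}

#' Mutational-signature contribution scan
#'
#' Per mutational signature, multiple regression of the score on that
#' signature's per-sample contribution plus the four z-scored
#' genomic-instability covariates (aneuploidy, mutation burden, CNA count,
#' clone count), so a signature association must hold independently of
#' overall instability. BH over signatures.
#'
#' @param score named `score_vector`.
#' @param contributions signature-by-sample matrix of non-negative
#'   contributions.
#' @param instability data.frame of instability covariates (rownames = sample
#'   ids); all are entered as `z_scored_numeric`.
#' @return an [association_table()]; signatures with < 2 distinct
#'   contribution values are skipped.
#' @export
signature_contribution_scan <- function(score, contributions, instability) {
  samples <- Reduce(intersect, list(names(score), colnames(contributions),
                                    rownames(instability)))
  d0 <- data.frame(score = as.numeric(score[samples]), row.names = samples)
  covs <- colnames(instability)
  for (v in covs) d0[[v]] <- instability[samples, v]
  roles <- stats::setNames(rep("z_scored_numeric", length(covs)), covs)
  .warn_vif(d0, covs, "signature_contribution_scan")
  rows <- list()
  for (s in rownames(contributions)) {
    contrib <- as.numeric(contributions[s, samples])
    if (length(unique(contrib[!is.na(contrib)])) < 2) next
    d <- d0
    d$contribution <- contrib
    fit <- fit_linear_model(d, "score", c(c(contribution = "numeric"), roles))
    fr <- fit[fit$covariate == "contribution", ]
    rows[[s]] <- data.frame(feature = s, estimate = fr$estimate, p = fr$p,
                            n = attr(fit, "n_used"))
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(association_table(character(), numeric(), numeric(), integer(),
                             scan = "signature_contribution_scan"))
  association_table(res$feature, res$estimate, res$p, res$n,
                    scan = "signature_contribution_scan")
}

#' Matched-normal arm anticipation test
#'
#' Asks whether normal samples whose matched tumours lost a given arm already
#' carry a higher score, using only normals that are themselves intact (call
#' 0) on that arm: rank-sum comparison of normal scores between "matched
#' tumour deleted" and "matched tumour not deleted".
#'
#' @param normal_scores named scores of normal samples.
#' @param normal_arm_calls arm-by-normal-sample call matrix (must be 0 on the
#'   tested arm for every normal supplied).
#' @param tumour_arm_status arm-by-normal-sample matrix of the matched
#'   tumour's call on each arm.
#' @param arms arms to test (default all rows of `tumour_arm_status`).
#' @return data.frame with `arm`, `p`, `direction` (`deleted-high` /
#'   `deleted-low`), `n_deleted`, `n_other`; `p` is `NA` with a warning when
#'   either group has fewer than 3 normals.
#' @export
matched_normal_arm_test <- function(normal_scores, normal_arm_calls,
                                    tumour_arm_status,
                                    arms = rownames(tumour_arm_status)) {
  samples <- intersect(names(normal_scores), colnames(tumour_arm_status))
  rows <- lapply(arms, function(a) {
    own <- normal_arm_calls[a, samples]
    if (any(own != 0, na.rm = TRUE))
      stop("normals with their own alteration on arm '", a,
           "' must be excluded before testing")
    status <- tumour_arm_status[a, samples]
    del <- normal_scores[samples][status == -1 & !is.na(status)]
    other <- normal_scores[samples][status != -1 & !is.na(status)]
    if (length(del) < 3 || length(other) < 3) {
      warning("arm '", a, "': a group has fewer than 3 normals; p not computed")
      return(data.frame(arm = a, p = NA_real_, direction = NA_character_,
                        n_deleted = length(del), n_other = length(other)))
    }
    ht <- rank_sum_compare(del, other)
    data.frame(arm = a, p = ht$p,
               direction = if (stats::median(del) >= stats::median(other))
                 "deleted-high" else "deleted-low",
               n_deleted = length(del), n_other = length(other))
  })
  do.call(rbind, rows)
}

#' Variance heterogeneity across groups (Fligner-Killeen)
#'
#' Rank-based test of equal score variances across groups, robust to
#' non-normality (used e.g. to ask whether score spread differs across
#' integrative clusters).
#'
#' @param values numeric vector.
#' @param groups group labels, at least two groups with >= 2 values each.
#' @return list with `statistic` and `p`.
#' @export
fligner_variance_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need at least two groups with two or more values each")
  ht <- stats::fligner.test(values, groups)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Signed amplification-vs-deletion balance per sample
#'
#' Two-sided equality-of-proportions test of a sample's amplification count
#' against its deletion count, reported as `-log10(p)` signed positive when
#' amplifications dominate and negative when deletions dominate (0 when the
#' counts balance).
#'
#' @param n_amp,n_del non-negative counts of amplifications and deletions per
#'   sample (vectorized).
#' @return numeric vector of signed log10 p-values.
#' @export
amplification_deletion_balance <- function(n_amp, n_del) {
  if (length(n_amp) != length(n_del)) stop("count vectors must align")
  mapply(function(a, d) {
    tot <- a + d
    if (tot == 0) stop("sample with no alterations: balance undefined")
    p <- suppressWarnings(stats::prop.test(a, tot, p = 0.5)$p.value)
    -log10(p) * sign(a - d)
  }, n_amp, n_del)
}

#' Two-way ANOVA interaction p-value
#'
#' Interaction term from `aov(values ~ group_a * group_b)`, used e.g. to test
#' whether the score-group effect on deletion bias depends on mutation
#' status.
#'
#' @param values numeric response.
#' @param group_a,group_b factors.
#' @return the interaction p-value.
#' @export
interaction_anova <- function(values, group_a, group_b) {
  group_a <- factor(group_a); group_b <- factor(group_b)
  if (nlevels(group_a) < 2 || nlevels(group_b) < 2)
    stop("both grouping factors need at least two levels")
  fit <- stats::aov(values ~ group_a * group_b)
  tab <- summary(fit)[[1]]
  idx <- grep(":", trimws(rownames(tab)))
  tab[idx, "Pr(>F)"]
}

#' Cluster cohorts by their association profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) of cohorts described by their -log10 association p-values across
#' features. Rows are sorted by label before clustering so the leaf order is
#' deterministic under input permutation.
#'
#' @param neglog_p cohort-by-feature numeric matrix of -log10 p-values.
#' @return list with `hclust` (the tree) and `order` (leaf labels in
#'   dendrogram order).
#' @export
cluster_association_profiles <- function(neglog_p) {
  if (nrow(neglog_p) < 2) stop("need at least 2 rows to cluster")
  if (any(!is.finite(neglog_p))) stop("matrix must be finite")
  m <- neglog_p[order(rownames(neglog_p)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  list(hclust = hc, order = rownames(m)[hc$order])
}
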