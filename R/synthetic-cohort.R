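#' Configuration for the synthetic multi-omic cohort generator
#'
#' Defines the statistical structure of a generated cohort: a continuous
#' latent centrosome-amplification level per sample drives the CA20 genes'
#' expression, the genomic-instability covariates, selected arm and mutation
#' probabilities, hypoxia/stromal/proliferation annotations and the survival
#' hazard. Defaults are the package's reference study conditions (see the
#' methods vignette); the planted coupling signs mirror the associations the
#' analyses are designed to detect: positive for aneuploidy, mutation
#' burden, CNA count, clone count and hypoxia, negative for stromal
#' infiltration; a deletion-coupled "5q"-like arm; a positively coupled
#' "TP53"-like and a negatively coupled "CDH1"-like mutation gene.
#'
#' @param n_cohorts number of cohorts.
#' @param tumours_per_cohort tumour samples per cohort.
#' @param n_genes total genes (>= 20; the first 20 are the CA20 genes).
#' @param frac_normal fraction of tumours that get a matched-normal sample.
#' @param beta_tumour latent shift of tumours over normals.
#' @param loading per-unit-latent log-expression increase of CA20 genes.
#' @param kappa named coupling coefficients for `aneuploidy`,
#'   `mutation_burden`, `n_cna`, `n_clones`, `hypoxia`, `stromal`.
#' @param arm_names chromosome-arm labels simulated.
#' @param coupled_arms named signs: -1 = deletion probability increases with
#'   the latent level, +1 = amplification probability increases.
#' @param coupled_mutations named signs for latent-coupled mutation genes.
#' @param n_mutation_genes total mutation genes (coupled ones included).
#' @param n_signatures mutational signatures simulated.
#' @param coupled_signatures named signs for latent-coupled signature
#'   contributions.
#' @param gamma log-hazard increase per latent unit.
#' @param sd_latent residual latent standard deviation.
#' @param sd_cohort cohort-offset standard deviation.
#' @param shared_normal_frac fraction of the tumour's individual latent
#'   residual inherited by its matched normal (lets a normal's score
#'   anticipate the tumour's coupled arm losses).
#' @param censor_days administrative censoring horizon (default 10 years).
#' @param seed integer seed; mandatory.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cohorts = 3,
                          tumours_per_cohort = 100,
                          n_genes = 60,
                          frac_normal = 0.2,
                          beta_tumour = 1.0,
                          loading = 0.25,
                          kappa = c(aneuploidy = 0.6, mutation_burden = 0.6,
                                    n_cna = 0.6, n_clones = 0.5,
                                    hypoxia = 0.7, stromal = -0.6),
                          arm_names = c("5q", "16p", "7p", "1q", "3p", "8q",
                                        "10p", "13q", "17p", "20q"),
                          coupled_arms = c("5q" = -1),
                          coupled_mutations = c(TP53 = 1, CDH1 = -1),
                          n_mutation_genes = 30,
                          n_signatures = 30,
                          coupled_signatures = c(S1 = 1, S12 = -1),
                          gamma = 0.8,
                          sd_latent = 1,
                          sd_cohort = 0.5,
                          shared_normal_frac = 0.6,
                          censor_days = 3650,
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (n_genes < 20) stop("`n_genes` must be at least 20 (CA20 genes)")
  stopifnot(n_cohorts >= 1, tumours_per_cohort >= 1,
            frac_normal >= 0, frac_normal <= 1,
            all(names(coupled_arms) %in% arm_names),
            n_mutation_genes >= length(coupled_mutations),
            n_signatures >= length(coupled_signatures))
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic multi-omic cohort bundle
#'
#' Draws a fully reproducible cohort under a [cohort_config()]: negative-
#' binomial RNA-seq counts (gene-wise log-normal dispersion) whose log-mean
#' for CA20 genes increases with the sample's latent level; sample
#' annotations with cohort, tumour/normal status, proliferation rate,
#' hypoxia/stromal scores and exponential survival with administrative
#' censoring; genomic-instability features, arm calls, binary mutations and
#' mutational-signature contributions coupled to the latent level per the
#' config. Matched normals share part of their tumour's latent residual and
#' are intact (call 0) on every simulated arm.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_bundle`: list with `expression` (raw counts),
#'   `samples` (annotation data.frame), `instability` (per-tumour covariate
#'   data.frame), `arm_calls`, `normal_arm_calls`, `tumour_arm_status_for_normals`,
#'   `mutations`, `signature_contributions`, and `latent` (the true latent
#'   vector, for recovery tests only).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  cohorts <- sprintf("COH%02d", seq_len(cfg$n_cohorts))
  n_tum <- cfg$n_cohorts * cfg$tumours_per_cohort
  tum_ids <- sprintf("T%04d", seq_len(n_tum))
  tum_cohort <- rep(cohorts, each = cfg$tumours_per_cohort)
  cohort_offset <- stats::setNames(stats::rnorm(cfg$n_cohorts, 0,
                                                cfg$sd_cohort), cohorts)
  eps_tum <- stats::rnorm(n_tum, 0, cfg$sd_latent)
  z_tum <- cohort_offset[tum_cohort] + cfg$beta_tumour + eps_tum

  n_norm_per <- round(cfg$frac_normal * cfg$tumours_per_cohort)
  norm_of <- unlist(lapply(seq_len(cfg$n_cohorts), function(k)
    seq_len(n_norm_per) + (k - 1) * cfg$tumours_per_cohort))
  n_norm <- length(norm_of)
  norm_ids <- if (n_norm) sprintf("N%04d", seq_len(n_norm)) else character()
  z_norm <- if (n_norm)
    cohort_offset[tum_cohort[norm_of]] +
      cfg$shared_normal_frac * eps_tum[norm_of] +
      stats::rnorm(n_norm, 0, cfg$sd_latent *
                     sqrt(1 - cfg$shared_normal_frac^2))
  else numeric()

  ids <- c(tum_ids, norm_ids)
  z <- stats::setNames(c(z_tum, z_norm), ids)

  # expression: first 20 genes are the CA20 genes, loaded on the latent level
  genes <- c(ca20_signature()$genes,
             if (cfg$n_genes > 20) sprintf("G%04d", seq_len(cfg$n_genes - 20)))
  base_log_mu <- stats::rnorm(cfg$n_genes, log(300), 0.7)
  size <- stats::rlnorm(cfg$n_genes, log(10), 0.5)
  load_vec <- c(rep(cfg$loading, 20), rep(0, cfg$n_genes - 20))
  mu <- exp(outer(base_log_mu, rep(1, length(ids))) + outer(load_vec, z))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(size, length(ids))),
                   nrow = cfg$n_genes, dimnames = list(genes, ids))
  expression <- expression_table(counts, "raw_counts")

  # sample annotation
  matched_normal <- rep(NA_character_, n_tum)
  if (n_norm) matched_normal[norm_of] <- norm_ids
  prolif <- 0.03 + 0.008 * z + stats::rnorm(length(z), 0, 0.008)
  hypoxia <- cfg$kappa[["hypoxia"]] * z + stats::rnorm(length(z), 0, 1)
  stromal <- cfg$kappa[["stromal"]] * z + stats::rnorm(length(z), 0, 1)
  immune <- -0.3 * z + stats::rnorm(length(z), 0, 1)
  h0 <- log(2) / 1095
  t_true <- stats::rexp(n_tum, rate = h0 * exp(cfg$gamma * (z_tum - mean(z_tum))))
  surv_time <- pmin(t_true, cfg$censor_days)
  event <- as.integer(t_true <= cfg$censor_days)
  samples <- data.frame(
    sample = ids,
    cohort = c(tum_cohort, tum_cohort[norm_of]),
    sample_type = c(rep("tumour", n_tum), rep("normal", n_norm)),
    matched_normal_id = c(matched_normal, rep(NA_character_, n_norm)),
    proliferation_rate = prolif,
    hypoxia_covariate = hypoxia,
    stromal_covariate = stromal,
    immune_covariate = immune,
    survival_time = c(surv_time, rep(NA_real_, n_norm)),
    event = c(event, rep(NA_integer_, n_norm)),
    row.names = ids, stringsAsFactors = FALSE)

  # instability covariates (tumours only); coupled probabilities use the
  # centred latent so a coupling's sign changes who is affected, not the
  # marginal rate
  zt <- z_tum
  zc <- zt - mean(zt)
  instability <- data.frame(
    aneuploidy = pmax(0, round(8 + 3 * cfg$kappa[["aneuploidy"]] * zt +
                                 stats::rnorm(n_tum, 0, 3))),
    mutation_burden = exp(0.5 + cfg$kappa[["mutation_burden"]] * zt +
                            stats::rnorm(n_tum, 0, 0.6)),
    n_cna = pmax(0, round(20 + 8 * cfg$kappa[["n_cna"]] * zt +
                            stats::rnorm(n_tum, 0, 6))),
    n_clones = pmax(1, round(2.5 + cfg$kappa[["n_clones"]] * zt +
                               stats::rnorm(n_tum, 0, 1))),
    genome_doubling = pmin(2L, stats::rbinom(n_tum, 1,
                                             stats::plogis(-0.5 + 0.8 * zc)) +
                             stats::rbinom(n_tum, 1,
                                           stats::plogis(-3 + 0.5 * zc))),
    row.names = tum_ids)

  # arm calls
  arm_calls <- matrix(0L, length(cfg$arm_names), n_tum,
                      dimnames = list(cfg$arm_names, tum_ids))
  for (a in cfg$arm_names) {
    sgn <- if (a %in% names(cfg$coupled_arms)) cfg$coupled_arms[[a]] else 0
    p_del <- if (sgn < 0) stats::plogis(-1.5 + 1.2 * zc) else rep(0.10, n_tum)
    p_amp <- if (sgn > 0) stats::plogis(-1.5 + 1.2 * zc) else rep(0.10, n_tum)
    u <- stats::runif(n_tum)
    arm_calls[a, u < p_del] <- -1L
    arm_calls[a, u >= p_del & u < p_del + p_amp] <- 1L
  }
  normal_arm_calls <- matrix(0L, length(cfg$arm_names), n_norm,
                             dimnames = list(cfg$arm_names, norm_ids))
  tumour_arm_status_for_normals <-
    arm_calls[, norm_of, drop = FALSE]
  if (n_norm) colnames(tumour_arm_status_for_normals) <- norm_ids

  # binary mutations
  mut_genes <- c(names(cfg$coupled_mutations),
                 sprintf("MUT%02d",
                         seq_len(cfg$n_mutation_genes -
                                   length(cfg$coupled_mutations))))
  mutations <- matrix(0L, length(mut_genes), n_tum,
                      dimnames = list(mut_genes, tum_ids))
  for (g in mut_genes) {
    sgn <- if (g %in% names(cfg$coupled_mutations))
      cfg$coupled_mutations[[g]] else 0
    pm <- stats::plogis(stats::qlogis(0.15) + 1.2 * sgn * zc)
    mutations[g, ] <- stats::rbinom(n_tum, 1, pm)
  }

  # mutational-signature contributions (non-negative, sum to 1 per sample)
  sig_names <- c(names(cfg$coupled_signatures),
                 sprintf("SIG%02d",
                         seq_len(cfg$n_signatures -
                                   length(cfg$coupled_signatures))))
  w <- matrix(stats::rgamma(cfg$n_signatures * n_tum, shape = 0.5),
              cfg$n_signatures, n_tum, dimnames = list(sig_names, tum_ids))
  for (s in names(cfg$coupled_signatures))
    w[s, ] <- w[s, ] * exp(0.8 * cfg$coupled_signatures[[s]] * zc)
  contributions <- sweep(w, 2, colSums(w), "/")

  structure(list(expression = expression, samples = samples,
                 instability = instability, arm_calls = arm_calls,
                 normal_arm_calls = normal_arm_calls,
                 tumour_arm_status_for_normals = tumour_arm_status_for_normals,
                 mutations = mutations,
                 signature_contributions = contributions,
                 latent = z, config = cfg),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d genes x %d samples (%d tumour, %d normal), %d cohorts\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$samples$sample_type == "tumour"),
              sum(x$samples$sample_type == "normal"),
              length(unique(x$samples$cohort))))
  invisible(x)
}

#' Score a cohort bundle with a signature
#'
#' Convenience pipeline: normalize raw counts, median-centre across all
#' loaded samples (tumours and normals together), and compute the metagene
#' score.
#'
#' @param bundle a `cohort_bundle` (or an `expression_table`).
#' @param signature a `gene_signature` (default CA20).
#' @param center_by optional per-sample centering groups (see
#'   [median_center()]).
#' @return a `score_vector` named by sample.
#' @export
score_cohort <- function(bundle, signature = ca20_signature(),
                         center_by = NULL) {
  expr <- if (inherits(bundle, "cohort_bundle")) bundle$expression else bundle
  if (expr_state(expr) == "raw_counts") expr <- normalize_counts(expr)
  if (expr_state(expr) == "log_quantile") expr <- median_center(expr, center_by)
  metagene_score(expr, signature)
}

#' Write a cohort bundle as a directory of TSV files
#'
#' Writes `expression.tsv`, `samples.tsv`, `instability.tsv`,
#' `arm_calls.tsv`, `mutations.tsv`, `signature_contributions.tsv` and a
#' `manifest.tsv` listing the files.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(bundle$expression, file.path(dir, "expression.tsv"))
  utils::write.table(bundle$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  wmat <- function(m, f, id) {
    d <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(d)[1] <- id
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  d <- data.frame(sample = rownames(bundle$instability), bundle$instability)
  utils::write.table(d, file.path(dir, "instability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  wmat(bundle$arm_calls, "arm_calls.tsv", "arm")
  wmat(bundle$mutations, "mutations.tsv", "gene")
  wmat(bundle$signature_contributions, "signature_contributions.tsv",
       "signature")
  manifest <- data.frame(
    file = c("expression.tsv", "samples.tsv", "instability.tsv",
             "arm_calls.tsv", "mutations.tsv",
             "signature_contributions.tsv"),
    seed = bundle$config$seed)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
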