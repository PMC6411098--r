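# shared fixtures built in code

# tiny integer count table with unique ids
tiny_counts <- function(n_genes = 4, n_samples = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  expression_table(m, "raw_counts")
}

# a centred table with known values for score arithmetic (values listed
# gene-row by gene-row)
centred_table <- function(values, genes, samples) {
  expression_table(matrix(values, length(genes), length(samples), byrow = TRUE,
                          dimnames = list(genes, samples)),
                   "median_centred")
}

# reference cohort config used across simulation tests (the package defaults,
# sized down only in replicate-loop tests where noted)
null_cohort_config <- function(seed, ...) {
  cohort_config(
    n_cohorts = 2, tumours_per_cohort = 40, n_genes = 40, frac_normal = 0.25,
    beta_tumour = 0, shared_normal_frac = 0,
    kappa = c(aneuploidy = 0, mutation_burden = 0, n_cna = 0, n_clones = 0,
              hypoxia = 0, stromal = 0),
    coupled_arms = c("5q" = 0), coupled_mutations = c(TP53 = 0, CDH1 = 0),
    coupled_signatures = c(S1 = 0, S12 = 0), gamma = 0,
    n_mutation_genes = 15, n_signatures = 10, seed = seed, ...)
}

# independent brute-force BH step-up: q_i = min over j with p_j >= p_i of
# min(1, p_j * n / rank_j)
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  qmin <- 1
  for (i in rev(seq_len(n))) {
    idx <- ord[i]
    qmin <- min(qmin, p[idx] * n / i)
    q[idx] <- qmin
  }
  q
}

# independent enrichment-score walk used as GSEA oracle
es_brute <- function(scores, hit, weight) {
  ord <- order(-scores, names(scores), method = "radix")
  scores <- scores[ord]; hit <- hit[ord]
  w <- abs(scores)^weight
  run <- 0; best <- 0
  for (i in seq_along(scores)) {
    run <- run + if (hit[i]) unname(w[i]) / sum(w[hit]) else -1 / sum(!hit)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
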