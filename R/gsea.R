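#' Preranked gene-set enrichment score
#'
#' Classical weighted Kolmogorov-Smirnov running sum over a ranked gene
#' list. Genes are ordered by decreasing score (ties broken by gene id so the
#' walk is deterministic); set members ("hits") increment the running sum by
#' `|score|^weight` normalized by the hit total, non-members decrement by
#' `1/(N - N_hits)`. The enrichment score is the extremum of largest
#' magnitude: positive when the set concentrates at the top of the ranking,
#' negative at the bottom.
#'
#' @param ranked named numeric vector: gene id -> ranking score (e.g. a
#'   signed -log10 p or a connectivity score). Names must be unique, scores
#'   finite.
#' @param gene_set a `gene_signature` (or character vector of gene ids).
#' @param weight exponent on |score| for hit increments; 1 is the standard
#'   default, 0 gives the unweighted KS statistic.
#' @return the enrichment score, in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- if (inherits(gene_set, "gene_signature")) gene_set$genes
           else as.character(gene_set)
  ranked <- .check_ranked(ranked)
  hit <- names(ranked) %in% genes
  if (!any(hit)) stop("gene set has no overlap with the ranked list")
  if (all(hit)) stop("gene set covers the entire ranked list")
  .es_from_hits(ranked, hit, weight)
}

.check_ranked <- function(ranked) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop("`ranked` must be named with unique gene ids")
  if (any(!is.finite(ranked))) stop("ranking scores must be finite")
  ord <- order(-ranked, names(ranked), method = "radix")
  ranked[ord]
}

.es_from_hits <- function(sorted_scores, hit, weight) {
  w <- abs(sorted_scores)^weight
  inc <- numeric(length(hit))
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / sum(!hit)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Permutation p-value for a gene-set enrichment score
#'
#' The null distribution is built by gene-label permutation: `n_perm` random
#' gene sets of the same size are drawn from the ranked list and scored. The
#' p-value counts null scores at least as extreme on the observed score's
#' sign side, with the +1 correction:
#' `p = (1 + #extreme) / (1 + n_perm)`. Phenotype permutation is undefined
#' for preranked lists, hence gene-label permutation throughout.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param seed integer seed; required for reproducibility.
#' @return list with `es`, `p`, `n_perm`.
#' @export
gsea_pvalue <- function(ranked, gene_set, weight = 1, n_perm = 1000, seed) {
  if (missing(seed)) stop("`seed` is required")
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse")
  genes <- if (inherits(gene_set, "gene_signature")) gene_set$genes
           else as.character(gene_set)
  sorted <- .check_ranked(ranked)
  hit <- names(sorted) %in% genes
  if (!any(hit)) stop("gene set has no overlap with the ranked list")
  if (all(hit)) stop("gene set covers the entire ranked list")
  es <- .es_from_hits(sorted, hit, weight)
  k <- sum(hit)
  n <- length(sorted)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(n)
    h[sample.int(n, k)] <- TRUE
    .es_from_hits(sorted, h, weight)
  }, 0)
  extreme <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
  list(es = es, p = (1 + extreme) / (1 + n_perm), n_perm = n_perm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Enrichment scan over a gene-set collection
#'
#' [gsea_pvalue()] for every set in a collection, with BH adjustment across
#' sets. FDR control is BH over the per-set permutation p-values (rather than
#' pooled normalized-ES FDR) for transparency.
#'
#' @inheritParams gsea_pvalue
#' @param gene_sets a named list of `gene_signature` objects (e.g. from
#'   [read_gene_sets()]); names must be unique.
#' @return data.frame with `set`, `es`, `p`, `q`, `size_used` (overlap with
#'   the ranked list); empty collection gives an empty table.
#' @export
enrichment_scan <- function(ranked, gene_sets, weight = 1, n_perm = 1000,
                            seed) {
  if (missing(seed)) stop("`seed` is required")
  if (!length(gene_sets))
    return(data.frame(set = character(), es = numeric(), p = numeric(),
                      q = numeric(), size_used = integer()))
  nms <- vapply(gene_sets, function(s)
    if (inherits(s, "gene_signature")) s$name else NA_character_, "")
  if (anyNA(nms)) stop("`gene_sets` must be a list of gene_signature objects")
  if (anyDuplicated(nms))
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  res <- lapply(seq_along(gene_sets), function(i) {
    r <- gsea_pvalue(ranked, gene_sets[[i]], weight = weight,
                     n_perm = n_perm, seed = seed + i)
    data.frame(set = nms[i], es = r$es, p = r$p,
               size_used = sum(names(ranked) %in% gene_sets[[i]]$genes))
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res[, c("set", "es", "p", "q", "size_used")]
}
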