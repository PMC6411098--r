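#' Gene signatures
#'
#' A `gene_signature` is a named, ordered list of gene identifiers.
#' Identifiers are case-sensitive symbols; no alias resolution is attempted
#' (mapping platform identifiers to the signature's namespace is the user's
#' responsibility).
#'
#' @param name signature name.
#' @param genes character vector of gene identifiers, non-empty, no duplicates.
#' @return a `gene_signature` object.
#' @export
gene_signature <- function(name, genes) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("`name` must be a non-empty string")
  genes <- as.character(genes)
  if (!length(genes)) stop("signature '", name, "' has no genes")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate genes in signature '", name, "': ",
         paste(dup, collapse = ", "))
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' The CA20 centrosome-amplification signature
#'
#' The 20 genes whose overexpression has been experimentally linked to
#' centrosome amplification; their summed median-centred log2 expression is
#' the CA20 score.
#'
#' @return a `gene_signature` of 20 genes.
#' @export
ca20_signature <- function() {
  gene_signature("CA20", c(
    "AURKA", "CCNA2", "CCND1", "CCNE2", "CDK1", "CEP63", "CEP152", "E2F1",
    "E2F2", "LMO4", "MDM2", "MYCN", "NDRG1", "NEK2", "PIN1", "PLK1", "PLK4",
    "SASS6", "STIL", "TUBG1"))
}

#' Synthetic centriole-duplication-factor list
#'
#' A stand-in for a curated centriole-duplication-factor gene list used in
#' knock-down enrichment analyses: 93 genes of which 10 belong to the CA20
#' signature. The 10 CA20 members are real centriole-biogenesis genes; the
#' remaining 83 identifiers are synthetic placeholders (`CDFxx`), so only the
#' list's composition (size and CA20 overlap) is meaningful, not its content.
#'
#' @return a `gene_signature` of 93 genes.
#' @export
synthetic_centriole_factors <- function() {
  ca20_members <- c("CEP63", "CEP152", "PLK4", "SASS6", "STIL", "PLK1",
                    "NEK2", "CDK1", "TUBG1", "AURKA")
  gene_signature("centriole_duplication_factors_synthetic",
                 c(ca20_members, sprintf("CDF%02d", seq_len(83))))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description is
#' discarded; member order is preserved.
#'
#' @param path path to a GMT file.
#' @return a named list of `gene_signature` objects (empty list for an empty
#'   file).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d fields; expected name, description and at least one member",
                   i, length(fields)))
    gene_signature(fields[1], fields[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#' @param sets a list of `gene_signature` objects.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_signature")) sets <- list(sets)
  writeLines(vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), ""), path)
  invisible(path)
}

#' Build a signature from candidates, dropping unmeasured and excluded genes
#'
#' Construction rule used for secondary metagenes (e.g. a hypoxia score built
#' from a published candidate list): keep candidates that are measured in the
#' expression data and not members of an exclusion signature, preserving the
#' candidate order. Removals are recorded by reason on the result.
#'
#' @param name name for the resulting signature.
#' @param candidates character vector of candidate gene identifiers.
#' @param measured character vector of genes measured in the dataset.
#' @param exclusions optional `gene_signature` whose members are removed (e.g.
#'   the CA20 signature itself, to keep two scores non-overlapping).
#' @return a `gene_signature` with attribute `removed`, a list with elements
#'   `unmeasured` and `excluded`.
#' @export
build_signature <- function(name, candidates, measured, exclusions = NULL) {
  if (!length(candidates)) stop("`candidates` must be non-empty")
  candidates <- as.character(candidates)
  unmeasured <- candidates[!candidates %in% measured]
  kept <- candidates[candidates %in% measured]
  excluded <- character()
  if (!is.null(exclusions)) {
    excluded <- kept[kept %in% exclusions$genes]
    kept <- kept[!kept %in% exclusions$genes]
  }
  if (!length(kept))
    stop("no candidate genes left after removing unmeasured and excluded genes")
  out <- gene_signature(name, kept)
  attr(out, "removed") <- list(unmeasured = unmeasured, excluded = excluded)
  out
}
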