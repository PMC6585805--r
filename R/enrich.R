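#' Map called peptides to parent gene symbols
#'
#' Consensus peptides covering different phospho-sites of one protein are
#' collapsed to a single gene symbol. The internal positive control is
#' dropped; the artificial ABL1 substrate maps to ABL1 through its
#' annotation record, so ABL1 enters the hit list whenever that peptide is
#' called.
#'
#' @param peptides character vector of (positive) peptide ids.
#' @param annotations annotation table from [read_peptide_annotations()].
#' @return sorted unique gene symbols (possibly empty).
#' @export
map_peptides_to_genes <- function(peptides, annotations = read_peptide_annotations()) {
  peptides <- unique(as.character(peptides))
  if (length(peptides) == 0L) return(character())
  idx <- match(peptides, annotations$peptide_id)
  if (anyNA(idx)) {
    kk_validation_error(sprintf("unannotated peptide(s): %s",
                                paste(kk_sort(peptides[is.na(idx)]), collapse = ", ")))
  }
  ann <- annotations[idx, , drop = FALSE]
  ann <- ann[!ann$is_internal_positive_control, , drop = FALSE]
  genes <- ann$gene_id[!is.na(ann$gene_id) & nzchar(ann$gene_id)]
  kk_sort(unique(toupper(genes)))
}

#' Right-tail hypergeometric gene-set enrichment
#'
#' Probability that a random hit list of size n drawn from a universe of N
#' genes overlaps a K-gene set in at least k genes: `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`. This is the one-sided Fisher test used as
#' a database-independent stand-in for proprietary pathway-enrichment
#' scores.
#'
#' @param hits character vector of hit genes.
#' @param gene_set character vector of set member genes.
#' @param background_size universe size N (default 20000, the order of the
#'   protein-coding genome).
#' @param set_name optional label carried into the result.
#' @return one-row data frame with `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `member_genes` (comma-separated overlap).
#' @export
hypergeom_enrichment <- function(hits, gene_set, background_size = 20000,
                                 set_name = NA_character_) {
  hits <- unique(toupper(hits))
  gene_set <- unique(toupper(gene_set))
  N <- as.integer(background_size)
  K <- length(gene_set)
  n <- length(hits)
  if (N < length(union(hits, gene_set))) {
    kk_validation_error("background_size smaller than the observed gene universe")
  }
  overlap <- kk_sort(intersect(hits, gene_set))
  k <- length(overlap)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(set_name = set_name, k = k, K = K, n = n, N = N,
             p_value = p, member_genes = paste(overlap, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Enrichment table and gene-by-set membership matrix
#'
#' Runs [hypergeom_enrichment()] for every (condition, gene set) pair and
#' builds the genes x sets matrix behind a two-condition pathway heat map:
#' for each hit gene and set, the cell says whether the gene is a set member
#' hit in `both` conditions, only the first (`a_only`), only the second
#' (`b_only`), or is not a member (`none`).
#'
#' @param hit_lists named list of per-condition gene hit vectors (two
#'   conditions for the membership matrix; the enrichment rows accept any
#'   number).
#' @param gene_sets a [read_gene_sets()] collection.
#' @param background_size universe size N.
#' @param p_adjust add Benjamini-Hochberg adjusted p-values per condition.
#' @return list with `results` (data frame: condition, set_name, k, K, n, N,
#'   p_value, optionally `p_adjusted`, member_genes) and `membership`
#'   (character matrix) when exactly two hit lists are given.
#' @export
enrichment_table <- function(hit_lists, gene_sets, background_size = 20000,
                             p_adjust = FALSE) {
  if (!length(gene_sets)) kk_validation_error("gene-set collection is empty")
  if (is.null(names(hit_lists)) || any(!nzchar(names(hit_lists)))) {
    kk_validation_error("hit_lists must be a named list (one entry per condition)")
  }
  rows <- lapply(names(hit_lists), function(cc) {
    res <- do.call(rbind, lapply(names(gene_sets), function(sn)
      hypergeom_enrichment(hit_lists[[cc]], gene_sets[[sn]],
                           background_size, set_name = sn)))
    res <- cbind(condition = cc, res, stringsAsFactors = FALSE)
    if (p_adjust) res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
    res
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  membership <- NULL
  if (length(hit_lists) == 2L) {
    a <- toupper(hit_lists[[1]])
    b <- toupper(hit_lists[[2]])
    genes <- kk_sort(union(a, b))
    membership <- matrix("none", length(genes), length(gene_sets),
                         dimnames = list(genes, names(gene_sets)))
    for (sn in names(gene_sets)) {
      inset <- genes %in% gene_sets[[sn]]
      flag <- ifelse(genes %in% a & genes %in% b, "both",
                     ifelse(genes %in% a, "a_only", "b_only"))
      membership[inset, sn] <- flag[inset]
    }
  }
  list(results = results, membership = membership)
}
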