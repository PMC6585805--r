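#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are uppercased
#' and deduplicated within each set so downstream matching is
#' case-insensitive.
#'
#' @param path GMT file.
#' @return named list of character vectors (one per set), with the set
#'   descriptions in the `"descriptions"` attribute; class `gene_sets`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) kk_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- fields[[i]]
    if (length(f) < 3L) {
      kk_format_error(sprintf("GMT line %d has fewer than 3 tab-separated fields", i))
    }
    nm <- f[1]
    if (nm %in% names(sets)) {
      kk_format_error(sprintf("GMT line %d: duplicate set name '%s'", i, nm))
    }
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  if (!length(sets)) kk_format_error("GMT file contains no gene sets")
  structure(sets, descriptions = desc, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Read a peptide annotation table
#'
#' Annotation rows map each array peptide to its parent protein label, HGNC
#' gene symbol and phospho-site span, and flag the artificial ABL1 substrate
#' and the internal positive control. The packaged default is a synthetic
#' reconstruction for the 67 published called peptides (gene symbols derived
#' from standard UniProt entry-name conventions) plus the internal control.
#'
#' @param path TSV with columns `peptide_id`, `protein_label`, `gene_id`,
#'   `site_start`, `site_end`, `is_artificial_control`,
#'   `is_internal_positive_control`; packaged fixture when `NULL`.
#' @return data frame with one row per peptide; gene symbols uppercased.
#' @export
read_peptide_annotations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "peptide_annotation_synthetic.tsv",
                        package = "kinomekin")
  }
  if (!nzchar(path) || !file.exists(path)) {
    kk_io_error(sprintf("annotation file not found: %s", path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("peptide_id", "protein_label", "gene_id", "site_start",
                "site_end", "is_artificial_control",
                "is_internal_positive_control")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    kk_format_error(sprintf("annotation table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$peptide_id)) {
    kk_validation_error("annotation table has duplicate peptide_id rows")
  }
  both <- !is.na(df$site_start) & !is.na(df$site_end)
  if (any(df$site_start[both] > df$site_end[both])) {
    kk_validation_error("site_start must be <= site_end")
  }
  df$gene_id <- toupper(df$gene_id)
  df$is_artificial_control <- as.logical(df$is_artificial_control)
  df$is_internal_positive_control <- as.logical(df$is_internal_positive_control)
  df[required]
}
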