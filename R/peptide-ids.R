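#' Split array peptide identifiers into protein label and site span
#'
#' Array peptide ids encode the parent protein and the first/last amino-acid
#' position of the spotted peptide, underscore-delimited, e.g. `CDK2_8_20`.
#' The split is taken from the right: when the last two tokens are both
#' integers they are the site span and the remainder is the protein label;
#' otherwise the whole id is the label with an absent span (this keeps
#' artificial substrates such as `ART_004_EAIYAAPFAKKKXC` intact, and
#' handles numeric protein labels such as the band-4.1 peptide `41_654_666`).
#'
#' @param peptide_id character vector of ids.
#' @return data frame with columns `peptide_id`, `protein_label`,
#'   `site_start`, `site_end` (`NA` when absent).
#' @examples
#' parse_peptide_id(c("CDK2_8_20", "ART_004_EAIYAAPFAKKKXC"))
#' @export
parse_peptide_id <- function(peptide_id) {
  peptide_id <- as.character(peptide_id)
  if (length(peptide_id) == 0L || any(is.na(peptide_id)) || any(!nzchar(peptide_id))) {
    kk_validation_error("peptide_id must be a non-empty string")
  }
  toks <- strsplit(peptide_id, "_", fixed = TRUE)
  label <- peptide_id
  start <- rep(NA_integer_, length(peptide_id))
  end <- rep(NA_integer_, length(peptide_id))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    n <- length(tk)
    if (n >= 3L && grepl("^[0-9]+$", tk[n - 1L]) && grepl("^[0-9]+$", tk[n])) {
      label[i] <- paste(tk[seq_len(n - 2L)], collapse = "_")
      start[i] <- as.integer(tk[n - 1L])
      end[i] <- as.integer(tk[n])
    }
  }
  data.frame(peptide_id = peptide_id, protein_label = label,
             site_start = start, site_end = end, stringsAsFactors = FALSE)
}
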