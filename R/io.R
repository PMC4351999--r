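#' Read a FASTA file into a record table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; the record id is
#' the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `record_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  tibble::tibble(record_id = ids, sequence = as.character(ss))
}

#' Write a record table to FASTA
#'
#' @param records Tibble with `record_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_record_table(records)
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$record_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Read a taxonomy table
#'
#' A tab-separated table with columns `record_id`, `phylum`, `class`,
#' `order`, `family`, `genus`, `species`. Cells may be empty below the
#' deepest assigned rank; assigned ranks must form a contiguous prefix
#' (no species without a genus).
#'
#' @param path Path to the TSV file.
#' @return A validated taxonomy tibble (empty cells become `NA`).
#' @export
read_taxonomy <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  validate_taxonomy(tbl)
}

#' Validate a taxonomy table
#'
#' Checks required columns, unique record ids, and that assigned ranks form
#' a contiguous prefix from phylum downward.
#'
#' @param taxonomy A data frame with `record_id` plus the six rank columns.
#' @return The taxonomy as a tibble (invisibly validated).
#' @export
validate_taxonomy <- function(taxonomy) {
  needed <- c("record_id", TAXONOMY_RANKS)
  missing <- setdiff(needed, names(taxonomy))
  if (length(missing)) {
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(taxonomy$record_id)) {
    dup <- unique(taxonomy$record_id[duplicated(taxonomy$record_id)])
    stop("duplicate record_id in taxonomy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  assigned <- !is.na(as.matrix(taxonomy[, TAXONOMY_RANKS]))
  # a rank assigned while a shallower rank is not breaks the prefix rule
  holes <- assigned[, -1, drop = FALSE] & !assigned[, -ncol(assigned),
                                                    drop = FALSE]
  if (any(holes)) {
    bad <- taxonomy$record_id[apply(holes, 1, any)]
    stop("non-contiguous rank assignment (gap above an assigned rank) for: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(taxonomy[, needed])
}

# Full-path taxon keys at a rank, to disambiguate homonymous labels under
# different parents. NA where the rank is unassigned.
lineage_keys <- function(taxonomy, rank) {
  stopifnot(rank %in% TAXONOMY_RANKS)
  upto <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
  m <- as.matrix(taxonomy[, upto, drop = FALSE])
  keys <- apply(m, 1, paste, collapse = "|")
  keys[is.na(taxonomy[[rank]])] <- NA_character_
  keys
}

#' Write a taxonomy table to TSV
#'
#' @param taxonomy Taxonomy tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(validate_taxonomy(taxonomy), path, progress = FALSE)
  invisible(path)
}
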