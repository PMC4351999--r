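#' Find primer binding sites within a mismatch budget
#'
#' Exhaustively scans every window of primer length along the sequence and
#' reports those whose IUPAC-aware Hamming distance to the primer is at most
#' `max_mismatch`. Coordinates are 0-based, half-open, on the strand of the
#' sequence as given; the primer is not reverse-complemented here.
#'
#' @param seq IUPAC nucleotide string (the subject, 5'->3').
#' @param primer A [primer()] object or IUPAC string.
#' @param max_mismatch Non-negative integer mismatch budget.
#' @return A tibble with columns `start`, `end` (0-based half-open) and
#'   `mismatches`, ordered by ascending `start`. A primer longer than the
#'   sequence yields zero rows (not an error).
#' @examples
#' find_primer_sites("AAACGTAAA", "ACGT", max_mismatch = 0)
#' @export
find_primer_sites <- function(seq, primer, max_mismatch) {
  stopifnot(length(max_mismatch) == 1L, max_mismatch >= 0)
  pbits <- encode_iupac(primer_sequence(primer), what = "primer")
  sbits <- encode_iupac(seq)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          mismatches = integer())
  mm <- window_mismatches(sbits, pbits)
  if (is.null(mm)) return(empty)
  keep <- which(mm <= max_mismatch)
  if (!length(keep)) return(empty)
  tibble::tibble(
    start = keep - 1L,
    end = keep - 1L + length(pbits),
    mismatches = mm[keep]
  )
}

# Mismatch count for every window, vectorized over window starts:
# one bitwAnd pass per primer position. Returns NULL if the sequence is
# shorter than the primer.
window_mismatches <- function(sbits, pbits) {
  L <- length(pbits)
  n <- length(sbits)
  if (n < L) return(NULL)
  nwin <- n - L + 1L
  mm <- integer(nwin)
  for (j in seq_len(L)) {
    mm <- mm + (bitwAnd(sbits[j:(j + nwin - 1L)], pbits[j]) == 0L)
  }
  mm
}

#' Virtually amplify a single record with one primer pair
#'
#' Searches both strands for (forward site, downstream reverse site) pairs.
#' The reverse primer is given 5'->3' and is matched as its reverse
#' complement downstream of each forward site. Every pair whose full
#' product length falls within `[min_full_length, max_full_length]` yields
#' one amplicon.
#'
#' Coordinates are always reported on the + strand (0-based, half-open);
#' the `strand` column records the orientation of the hit. For `-` strand
#' amplicons the forward-primer footprint therefore has the larger
#' coordinates. `inner_length` counts the bases strictly between the two
#' primer footprints (the spacer-bearing region); `full_length` includes
#' both footprints, so `full_length = inner_length + len(fwd) + len(rev)`.
#'
#' @param sequence IUPAC nucleotide string.
#' @param primers A [primer_set()] (or one row of a primer-set tibble).
#' @param max_mismatch Per-primer mismatch budget, applied to the forward
#'   and reverse primers separately (not summed).
#' @param min_full_length,max_full_length Inclusive bounds on the product
#'   length including primer footprints.
#' @param record_id Identifier copied into the output.
#' @return Tibble with one row per amplicon: `record_id`, `strand`,
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end`, `inner_length`,
#'   `full_length`, `fwd_mismatches`, `rev_mismatches`.
#' @export
amplify_record <- function(sequence, primers, max_mismatch,
                           min_full_length = 100, max_full_length = 2000,
                           record_id = "record") {
  stopifnot(min_full_length > 0, min_full_length <= max_full_length)
  primers <- as_primer_set_single(primers)
  fwd <- primers$forward$sequence
  rev_rc <- reverse_complement(primers$reverse$sequence)
  sequence <- normalize_iupac(sequence)
  n <- nchar(sequence)

  one_strand <- function(s, strand) {
    fs <- find_primer_sites(s, fwd, max_mismatch)
    if (!nrow(fs)) return(NULL)
    rs <- find_primer_sites(s, rev_rc, max_mismatch)
    if (!nrow(rs)) return(NULL)
    pairs <- tidyr::expand_grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
    f_end <- fs$end[pairs$f]
    r_start <- rs$start[pairs$r]
    f_start <- fs$start[pairs$f]
    r_end <- rs$end[pairs$r]
    full <- r_end - f_start
    ok <- f_end <= r_start & full >= min_full_length & full <= max_full_length
    if (!any(ok)) return(NULL)
    out <- tibble::tibble(
      strand = strand,
      fwd_start = f_start[ok], fwd_end = f_end[ok],
      rev_start = r_start[ok], rev_end = r_end[ok],
      inner_length = (r_start - f_end)[ok],
      full_length = full[ok],
      fwd_mismatches = fs$mismatches[pairs$f][ok],
      rev_mismatches = rs$mismatches[pairs$r][ok]
    )
    if (strand == "-") {
      # map coordinates from the reverse-complement back to the + strand
      out <- dplyr::mutate(out,
        fwd_start0 = n - .data$fwd_end, fwd_end0 = n - .data$fwd_start,
        rev_start0 = n - .data$rev_end, rev_end0 = n - .data$rev_start,
        fwd_start = .data$fwd_start0, fwd_end = .data$fwd_end0,
        rev_start = .data$rev_start0, rev_end = .data$rev_end0
      )
      out <- dplyr::select(out, -dplyr::ends_with("0"))
    }
    out
  }

  hits <- dplyr::bind_rows(
    one_strand(sequence, "+"),
    one_strand(reverse_complement(sequence), "-")
  )
  if (!nrow(hits)) {
    return(empty_amplicon_tbl())
  }
  hits <- tibble::add_column(hits, record_id = record_id, .before = 1)
  # degenerate palindromic hits can duplicate within a strand
  hits <- dplyr::distinct(hits, .data$record_id, .data$strand,
                          .data$fwd_start, .data$rev_end, .keep_all = TRUE)
  dplyr::arrange(hits, .data$strand, .data$fwd_start, .data$rev_end)
}

empty_amplicon_tbl <- function() {
  tibble::tibble(
    record_id = character(), strand = character(),
    fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer(),
    inner_length = integer(), full_length = integer(),
    fwd_mismatches = integer(), rev_mismatches = integer()
  )
}

as_primer_set_single <- function(primers) {
  if (inherits(primers, "barisa_primer_set")) return(primers)
  if (is.data.frame(primers)) {
    if (nrow(primers) != 1L) {
      stop("expected a single primer set; got ", nrow(primers), " rows",
           call. = FALSE)
    }
    return(as_primer_set(primers))
  }
  stop("primers must be a primer_set or a one-row primer-set tibble",
       call. = FALSE)
}

#' Virtually amplify a database across a sweep of mismatch budgets
#'
#' Runs [amplify_record()] for every record and primer set at the largest
#' budget, then derives the result at each smaller budget by filtering
#' (both per-primer mismatch counts must be within the budget), which makes
#' the budget sweep exactly nested by construction. Within each
#' (primer set, budget, record) group the shortest product is flagged
#' `primary`: the fragment a capillary run would predominantly report,
#' since shorter products dominate PCR.
#'
#' @param records Tibble with columns `record_id` and `sequence`
#'   (see [read_fasta()]), or a named character vector of sequences.
#' @param primer_sets A primer-set tibble (possibly several rows) or a
#'   single [primer_set()].
#' @param budgets Integer vector of per-primer mismatch budgets, sorted
#'   ascending.
#' @param min_full_length,max_full_length Product length bounds, passed to
#'   [amplify_record()].
#' @return A tibble of class `barisa_amplification`: one row per
#'   (primer set, budget, amplicon), with the [amplify_record()] columns
#'   plus `primer_set`, `budget` and logical `primary`.
#' @export
amplify_database <- function(records, primer_sets, budgets = 0:3,
                             min_full_length = 100, max_full_length = 2000) {
  records <- as_record_table(records)
  if (anyDuplicated(records$record_id)) {
    dup <- unique(records$record_id[duplicated(records$record_id)])
    stop("duplicate record_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  budgets <- sort(unique(as.integer(budgets)))
  if (any(budgets < 0)) stop("budgets must be non-negative", call. = FALSE)
  sets <- primer_set_list(primer_sets)
  bmax <- max(budgets)

  per_set <- purrr::imap(sets, function(ps, nm) {
    hits <- purrr::map2(records$sequence, records$record_id, function(s, id) {
      amplify_record(s, ps, bmax, min_full_length, max_full_length,
                     record_id = id)
    })
    hits <- dplyr::bind_rows(hits)
    if (nrow(hits) == 0L) hits <- empty_amplicon_tbl()
    per_budget <- purrr::map(budgets, function(b) {
      sub <- dplyr::filter(hits, .data$fwd_mismatches <= b,
                           .data$rev_mismatches <= b)
      if (nrow(sub)) {
        sub <- dplyr::mutate(
          dplyr::group_by(sub, .data$record_id),
          primary = seq_len(dplyr::n()) == order(.data$full_length,
                                                 .data$fwd_start,
                                                 .data$strand)[1]
        )
        sub <- dplyr::ungroup(sub)
      } else {
        sub$primary <- logical()
      }
      tibble::add_column(sub, budget = b, .before = 1)
    })
    tibble::add_column(dplyr::bind_rows(per_budget), primer_set = nm,
                       .before = 1)
  })
  out <- dplyr::bind_rows(per_set)
  structure(
    out,
    budgets = budgets,
    primer_set_names = names(sets),
    n_records = nrow(records),
    class = c("barisa_amplification", class(tibble::tibble()))
  )
}

# The (primer_set, budget) combinations an amplicon table covers. Uses the
# sweep attributes when present so that all-negative screens still report
# explicit zero rows; falls back to the combinations present in the rows.
amp_combos <- function(amplicons) {
  budgets <- attr(amplicons, "budgets")
  sets <- attr(amplicons, "primer_set_names")
  if (!is.null(budgets) && !is.null(sets)) {
    return(tidyr::expand_grid(primer_set = sets, budget = budgets))
  }
  dplyr::distinct(tibble::as_tibble(amplicons[, c("primer_set", "budget")]))
}

as_record_table <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records))) {
      stop("a character vector of records must be named by record_id",
           call. = FALSE)
    }
    records <- tibble::tibble(record_id = names(records),
                              sequence = unname(records))
  }
  stopifnot(is.data.frame(records))
  missing <- setdiff(c("record_id", "sequence"), names(records))
  if (length(missing)) {
    stop("records table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(records[, c("record_id", "sequence")])
}

#' Record ids with at least one amplicon
#'
#' @param amplicons A `barisa_amplification` tibble from
#'   [amplify_database()].
#' @param budget,primer_set Optional filters; by default all rows are used.
#' @return Character vector of distinct record ids.
#' @export
amplified_ids <- function(amplicons, budget = NULL, primer_set = NULL) {
  x <- amplicons
  if (!is.null(budget)) x <- dplyr::filter(x, .data$budget == !!budget)
  if (!is.null(primer_set)) {
    x <- dplyr::filter(x, .data$primer_set == !!primer_set)
  }
  unique(x$record_id)
}
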