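#' Construct a primer
#'
#' A primer is a degenerate oligonucleotide stored 5'->3' with a role
#' (forward or reverse). The sequence is normalized to uppercase DNA
#' (U -> T) and validated against the IUPAC alphabet.
#'
#' @param name Primer name.
#' @param sequence IUPAC nucleotide string, 5'->3'.
#' @param role `"forward"` or `"reverse"`.
#' @return An object of class `barisa_primer`.
#' @examples
#' primer("ITSF", "GTCGTAACAAGGTAGCCGTA", "forward")
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_iupac(sequence, what = paste0("primer '", name, "'"))
  structure(
    list(name = name, sequence = sequence, role = role),
    class = "barisa_primer"
  )
}

#' @export
print.barisa_primer <- function(x, ...) {
  cat("<primer> ", x$name, " (", x$role, "): 5'-", x$sequence, "-3'\n",
      sep = "")
  invisible(x)
}

primer_sequence <- function(x) {
  if (inherits(x, "barisa_primer")) x$sequence else normalize_iupac(x, "primer")
}

primer_length <- function(x) nchar(primer_sequence(x))

#' Construct a primer set
#'
#' A forward/reverse primer pair defining one assay. Both primers are given
#' 5'->3'; the virtual PCR engine searches for the reverse primer's reverse
#' complement downstream of a forward site.
#'
#' @param name Set name.
#' @param forward,reverse [primer()] objects (or IUPAC strings, which are
#'   wrapped with default names `<name>_F` / `<name>_R`).
#' @return An object of class `barisa_primer_set`.
#' @export
primer_set <- function(name, forward, reverse) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(forward, "barisa_primer")) {
    forward <- primer(paste0(name, "_F"), forward, "forward")
  }
  if (!inherits(reverse, "barisa_primer")) {
    reverse <- primer(paste0(name, "_R"), reverse, "reverse")
  }
  if (forward$role != "forward" || reverse$role != "reverse") {
    stop("forward/reverse primers have mismatched roles", call. = FALSE)
  }
  structure(
    list(name = name, forward = forward, reverse = reverse),
    class = "barisa_primer_set"
  )
}

#' @export
print.barisa_primer_set <- function(x, ...) {
  cat("<primer set> ", x$name, "\n", sep = "")
  cat("  forward ", x$forward$name, ": 5'-", x$forward$sequence, "-3'\n",
      sep = "")
  cat("  reverse ", x$reverse$name, ": 5'-", x$reverse$sequence, "-3'\n",
      sep = "")
  invisible(x)
}

#' Read primer sets from a CSV/TSV table
#'
#' Expects columns `set_name`, `forward_name`, `forward_seq`,
#' `reverse_name`, `reverse_seq`. Sequences are validated and normalized.
#'
#' @param path Path to a comma- or tab-separated file (delimiter guessed
#'   from the extension: `.tsv`/`.tab` means tab).
#' @return A tibble with the five columns above, one row per primer set,
#'   sequences normalized to uppercase IUPAC DNA.
#' @seealso [default_primer_sets()] for the bundled B-ARISA assays.
#' @export
read_primer_sets <- function(path) {
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c("set_name", "forward_name", "forward_seq",
              "reverse_name", "reverse_seq")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    stop("primer table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- dplyr::select(tbl, dplyr::all_of(needed))
  if (anyDuplicated(tbl$set_name)) {
    stop("duplicate set_name in primer table", call. = FALSE)
  }
  tbl$forward_seq <- vapply(tbl$forward_seq, normalize_iupac, character(1),
                            what = "forward_seq")
  tbl$reverse_seq <- vapply(tbl$reverse_seq, normalize_iupac, character(1),
                            what = "reverse_seq")
  tibble::as_tibble(tbl)
}

#' Bundled B-ARISA primer sets
#'
#' The three published primer systems commonly used for bacterial ARISA
#' (1406f/23Sr, ITSF/ITSReub and S-D-Bact-1522-b-S-20/L-D-Bact-132-a-A-18),
#' shipped as a data file transcribed from the original publications that
#' introduced each assay.
#'
#' @return A primer-set tibble as returned by [read_primer_sets()].
#' @export
default_primer_sets <- function() {
  read_primer_sets(
    system.file("extdata", "primer_sets.csv", package = "barisa",
                mustWork = TRUE)
  )
}

#' Convert one row of a primer-set table to a primer_set object
#'
#' @param tbl A primer-set tibble (see [read_primer_sets()]).
#' @param set_name Which set to extract; defaults to the first row.
#' @return A [primer_set()] object.
#' @export
as_primer_set <- function(tbl, set_name = NULL) {
  if (inherits(tbl, "barisa_primer_set")) return(tbl)
  if (is.null(set_name)) set_name <- tbl$set_name[[1]]
  row <- tbl[tbl$set_name == set_name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("primer set '", set_name, "' not found (or duplicated) in table",
         call. = FALSE)
  }
  primer_set(
    row$set_name,
    forward = primer(row$forward_name, row$forward_seq, "forward"),
    reverse = primer(row$reverse_name, row$reverse_seq, "reverse")
  )
}

# Iterate a primer-set table (or single set object) as a list of
# barisa_primer_set objects.
primer_set_list <- function(primer_sets) {
  if (inherits(primer_sets, "barisa_primer_set")) {
    return(stats::setNames(list(primer_sets), primer_sets$name))
  }
  stopifnot(is.data.frame(primer_sets), nrow(primer_sets) >= 1L)
  sets <- lapply(primer_sets$set_name, function(nm) as_primer_set(primer_sets, nm))
  stats::setNames(sets, primer_sets$set_name)
}
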