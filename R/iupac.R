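# IUPAC nucleotide codes as 4-bit sets over {A, C, G, T}.
# Two codes are compatible iff their base sets intersect, i.e. the bitwise
# AND of their masks is non-zero. U is treated as T throughout.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

# Complement maps each base set to the set of its complements
# (A<->T, C<->G), which for degenerate codes gives R<->Y, K<->M, B<->V,
# D<->H and fixes S, W, N.
IUPAC_FROM <- "ACGTURYSWKMBDHVN"
IUPAC_TO   <- "TGCAAYRSWMKVHDBN"

#' Normalize a nucleotide string to the uppercase IUPAC DNA alphabet
#'
#' Uppercases the input and converts U to T. Every character must be one of
#' the 15 IUPAC nucleotide codes (plus U); anything else is an error naming
#' the offending character.
#'
#' @param seq A single character string.
#' @param what Label used in error messages.
#' @return The normalized string.
#' @examples
#' normalize_iupac("acgu") # "ACGT"
#' @export
normalize_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!nzchar(seq)) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  out <- chartr("u", "t", toupper(seq))
  out <- chartr("U", "T", out)
  chars <- strsplit(out, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% names(IUPAC_BITS))
  if (any(bad)) {
    stop(
      "invalid IUPAC character(s) in ", what, ": ",
      paste(unique(chars[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# Integer bit-mask encoding of a normalized IUPAC string.
encode_iupac <- function(seq, what = "sequence") {
  seq <- normalize_iupac(seq, what = what)
  unname(IUPAC_BITS[strsplit(seq, "", fixed = TRUE)[[1]]])
}

#' Do two IUPAC codes match?
#'
#' Two codes match iff the nucleotide sets they encode intersect, the
#' permissive convention used by in-silico PCR tools: `N` in either the
#' primer or the subject never counts as a mismatch, and degenerate codes
#' on both sides match whenever they share at least one concrete base.
#' The relation is symmetric.
#'
#' @param primer_base,sequence_base Single IUPAC characters (vectorized;
#'   recycled to a common length).
#' @return Logical vector.
#' @examples
#' iupac_match("Y", "C") # TRUE:  {C,T} contains C
#' iupac_match("R", "C") # FALSE: {A,G} disjoint from {C}
#' iupac_match("N", "W") # TRUE:  N intersects everything
#' @export
iupac_match <- function(primer_base, sequence_base) {
  a <- to_bits(primer_base, "primer_base")
  b <- to_bits(sequence_base, "sequence_base")
  bitwAnd(a, b) > 0L
}

to_bits <- function(x, what) {
  x <- toupper(as.character(x))
  x <- chartr("U", "T", x)
  bits <- IUPAC_BITS[x]
  if (anyNA(bits)) {
    stop(
      "invalid IUPAC character(s) in ", what, ": ",
      paste(unique(x[is.na(bits)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(bits)
}

#' Reverse-complement an IUPAC string
#'
#' Complements every code (degenerate codes included: R<->Y, K<->M, B<->V,
#' D<->H; S, W and N are self-complementary) and reverses the string. The
#' operation is an involution.
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse complement, uppercase, U normalized to T.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' reverse_complement("RYN")  # "NRY"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_iupac(seq)
  comp <- chartr(IUPAC_FROM, IUPAC_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Count mismatches between a primer and an equal-length window
#'
#' Pure Hamming distance under IUPAC set-intersection matching: no indels,
#' no positional weighting. A position is a mismatch iff [iupac_match()] is
#' `FALSE` there.
#'
#' @param primer A [primer()] object or an IUPAC string.
#' @param window IUPAC string of the same length as the primer.
#' @return Integer mismatch count in `[0, nchar(primer)]`.
#' @examples
#' count_mismatches("ACGT", "ACGA") # 1
#' count_mismatches("AYGT", "ATGG") # 1 (Y matches T; final T vs G does not)
#' @export
count_mismatches <- function(primer, window) {
  pbits <- encode_iupac(primer_sequence(primer), what = "primer")
  wbits <- encode_iupac(window, what = "window")
  if (length(pbits) != length(wbits)) {
    stop(
      "window length (", length(wbits), ") must equal primer length (",
      length(pbits), ")",
      call. = FALSE
    )
  }
  sum(bitwAnd(pbits, wbits) == 0L)
}
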