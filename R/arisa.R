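#' Bin fragment-length fingerprints into an OTU table
#'
#' ARISA discriminates taxa by the length of the amplified 16S-23S spacer
#' product; capillary sizing reports fractional fragment lengths, which are
#' binned on a fixed grid so peaks from the same template co-locate across
#' runs. The grid is anchored at `range[1]` with half-open bins of `window`
#' bases: a peak of length `x` falls in bin `floor((x - range[1]) / window)`,
#' so a peak exactly on a boundary goes to the upper bin. Peaks outside
#' `[range[1], range[2])` are dropped; abundances are summed within bins.
#'
#' @param fingerprints Tibble with columns `sample_id`, `fragment_length`,
#'   `abundance` (one row per called peak).
#' @param window Bin width in bases (default 2, the conventional ARISA
#'   window).
#' @param range Instrument range in bases, default `c(100, 1500)` (the
#'   length range of the bacterial spacer region).
#' @return A wide tibble of class `barisa_otu_table`: `sample_id` plus one
#'   column per occupied bin, named `bin_<start>`. Samples with no in-range
#'   peaks are dropped with a warning. Bin definitions are stored in the
#'   `bins` attribute (tibble `bin`, `start`, `end`).
#' @examples
#' fp <- tibble::tibble(sample_id = "s1",
#'                      fragment_length = c(100.4, 101.6, 103),
#'                      abundance = c(5, 3, 2))
#' bin_fragments(fp)
#' @export
bin_fragments <- function(fingerprints, window = 2, range = c(100, 1500)) {
  stopifnot(is.data.frame(fingerprints), window >= 1,
            length(range) == 2L, range[1] < range[2])
  missing <- setdiff(c("sample_id", "fragment_length", "abundance"),
                     names(fingerprints))
  if (length(missing)) {
    stop("fingerprints are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(fingerprints$abundance < 0, na.rm = TRUE)) {
    stop("negative abundance in fingerprints", call. = FALSE)
  }
  all_samples <- unique(fingerprints$sample_id)
  fp <- dplyr::filter(fingerprints,
                      .data$fragment_length >= range[1],
                      .data$fragment_length < range[2])
  fp <- dplyr::mutate(fp,
    bin = floor((.data$fragment_length - range[1]) / window)
  )
  binned <- dplyr::summarise(
    dplyr::group_by(fp, .data$sample_id, .data$bin),
    abundance = sum(.data$abundance),
    .groups = "drop"
  )
  kept <- dplyr::summarise(
    dplyr::group_by(binned, .data$sample_id),
    total = sum(.data$abundance), .groups = "drop"
  )
  kept <- kept$sample_id[kept$total > 0]
  dropped <- setdiff(all_samples, kept)
  if (length(dropped)) {
    warning("dropping sample(s) with no in-range signal: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  binned <- dplyr::filter(binned, .data$sample_id %in% kept)
  bins <- sort(unique(binned$bin))
  binned$bin_name <- sprintf("bin_%g", range[1] + binned$bin * window)
  wide <- tidyr::pivot_wider(
    dplyr::select(binned, "sample_id", "bin_name", "abundance"),
    names_from = "bin_name", values_from = "abundance", values_fill = 0
  )
  bin_defs <- tibble::tibble(
    bin = bins,
    start = range[1] + bins * window,
    end = pmin(range[1] + (bins + 1) * window, range[2])
  )
  structure(
    wide,
    bins = bin_defs, window = window, range = range,
    class = c("barisa_otu_table", class(tibble::tibble()))
  )
}

#' Extract the numeric sample-by-bin matrix from an OTU table
#'
#' @param otu A `barisa_otu_table` (or any wide tibble whose first column
#'   is `sample_id`).
#' @return Numeric matrix with sample ids as row names.
#' @export
otu_matrix <- function(otu) {
  stopifnot(is.data.frame(otu), "sample_id" %in% names(otu))
  m <- as.matrix(otu[, setdiff(names(otu), "sample_id"), drop = FALSE])
  rownames(m) <- otu$sample_id
  storage.mode(m) <- "double"
  m
}

#' Shannon diversity of an abundance vector
#'
#' `H = -sum(p_i * log(p_i))` over relative abundances `p_i` of the
#' non-zero bins; natural log by default (nats).
#'
#' @param x Non-negative abundance vector with positive sum.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index; 0 iff exactly one bin is occupied, `log(n)` for
#'   a uniform profile over `n` bins.
#' @export
shannon <- function(x, base = exp(1)) {
  check_abundance(x)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p)) / log(base)
}

#' OTU richness of an abundance vector
#'
#' @param x Non-negative abundance vector with positive sum.
#' @return Number of non-zero bins.
#' @export
richness <- function(x) {
  check_abundance(x)
  sum(x > 0)
}

check_abundance <- function(x) {
  if (!is.numeric(x) || anyNA(x)) {
    stop("abundance vector must be numeric without NA", call. = FALSE)
  }
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) <= 0) stop("abundance vector sums to zero", call. = FALSE)
  invisible(x)
}

#' Per-sample richness and Shannon diversity
#'
#' @param otu A `barisa_otu_table` from [bin_fragments()].
#' @param base Logarithm base for Shannon (default natural log).
#' @return Tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
diversity_stats <- function(otu, base = exp(1)) {
  m <- otu_matrix(otu)
  tibble::tibble(
    sample_id = rownames(m),
    richness = unname(apply(m, 1, richness)),
    shannon = unname(apply(m, 1, shannon, base = base))
  )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = sum(|a_i - b_i|) / sum(a_i + b_i)`; 0 for identical profiles,
#' 1 for disjoint supports.
#'
#' @param a,b Equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  check_pair(a, b)
  sum(abs(a - b)) / sum(a + b)
}

#' Jaccard dissimilarity (presence/absence) between two profiles
#'
#' `1 - |A intersect B| / |A union B|` over the sets of occupied bins.
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  check_pair(a, b)
  A <- a > 0
  B <- b > 0
  1 - sum(A & B) / sum(A | B)
}

check_pair <- function(a, b) {
  if (length(a) != length(b)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (sum(a) + sum(b) <= 0) {
    stop("both profiles are all-zero", call. = FALSE)
  }
  invisible(NULL)
}

#' Pairwise dissimilarity matrix for an OTU table
#'
#' Bray-Curtis on abundances (peak heights) or Jaccard on
#' presence/absence, computed with [vegan::vegdist()].
#'
#' @param otu A `barisa_otu_table`.
#' @param method `"bray"` or `"jaccard"`.
#' @return A `dist` object labelled by sample id.
#' @export
dissimilarity_matrix <- function(otu, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  m <- otu_matrix(otu)
  if (method == "bray") {
    vegan::vegdist(m, method = "bray")
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
}
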