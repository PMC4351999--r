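#' Plot rank-wise coverage across mismatch budgets
#'
#' @param coverage A [coverage_by_rank()] tibble.
#' @return A ggplot: proportion of taxa amplified vs budget, one panel per
#'   rank, coloured by primer set.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage,
    ggplot2::aes(x = .data$budget, y = .data$proportion,
                 colour = .data$primer_set, group = .data$primer_set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rank) +
    ggplot2::labs(x = "mismatch budget (per primer)",
                  y = "taxa amplified (%)", colour = "primer set") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-phylum species counts across the mismatch sweep
#'
#' Row-normalized by the number of species the database holds per phylum,
#' with the amplified/total counts printed in each cell.
#'
#' @param matrix_tbl A [phylum_mismatch_matrix()] tibble.
#' @return A ggplot.
#' @export
plot_mismatch_matrix <- function(matrix_tbl) {
  ggplot2::ggplot(matrix_tbl,
    ggplot2::aes(x = factor(.data$budget), y = .data$phylum,
                 fill = .data$fraction_amplified)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0(.data$n_species_amplified, "/",
                                  .data$n_species_total)),
      size = 3
    ) +
    ggplot2::facet_wrap(~primer_set) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "mismatch budget (per primer)", y = NULL,
                  fill = "fraction of\nspecies amplified") +
    ggplot2::theme_minimal()
}

#' Plot an ARISA fingerprint
#'
#' @param fingerprints Fingerprint tibble (`sample_id`, `fragment_length`,
#'   `abundance`).
#' @return A ggplot: one electropherogram-style panel per sample.
#' @export
plot_fingerprint <- function(fingerprints) {
  ggplot2::ggplot(fingerprints,
    ggplot2::aes(x = .data$fragment_length, xend = .data$fragment_length,
                 y = 0, yend = .data$abundance)) +
    ggplot2::geom_segment() +
    ggplot2::facet_wrap(~sample_id, scales = "free_y") +
    ggplot2::labs(x = "fragment length (bases)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname nmds_ordination
#' @param object A `barisa_nmds` object.
#' @param groups Optional group labels (named by sample id or in sample
#'   order) used for point colour.
#' @exportS3Method ggplot2::autoplot
autoplot.barisa_nmds <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  p <- if (is.null(groups)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  } else {
    g <- align_groups(groups, df$sample_id, nrow(df))
    df$group <- g
    ggplot2::ggplot(df, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                     colour = .data$group))
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                      label = sprintf("stress = %.3f", object$stress)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
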