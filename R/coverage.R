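#' Taxa with positive virtual amplification at a rank
#'
#' A taxon counts as amplified when at least one of its member records has
#' an amplicon. Records whose lineage is unassigned at the requested rank
#' are ignored. Taxa are identified by their full lineage path down to the
#' rank, so homonymous labels under different parents never collapse.
#'
#' @param amplicons A `barisa_amplification` tibble (optionally
#'   pre-filtered; use `budget`/`primer_set` to filter here).
#' @param taxonomy Taxonomy tibble covering every amplified record.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @param budget,primer_set Optional filters on the amplicon table.
#' @return Tibble of distinct lineage prefixes (columns `phylum` .. `rank`)
#'   among amplified records with the rank assigned.
#' @export
taxa_amplified <- function(amplicons, taxonomy, rank,
                           budget = NULL, primer_set = NULL) {
  stopifnot(rank %in% TAXONOMY_RANKS)
  taxonomy <- validate_taxonomy(taxonomy)
  ids <- amplified_ids(amplicons, budget = budget, primer_set = primer_set)
  unknown <- setdiff(ids, taxonomy$record_id)
  if (length(unknown)) {
    stop("amplified record(s) missing from taxonomy: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  upto <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
  sub <- taxonomy[taxonomy$record_id %in% ids & !is.na(taxonomy[[rank]]),
                  upto, drop = FALSE]
  dplyr::distinct(tibble::as_tibble(sub))
}

#' Rank-wise taxonomic coverage of a primer set sweep
#'
#' For every (primer set, budget, rank) combination, counts the taxa
#' represented in the database at that rank (the denominator: taxa with at
#' least one record, read from the taxonomy) and the taxa with at least one
#' virtually amplified member (the numerator), and reports the percentage.
#' Records unassigned at a rank are excluded from both counts at that rank.
#'
#' @param amplicons A `barisa_amplification` tibble from
#'   [amplify_database()].
#' @param taxonomy Taxonomy tibble covering all database records.
#' @param ranks Ranks to report (default: phylum through species).
#' @return Tibble with columns `primer_set`, `budget`, `rank`,
#'   `n_taxa_total`, `n_taxa_amplified`, `proportion` (percent, full
#'   precision). Proportions are non-decreasing in budget for fixed rank
#'   and primer set.
#' @export
coverage_by_rank <- function(amplicons, taxonomy, ranks = TAXONOMY_RANKS) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (nrow(taxonomy) == 0L) {
    stop("empty database: taxonomy has no records", call. = FALSE)
  }
  stopifnot(all(ranks %in% TAXONOMY_RANKS))
  combos <- amp_combos(amplicons)
  if (nrow(combos) == 0L) {
    stop("amplicon table has no (primer_set, budget) combinations; ",
         "run amplify_database() first", call. = FALSE)
  }
  totals <- vapply(ranks, function(r) {
    length(unique(stats::na.omit(lineage_keys(taxonomy, r))))
  }, integer(1))

  out <- purrr::pmap(combos, function(primer_set, budget) {
    purrr::map(ranks, function(r) {
      amp <- taxa_amplified(amplicons, taxonomy, r,
                            budget = budget, primer_set = primer_set)
      tibble::tibble(
        primer_set = primer_set, budget = budget, rank = r,
        n_taxa_total = totals[[r]], n_taxa_amplified = nrow(amp),
        proportion = 100 * nrow(amp) / totals[[r]]
      )
    })
  })
  out <- dplyr::bind_rows(out)
  out$rank <- factor(out$rank, levels = TAXONOMY_RANKS)
  dplyr::arrange(out, .data$primer_set, .data$rank, .data$budget)
}

#' Per-phylum species counts across a mismatch sweep
#'
#' The mismatch-sweep matrix: for each primer set and phylum, the number of
#' distinct species with at least one amplicon at each budget, together
#' with the total number of species the database holds for that phylum
#' (the denominator used for row-normalization). Rows are non-decreasing
#' across budgets because budget sweeps are nested.
#'
#' @inheritParams coverage_by_rank
#' @return Long tibble with columns `primer_set`, `phylum`, `budget`,
#'   `n_species_amplified`, `n_species_total` and `fraction_amplified`
#'   (the row-normalized copy). Use [tidyr::pivot_wider()] for the matrix
#'   layout, or [plot_mismatch_matrix()] for a heatmap.
#' @export
phylum_mismatch_matrix <- function(amplicons, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  species_key <- lineage_keys(taxonomy, "species")
  tax <- tibble::tibble(
    record_id = taxonomy$record_id,
    phylum = taxonomy$phylum,
    species_key = species_key
  )
  tax <- dplyr::filter(tax, !is.na(.data$species_key))
  totals <- dplyr::summarise(
    dplyr::group_by(tax, .data$phylum),
    n_species_total = dplyr::n_distinct(.data$species_key),
    .groups = "drop"
  )
  combos <- amp_combos(amplicons)
  counts <- purrr::pmap(combos, function(primer_set, budget) {
    ids <- amplified_ids(amplicons, budget = budget, primer_set = primer_set)
    sub <- dplyr::filter(tax, .data$record_id %in% ids)
    n <- dplyr::summarise(
      dplyr::group_by(sub, .data$phylum),
      n_species_amplified = dplyr::n_distinct(.data$species_key),
      .groups = "drop"
    )
    tibble::add_column(n, primer_set = primer_set, budget = budget,
                       .before = 1)
  })
  counts <- dplyr::bind_rows(counts)
  grid <- tidyr::expand_grid(combos, phylum = totals$phylum)
  out <- dplyr::left_join(grid, counts,
                          by = c("primer_set", "budget", "phylum"))
  out <- dplyr::left_join(out, totals, by = "phylum")
  out$n_species_amplified[is.na(out$n_species_amplified)] <- 0L
  out$fraction_amplified <- out$n_species_amplified / out$n_species_total
  dplyr::arrange(out, .data$primer_set, .data$phylum, .data$budget)
}

#' Non-target specificity screen
#'
#' Runs the virtual PCR sweep on each non-target database (chloroplast-,
#' mitochondrion-, fungus-, plant- or invertebrate-derived sequences) and
#' tabulates, per database, phylum, primer set and budget, how many species
#' are amplifiable out of how many the database holds. For a truly
#' bacteria-specific assay these counts stay at (or near) zero even at
#' generous mismatch budgets.
#'
#' @param nontarget_dbs Named list; each element is a list with `records`
#'   (record tibble) and `taxonomy` (taxonomy tibble), as returned by
#'   [generate_nontarget_db()].
#' @param primer_sets Primer-set tibble or [primer_set()].
#' @param budgets Mismatch budgets to sweep.
#' @param min_full_length,max_full_length Product length bounds.
#' @return Tibble with columns `database`, `primer_set`, `budget`,
#'   `phylum`, `species_amplified`, `species_total`.
#' @export
specificity_screen <- function(nontarget_dbs, primer_sets, budgets = 0:3,
                               min_full_length = 100,
                               max_full_length = 2000) {
  stopifnot(is.list(nontarget_dbs), length(nontarget_dbs) >= 1L,
            !is.null(names(nontarget_dbs)))
  out <- purrr::imap(nontarget_dbs, function(db, nm) {
    amp <- amplify_database(db$records, primer_sets, budgets,
                            min_full_length, max_full_length)
    pm <- phylum_mismatch_matrix(amp, db$taxonomy)
    tibble::tibble(
      database = nm,
      primer_set = pm$primer_set,
      budget = pm$budget,
      phylum = pm$phylum,
      species_amplified = pm$n_species_amplified,
      species_total = pm$n_species_total
    )
  })
  dplyr::bind_rows(out)
}
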