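#' Specification for synthetic two-group ARISA communities
#'
#' Describes a two-group community design (e.g. fertilized vs unfertilized
#' soil): an OTU pool with a configurable shared fraction between groups,
#' log-normal abundances, a multiplicative group effect on composition,
#' per-sample noise and random peak dropout.
#'
#' @param group_labels Two group names.
#' @param n_per_group Samples per group (>= 2).
#' @param n_otus Size of the OTU pool.
#' @param shared_fraction Fraction of the pool present in both groups;
#'   the remainder is split evenly into group-exclusive OTUs. With
#'   `shared_fraction = 0` the two groups have disjoint OTU supports.
#' @param effect_size Magnitude of the multiplicative group effect on
#'   shared-OTU abundances (0 = no compositional difference between
#'   groups beyond sampling noise).
#' @param meanlog,sdlog Log-normal parameters of baseline OTU intensities
#'   (arbitrary fluorescence units).
#' @param noise_sd Standard deviation of per-sample multiplicative
#'   log-normal noise.
#' @param dropout Per-sample probability that a pool OTU fails to yield a
#'   peak (models stochastic PCR/detection dropout and makes sample
#'   supports vary realistically).
#' @param fragment_range Fragment-length range in bases; one length per
#'   OTU is drawn uniformly from it (to 0.1 base, as from capillary
#'   sizing).
#' @param seed Master seed.
#' @return An object of class `barisa_community_spec`.
#' @export
community_spec <- function(group_labels = c("group1", "group2"),
                           n_per_group = 5, n_otus = 60,
                           shared_fraction = 1, effect_size = 0,
                           meanlog = 4, sdlog = 1, noise_sd = 0.3,
                           dropout = 0.1,
                           fragment_range = c(100, 1500), seed = 1) {
  stopifnot(length(group_labels) == 2L, n_per_group >= 2, n_otus >= 2,
            shared_fraction >= 0, shared_fraction <= 1, effect_size >= 0,
            noise_sd >= 0, dropout >= 0, dropout < 1,
            length(fragment_range) == 2L,
            fragment_range[1] < fragment_range[2])
  structure(
    list(group_labels = as.character(group_labels),
         n_per_group = as.integer(n_per_group),
         n_otus = as.integer(n_otus),
         shared_fraction = shared_fraction, effect_size = effect_size,
         meanlog = meanlog, sdlog = sdlog, noise_sd = noise_sd,
         dropout = dropout, fragment_range = fragment_range,
         seed = as.integer(seed)),
    class = "barisa_community_spec"
  )
}

#' Generate two-group ARISA fingerprints with known group labels
#'
#' Each OTU gets a fixed fragment length and a log-normal baseline
#' intensity; shared OTUs appear in both groups, group-exclusive OTUs in
#' one. Sample abundances multiply the baseline by a group effect
#' (`exp(effect_size * delta_otu * sign(group))`, with a fixed per-OTU
#' direction `delta_otu`) and per-sample log-normal noise; each pool OTU
#' independently drops out with probability `dropout`. Deterministic for
#' a fixed seed.
#'
#' @param spec A [community_spec()].
#' @return List with `fingerprints` (tibble `sample_id`,
#'   `fragment_length`, `abundance`), `groups` (tibble `sample_id`,
#'   `group`) and `otus` (tibble `otu`, `fragment_length`, `pool`, one of
#'   `"shared"` or a group label).
#' @export
generate_community_profiles <- function(spec) {
  stopifnot(inherits(spec, "barisa_community_spec"))
  withr::with_seed(substream_seed(spec$seed, "community"), {
    n <- spec$n_otus
    n_shared <- round(spec$shared_fraction * n)
    n_excl <- n - n_shared
    n_excl1 <- n_excl %/% 2L
    pool <- c(rep("shared", n_shared),
              rep(spec$group_labels[1], n_excl1),
              rep(spec$group_labels[2], n_excl - n_excl1))
    otus <- tibble::tibble(
      otu = sprintf("OTU%04d", seq_len(n)),
      fragment_length = round(stats::runif(n, spec$fragment_range[1],
                                           spec$fragment_range[2] - 0.1), 1),
      pool = pool
    )
    baseline <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
    delta <- stats::rnorm(n)

    samples <- list()
    groups <- list()
    i <- 0L
    for (g in seq_len(2L)) {
      glab <- spec$group_labels[g]
      sign_g <- c(1, -1)[g]
      in_pool <- which(pool %in% c("shared", glab))
      for (s in seq_len(spec$n_per_group)) {
        i <- i + 1L
        sid <- sprintf("%s_%02d", glab, s)
        repeat {
          keep <- in_pool[stats::runif(length(in_pool)) >= spec$dropout]
          if (length(keep) > 0) break
        }
        ab <- baseline[keep] *
          exp(spec$effect_size * delta[keep] * sign_g) *
          exp(stats::rnorm(length(keep), 0, spec$noise_sd))
        samples[[i]] <- tibble::tibble(
          sample_id = sid,
          fragment_length = otus$fragment_length[keep],
          abundance = ab
        )
        groups[[i]] <- tibble::tibble(sample_id = sid, group = glab)
      }
    }
    list(
      fingerprints = dplyr::bind_rows(samples),
      groups = dplyr::bind_rows(groups),
      otus = otus
    )
  })
}

#' Simulate an ARISA fingerprint from virtual-amplification results
#'
#' Links the virtual PCR half of the pipeline to the fingerprint half:
#' given a community (record abundances) and an amplification sweep, each
#' community member that amplified contributes one peak at the full
#' product length of its `primary` (shortest) amplicon, with the member's
#' abundance; members that failed to amplify contribute nothing, which is
#' exactly how primer bias removes taxa from real fingerprints.
#'
#' @param amplicons A `barisa_amplification` tibble.
#' @param community Tibble with columns `record_id`, `abundance` and
#'   optionally `sample_id` (default `"S1"`); or a named numeric vector.
#' @param budget,primer_set Select one (budget, primer set) combination
#'   from the sweep; may be omitted when the sweep holds only one.
#' @return Fingerprint tibble (`sample_id`, `fragment_length`,
#'   `abundance`), one row per amplified community member.
#' @export
simulate_fingerprint_from_db <- function(amplicons, community,
                                         budget = NULL, primer_set = NULL) {
  if (is.numeric(community) && !is.null(names(community))) {
    community <- tibble::tibble(record_id = names(community),
                                abundance = unname(community))
  }
  stopifnot(is.data.frame(community),
            all(c("record_id", "abundance") %in% names(community)))
  if (any(community$abundance < 0)) {
    stop("community abundances must be non-negative", call. = FALSE)
  }
  if (!"sample_id" %in% names(community)) community$sample_id <- "S1"

  amp <- amplicons
  if (!is.null(budget)) amp <- dplyr::filter(amp, .data$budget == !!budget)
  if (!is.null(primer_set)) {
    amp <- dplyr::filter(amp, .data$primer_set == !!primer_set)
  }
  combos <- dplyr::distinct(
    tibble::as_tibble(amp[, c("primer_set", "budget")])
  )
  if (nrow(combos) > 1L) {
    stop("amplicon table spans several (primer_set, budget) combinations; ",
         "select one via the budget/primer_set arguments", call. = FALSE)
  }
  amp <- dplyr::filter(tibble::as_tibble(amp), .data$primary)
  peaks <- dplyr::inner_join(
    community, amp[, c("record_id", "full_length")], by = "record_id"
  )
  out <- tibble::tibble(
    sample_id = peaks$sample_id,
    fragment_length = as.numeric(peaks$full_length),
    abundance = peaks$abundance
  )
  dplyr::arrange(out, .data$sample_id, .data$fragment_length)
}
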