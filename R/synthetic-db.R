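#' Specification for a synthetic reference database
#'
#' Describes a taxonomy-annotated mock database of rDNA-operon-like
#' records (16S tail, spacer of controlled length, 23S head) in which
#' primer binding sites are planted at exact, known mismatch counts. The
#' generator's ground truth is analytic, so pipeline output can be checked
#' for exact equality.
#'
#' @param n_species Number of species (one record per species).
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family
#'   Branching factors of the synthetic taxonomy; species are distributed
#'   round-robin over the resulting genera.
#' @param primer_sets Primer-set tibble (see [read_primer_sets()]); sites
#'   are planted for every set listed.
#' @param site_plan Named list, one numeric vector of length 4 per primer
#'   set (names must match `set_name`), giving the fraction of species
#'   planted with binding sites at exactly 0, 1, 2 and 3 mismatches (on
#'   both primers). Fractions must sum to at most 1; the remainder of the
#'   species carry no binding site for that set.
#' @param igs_range Spacer length range in bases (default `c(100, 1500)`,
#'   the span over which bacterial spacers vary).
#' @param igs_lengths `"even_grid"` (default) draws spacer lengths without
#'   replacement from the even integers in `igs_range`, so every record's
#'   product length is unique and 2-bp binning never merges two records;
#'   `"uniform"` draws integer lengths uniformly with replacement.
#' @param flank_length,spacer_length Lengths of the random flanking and
#'   inter-slot segments (constant across records, so product length
#'   differences reflect spacer length differences only).
#' @param seed Master seed; all stage-level randomness is derived from it.
#' @return An object of class `barisa_db_spec` (validated list).
#' @export
db_spec <- function(n_species = 200,
                    n_phyla = 5, classes_per_phylum = 2,
                    orders_per_class = 2, families_per_order = 2,
                    genera_per_family = 2,
                    primer_sets = default_primer_sets()[2, ],
                    site_plan = NULL,
                    igs_range = c(100, 1500),
                    igs_lengths = c("even_grid", "uniform"),
                    flank_length = 60, spacer_length = 8,
                    seed = 1) {
  igs_lengths <- match.arg(igs_lengths)
  stopifnot(n_species >= 1, n_phyla >= 1, classes_per_phylum >= 1,
            orders_per_class >= 1, families_per_order >= 1,
            genera_per_family >= 1, flank_length >= 10,
            spacer_length >= 1, length(igs_range) == 2L,
            igs_range[1] < igs_range[2])
  sets <- primer_set_list(primer_sets)
  if (is.null(site_plan)) {
    site_plan <- stats::setNames(
      rep(list(c(1, 0, 0, 0)), length(sets)), names(sets)
    )
  }
  if (!setequal(names(site_plan), names(sets))) {
    stop("site_plan names must match primer set names", call. = FALSE)
  }
  for (nm in names(site_plan)) {
    f <- site_plan[[nm]]
    if (length(f) != 4L || any(f < 0) || sum(f) > 1 + 1e-9) {
      stop("site_plan[['", nm, "']] must be 4 non-negative fractions ",
           "summing to at most 1", call. = FALSE)
    }
  }
  structure(
    list(
      n_species = as.integer(n_species),
      branching = c(
        phylum = as.integer(n_phyla), class = as.integer(classes_per_phylum),
        order = as.integer(orders_per_class),
        family = as.integer(families_per_order),
        genus = as.integer(genera_per_family)
      ),
      primer_sets = sets,
      site_plan = site_plan[names(sets)],
      igs_range = igs_range, igs_lengths = igs_lengths,
      flank_length = as.integer(flank_length),
      spacer_length = as.integer(spacer_length),
      seed = as.integer(seed)
    ),
    class = "barisa_db_spec"
  )
}

# Deterministic per-stage seed derived from the master seed.
substream_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A concrete ACGT window matching `primer_seq` at exactly `n_mismatch`
# positions. Mismatch positions are drawn among positions whose IUPAC set
# is not universal (an N position cannot mismatch); at those positions a
# base outside the primer's set is used, guaranteeing the exact count.
plant_site <- function(primer_seq, n_mismatch) {
  bits <- encode_iupac(primer_seq)
  bases <- c("A", "C", "G", "T")
  base_bits <- c(1L, 2L, 4L, 8L)
  eligible <- which(bits != 15L)
  if (n_mismatch > length(eligible)) {
    stop("cannot plant ", n_mismatch, " mismatches in primer ", primer_seq,
         ": only ", length(eligible), " non-N positions", call. = FALSE)
  }
  mm_pos <- if (n_mismatch > 0) sample(eligible, n_mismatch) else integer(0)
  out <- character(length(bits))
  for (i in seq_along(bits)) {
    ok <- bitwAnd(base_bits, bits[i]) > 0L
    pool <- if (i %in% mm_pos) bases[!ok] else bases[ok]
    out[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  paste(out, collapse = "")
}

# Build one operon-like record carrying (or lacking) binding sites for each
# primer set, with exact planted mismatch counts, and verify by scanning
# that no unplanned site exists anywhere at budget <= verify_budget.
# categories: integer vector per set (0..3) or NA for "no site".
# Returns sequence plus per-set layout ground truth.
build_operon_record <- function(sets, categories, igs_len, flank_length,
                                spacer_length, verify_budget = 3,
                                max_tries = 60) {
  K <- length(sets)
  igs_len <- as.integer(igs_len)
  flank_length <- as.integer(flank_length)
  spacer_length <- as.integer(spacer_length)
  fwd <- vapply(sets, function(s) s$forward$sequence, character(1))
  rev <- vapply(sets, function(s) s$reverse$sequence, character(1))
  Lf <- nchar(fwd)
  Lr <- nchar(rev)

  # fixed layout offsets (0-based): flank5 | [fslot spacer]xK | core |
  # [spacer rslot] x K (innermost set last planted first) | flank3
  f_off <- integer(K)
  pos <- flank_length
  for (k in seq_len(K)) {
    f_off[k] <- pos
    pos <- pos + Lf[k] + spacer_length
  }
  core_off <- pos
  pos <- pos + igs_len
  r_off <- integer(K)
  for (k in rev(seq_len(K))) {
    pos <- pos + spacer_length
    r_off[k] <- pos
    pos <- pos + Lr[k]
  }
  total <- pos + flank_length

  for (try in seq_len(max_tries)) {
    fslots <- character(K)
    rslots <- character(K)
    for (k in seq_len(K)) {
      if (is.na(categories[k])) {
        fslots[k] <- random_dna(Lf[k])
        rslots[k] <- random_dna(Lr[k])
      } else {
        fslots[k] <- plant_site(fwd[k], categories[k])
        rslots[k] <- reverse_complement(plant_site(rev[k], categories[k]))
      }
    }
    parts <- c(random_dna(flank_length))
    for (k in seq_len(K)) {
      parts <- c(parts, fslots[k], random_dna(spacer_length))
    }
    parts <- c(parts, random_dna(igs_len))
    for (k in rev(seq_len(K))) {
      parts <- c(parts, random_dna(spacer_length), rslots[k])
    }
    parts <- c(parts, random_dna(flank_length))
    seq <- paste(parts, collapse = "")
    stopifnot(nchar(seq) == total)

    if (verify_operon_record(seq, sets, categories, f_off, r_off,
                             verify_budget)) {
      gt <- tibble::tibble(
        primer_set = names(sets),
        fwd_mismatches = unname(as.integer(categories)),
        rev_mismatches = unname(as.integer(categories)),
        fwd_start = unname(f_off), fwd_end = unname(f_off + Lf),
        rev_start = unname(r_off), rev_end = unname(r_off + Lr),
        inner_length = unname(r_off - (f_off + Lf)),
        full_length = unname((r_off + Lr) - f_off)
      )
      return(list(sequence = seq, ground_truth = gt))
    }
  }
  stop("could not build a record free of unplanned binding sites after ",
       max_tries, " attempts; primer sets may conflict with each other ",
       "(spec infeasible)", call. = FALSE)
}

# TRUE iff every primer of every set hits the record exactly at its planted
# window (if any) and nowhere else within the verification budget, on
# either strand.
verify_operon_record <- function(seq, sets, categories, f_off, r_off,
                                 budget) {
  for (k in seq_along(sets)) {
    fwd <- sets[[k]]$forward$sequence
    rev <- sets[[k]]$reverse$sequence
    planted <- !is.na(categories[k]) && categories[k] <= budget
    fs <- find_primer_sites(seq, fwd, budget)
    want_f <- if (planted) as.integer(f_off[k]) else integer(0)
    if (!identical(fs$start, want_f)) return(FALSE)
    if (planted && any(fs$mismatches != categories[k])) return(FALSE)
    rs <- find_primer_sites(seq, reverse_complement(rev), budget)
    want_r <- if (planted) as.integer(r_off[k]) else integer(0)
    if (!identical(rs$start, want_r)) return(FALSE)
    if (planted && any(rs$mismatches != categories[k])) return(FALSE)
    # no minus-strand geometry anywhere
    if (nrow(find_primer_sites(seq, reverse_complement(fwd), budget)) > 0) {
      return(FALSE)
    }
    if (nrow(find_primer_sites(seq, rev, budget)) > 0) return(FALSE)
  }
  TRUE
}

# Synthetic taxonomy: n_species distributed round-robin over the genus
# tier of a balanced hierarchy with globally unique labels.
synthetic_taxonomy <- function(n_species, branching,
                               prefix = c(phylum = "Phy", class = "Cla",
                                          order = "Ord", family = "Fam",
                                          genus = "Gen")) {
  counts <- cumprod(branching)
  genus_total <- counts[["genus"]]
  # visit genera cycling across phyla so small databases still span the
  # whole hierarchy rather than filling the first phylum's block
  genus_order <- as.vector(t(matrix(seq_len(genus_total),
                                    ncol = branching[["phylum"]])))
  genus_idx <- genus_order[((seq_len(n_species) - 1L) %% genus_total) + 1L]
  idx_at <- function(rank) {
    per_genus <- genus_total / counts[[rank]]
    ((genus_idx - 1L) %/% per_genus) + 1L
  }
  lab <- function(rank) {
    sprintf("%s%03d", prefix[[rank]], idx_at(rank))
  }
  tibble::tibble(
    record_id = sprintf("REC%04d", seq_len(n_species)),
    phylum = lab("phylum"), class = lab("class"), order = lab("order"),
    family = lab("family"), genus = lab("genus"),
    species = sprintf("Spe%04d", seq_len(n_species))
  )
}

#' Generate a synthetic reference database with planted ground truth
#'
#' Builds one operon-like record per species according to a [db_spec()]:
#' a random 16S-tail flank, a forward binding site mutated at exactly the
#' planned number of positions (mutations always break the IUPAC match),
#' a spacer of planned length, the reverse-complemented reverse site
#' mutated likewise, and a random 23S-head flank. Each record is verified
#' by exhaustive scanning to carry no unplanned binding site within
#' mismatch budget 3 on either strand (flanks are rejection-resampled
#' until this holds), so the returned ground truth is exact, not
#' probabilistic. The whole construction is deterministic given the
#' spec's seed.
#'
#' @param spec A [db_spec()].
#' @return List with elements `records` (tibble `record_id`, `sequence`),
#'   `taxonomy` (tibble, see [read_taxonomy()]), `ground_truth` (list with
#'   `records`, the per record x primer set planted mismatch counts and
#'   product lengths, and `coverage`, the analytic rank x budget coverage
#'   table computed from the planting alone), and `spec`.
#' @export
generate_reference_db <- function(spec) {
  stopifnot(inherits(spec, "barisa_db_spec"))
  n <- spec$n_species
  sets <- spec$primer_sets
  K <- length(sets)

  taxonomy <- synthetic_taxonomy(n, spec$branching)

  # mismatch category per species per set: round(fraction * n) species per
  # category, assigned by a seeded shuffle; NA = no binding site
  categories <- matrix(NA_integer_, nrow = n, ncol = K,
                       dimnames = list(NULL, names(sets)))
  for (k in seq_len(K)) {
    counts <- round(spec$site_plan[[k]] * n)
    if (sum(counts) > n) {
      stop("site_plan for '", names(sets)[k], "' rounds to more species (",
           sum(counts), ") than available (", n, ")", call. = FALSE)
    }
    withr::with_seed(substream_seed(spec$seed, paste0("plan_", k)), {
      perm <- sample.int(n)
    })
    at <- 0L
    for (m in 0:3) {
      cnt <- counts[m + 1L]
      if (cnt > 0) categories[perm[(at + 1L):(at + cnt)], k] <- m
      at <- at + cnt
    }
  }

  igs <- withr::with_seed(substream_seed(spec$seed, "igs"), {
    grid <- seq(spec$igs_range[1], spec$igs_range[2] - 2L, by = 2L)
    if (spec$igs_lengths == "even_grid") {
      if (n <= length(grid)) sample(grid, n) else sample(grid, n, replace = TRUE)
    } else {
      sample(seq(spec$igs_range[1], spec$igs_range[2] - 1L), n,
             replace = TRUE)
    }
  })

  built <- withr::with_seed(substream_seed(spec$seed, "sequences"), {
    lapply(seq_len(n), function(s) {
      build_operon_record(sets, categories[s, ], igs[s],
                          spec$flank_length, spec$spacer_length)
    })
  })
  records <- tibble::tibble(
    record_id = taxonomy$record_id,
    sequence = vapply(built, `[[`, character(1), "sequence")
  )
  gt_records <- dplyr::bind_rows(
    lapply(seq_len(n), function(s) {
      tibble::add_column(built[[s]]$ground_truth,
                         record_id = taxonomy$record_id[s], .before = 1)
    })
  )
  gt_records$min_budget <- pmax(gt_records$fwd_mismatches,
                                gt_records$rev_mismatches)

  list(
    records = records,
    taxonomy = taxonomy,
    ground_truth = list(
      records = gt_records,
      coverage = analytic_coverage(gt_records, taxonomy)
    ),
    spec = spec
  )
}

# Analytic coverage table derived from the planting alone (never from
# scanning sequences): a species is amplifiable at budget b iff it carries
# sites on both primers with at most b mismatches.
analytic_coverage <- function(gt_records, taxonomy, budgets = 0:3,
                              ranks = TAXONOMY_RANKS) {
  out <- list()
  for (set_nm in unique(gt_records$primer_set)) {
    sub <- gt_records[gt_records$primer_set == set_nm, ]
    for (b in budgets) {
      ok_ids <- sub$record_id[!is.na(sub$min_budget) & sub$min_budget <= b]
      for (r in ranks) {
        keys <- lineage_keys(taxonomy, r)
        total <- length(unique(stats::na.omit(keys)))
        amp <- length(unique(stats::na.omit(
          keys[taxonomy$record_id %in% ok_ids]
        )))
        out[[length(out) + 1L]] <- tibble::tibble(
          primer_set = set_nm, budget = b, rank = r,
          n_taxa_total = total, n_taxa_amplified = amp,
          proportion = 100 * amp / total
        )
      }
    }
  }
  out <- dplyr::bind_rows(out)
  out$rank <- factor(out$rank, levels = TAXONOMY_RANKS)
  dplyr::arrange(out, .data$primer_set, .data$rank, .data$budget)
}

NONTARGET_PHYLA <- list(
  "chloroplast-like" = c("Chlorophyta", "Chromerida", "Euglenida"),
  "mitochondrial-like" = c("Chordata", "Arthropoda"),
  "plant-like" = c("Streptophyta", "Chlorophyta"),
  "fungal-like" = c("Ascomycota", "Basidiomycota"),
  "invertebrate-like" = c("Echinodermata", "Arthropoda", "Mollusca")
)

#' Generate a synthetic non-target database
#'
#' Emulates the organelle, plant, fungal or invertebrate databases used to
#' probe primer specificity. A fraction `contamination_fraction` of the
#' species carry planted binding sites (at `planted_mismatches` mismatches
#' on both primers, for every primer set supplied), mimicking the few
#' non-target species a bacterial assay can amplify; the rest are verified
#' by scanning to carry no binding site within budget 3 on either strand.
#'
#' @param kind One of `"chloroplast-like"`, `"mitochondrial-like"`,
#'   `"plant-like"`, `"fungal-like"`, `"invertebrate-like"`; fixes the
#'   phylum namespace so non-target reports never collide with bacterial
#'   ones.
#' @param n_species Number of species (one record each).
#' @param contamination_fraction Fraction in `[0, 1]` of species planted
#'   with binding sites; `round(f * n_species)` species are planted.
#' @param primer_sets Primer-set tibble or [primer_set()]; sites (and the
#'   site-free guarantee) apply to every listed set.
#' @param planted_mismatches Mismatch count for the planted sites
#'   (default 0).
#' @param record_length Length of clean (site-free) records.
#' @param seed Master seed.
#' @return List with `records`, `taxonomy` and `ground_truth` (tibble
#'   `record_id`, `primer_set`, `min_budget`; `NA` for clean records).
#' @export
generate_nontarget_db <- function(kind = names(NONTARGET_PHYLA),
                                  n_species = 100,
                                  contamination_fraction = 0,
                                  primer_sets = default_primer_sets()[2, ],
                                  planted_mismatches = 0,
                                  record_length = 400,
                                  seed = 1) {
  kind <- match.arg(kind)
  stopifnot(contamination_fraction >= 0, contamination_fraction <= 1,
            n_species >= 1, planted_mismatches %in% 0:3)
  sets <- primer_set_list(primer_sets)
  K <- length(sets)
  phyla <- NONTARGET_PHYLA[[kind]]
  n_cont <- round(contamination_fraction * n_species)

  prefix_tag <- toupper(substr(gsub("-like", "", kind), 1, 3))
  taxonomy <- tibble::tibble(
    record_id = sprintf("NT%s%04d", prefix_tag, seq_len(n_species)),
    phylum = phyla[((seq_len(n_species) - 1L) %% length(phyla)) + 1L],
    species = sprintf("NTSpe%s%04d", prefix_tag, seq_len(n_species))
  )
  taxonomy$class <- paste0(taxonomy$phylum, "_cls")
  taxonomy$order <- paste0(taxonomy$phylum, "_ord")
  taxonomy$family <- paste0(taxonomy$phylum, "_fam")
  taxonomy$genus <- paste0(taxonomy$phylum, "_gen")
  taxonomy <- taxonomy[, c("record_id", TAXONOMY_RANKS)]

  res <- withr::with_seed(substream_seed(seed, paste0("nontarget_", kind)), {
    which_cont <- if (n_cont > 0) sample.int(n_species, n_cont) else integer(0)
    seqs <- character(n_species)
    gt <- vector("list", n_species)
    for (s in seq_len(n_species)) {
      if (s %in% which_cont) {
        cat_vec <- rep(as.integer(planted_mismatches), K)
        igs_len <- sample(150:400, 1)
        rec <- build_operon_record(sets, cat_vec, igs_len,
                                   flank_length = 40, spacer_length = 6)
        seqs[s] <- rec$sequence
        gt[[s]] <- tibble::tibble(
          record_id = taxonomy$record_id[s],
          primer_set = names(sets),
          min_budget = as.integer(planted_mismatches)
        )
      } else {
        seqs[s] <- clean_random_record(sets, record_length)
        gt[[s]] <- tibble::tibble(
          record_id = taxonomy$record_id[s],
          primer_set = names(sets),
          min_budget = NA_integer_
        )
      }
    }
    list(seqs = seqs, gt = dplyr::bind_rows(gt))
  })

  list(
    records = tibble::tibble(record_id = taxonomy$record_id,
                             sequence = res$seqs),
    taxonomy = taxonomy,
    ground_truth = res$gt
  )
}

# Random sequence verified to carry no binding-site geometry for any of
# the given primer sets within budget 3, on either strand.
clean_random_record <- function(sets, record_length, budget = 3,
                                max_tries = 60) {
  for (try in seq_len(max_tries)) {
    seq <- random_dna(record_length)
    ok <- TRUE
    for (ps in sets) {
      for (p in c(ps$forward$sequence,
                  reverse_complement(ps$forward$sequence),
                  ps$reverse$sequence,
                  reverse_complement(ps$reverse$sequence))) {
        if (nrow(find_primer_sites(seq, p, budget)) > 0) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) return(seq)
  }
  stop("could not generate a site-free record after ", max_tries,
       " attempts", call. = FALSE)
}
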