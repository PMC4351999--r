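# Independent oracles used throughout the suite. These deliberately avoid
# the package's bitmask encoding: the match table is rebuilt here from the
# IUPAC set definitions, and the site scanner walks windows one by one.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_match_table <- local({
  codes <- names(iupac_sets)
  tab <- matrix(FALSE, length(codes), length(codes),
                dimnames = list(codes, codes))
  for (a in codes) {
    for (b in codes) {
      tab[a, b] <- length(intersect(iupac_sets[[a]], iupac_sets[[b]])) > 0
    }
  }
  tab
})

# Position-by-position scan for primer sites, one window at a time.
naive_find_sites <- function(seq, primer, max_mismatch) {
  codes <- rownames(naive_match_table)
  s <- match(strsplit(toupper(seq), "")[[1]], codes)
  p <- match(strsplit(toupper(primer), "")[[1]], codes)
  L <- length(p)
  n <- length(s)
  starts <- integer(0)
  mms <- integer(0)
  if (n >= L) {
    for (st in 0:(n - L)) {
      mm <- sum(!naive_match_table[cbind(p, s[(st + 1):(st + L)])])
      if (mm <= max_mismatch) {
        starts <- c(starts, st)
        mms <- c(mms, mm)
      }
    }
  }
  data.frame(start = starts, end = starts + L, mismatches = as.integer(mms))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random flank guaranteed (by the naive scanner) to carry no site for the
# given primers within `budget` mismatches, in either orientation.
site_free_flank <- function(n, primers, budget = 3) {
  repeat {
    s <- rand_dna(n)
    hit <- FALSE
    for (p in primers) {
      for (q in c(p, reverse_complement(p))) {
        if (nrow(naive_find_sites(s, q, budget)) > 0) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) return(s)
  }
}

# Mutate `window` at `k` currently-matching positions so each stops
# matching `primer` (checked against the naive table).
corrupt_window <- function(window, primer, k = 1) {
  w <- strsplit(window, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  matching <- which(mapply(function(a, b) naive_match_table[a, b], p, w))
  stopifnot(length(matching) >= k)
  for (i in sample(matching, k)) {
    bad <- setdiff(c("A", "C", "G", "T"), iupac_sets[[p[i]]])
    w[i] <- sample(bad, 1)
  }
  paste(w, collapse = "")
}

# Clarke's ANOSIM statistic written independently: explicit rank vectors
# over the condensed distance, no shared code with the package.
brute_anosim_R <- function(dmat, groups) {
  n <- nrow(dmat)
  rb <- c()
  rw <- c()
  dv <- c()
  wv <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dv <- c(dv, dmat[i, j])
      wv <- c(wv, groups[i] == groups[j])
    }
  }
  rk <- rank(dv)
  (mean(rk[!wv]) - mean(rk[wv])) / (length(dv) / 2)
}

# Exact permutation distribution of R over every distinct relabelling.
exhaustive_anosim <- function(dmat, groups) {
  n <- nrow(dmat)
  perms <- combn(n, sum(groups == groups[1]))
  stats <- apply(perms, 2, function(idx) {
    g <- rep("b", n)
    g[idx] <- "a"
    brute_anosim_R(dmat, g)
  })
  observed <- brute_anosim_R(dmat, groups)
  list(observed = observed, stats = stats,
       p_exact = mean(stats >= observed))
}

# Small planted database used by several files: returns the full
# generator output for a 40-species database with a mixed site plan.
# Cached per seed (the generator is deterministic, so this is safe).
.fixture_cache <- new.env(parent = emptyenv())
small_planted_db <- function(seed = 42) {
  key <- paste0("db", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_small_planted_db(seed)
  }
  .fixture_cache[[key]]
}

make_small_planted_db <- function(seed = 42) {
  ps <- default_primer_sets()[2, ]
  spec <- db_spec(
    n_species = 40, n_phyla = 3, classes_per_phylum = 2,
    orders_per_class = 1, families_per_order = 2, genera_per_family = 2,
    primer_sets = ps,
    site_plan = list("ITSF/ITSReub" = c(0.5, 0.2, 0.1, 0.05)),
    seed = seed
  )
  list(db = generate_reference_db(spec), primer_sets = ps, spec = spec)
}
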