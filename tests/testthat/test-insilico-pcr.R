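itsf <- "GTCGTAACAAGGTAGCCGTA"
itsreub <- "GCCAAGGCATCCACC"

test_that("find_primer_sites locates a planted exact site and nothing else", {
  set.seed(11)
  for (rep in 1:5) {
    x <- site_free_flank(150, c(itsf))
    y <- site_free_flank(200, c(itsf))
    seq <- paste0(x, itsf, y)
    hits <- find_primer_sites(seq, itsf, 0)
    expect_identical(hits$start, nchar(x))
    expect_identical(hits$mismatches, 0L)
  }
})

test_that("find_primer_sites degenerate cases", {
  expect_identical(nrow(find_primer_sites(strrep("A", 50), "CCCC", 0)), 0L)
  # budget = primer length reports every window
  hits <- find_primer_sites(rand_dna(30), "ACGT", 4)
  expect_identical(hits$start, 0:26)
  # primer longer than sequence: empty result, not an error
  expect_identical(nrow(find_primer_sites("ACG", "ACGTACGT", 3)), 0L)
})

test_that("find_primer_sites agrees exactly with the naive scanner", {
  set.seed(2024)
  primers <- c(itsf, itsreub, "TGYACACACCGCCCGT", "GGGTTBCCCCATTCRG")
  for (rep in 1:40) {
    seq <- rand_dna(sample(60:500, 1))
    p <- sample(primers, 1)
    for (b in c(0, 1, 3)) {
      got <- as.data.frame(find_primer_sites(seq, p, b))
      want <- naive_find_sites(seq, p, b)
      expect_identical(got$start, want$start)
      expect_identical(got$mismatches, want$mismatches)
    }
  }
})

test_that("find_primer_sites agrees with Biostrings ambiguity matching", {
  set.seed(77)
  for (rep in 1:10) {
    seq <- rand_dna(400)
    for (b in 0:2) {
      got <- find_primer_sites(seq, "GGGTTBCCCCATTCRG", b)
      m <- Biostrings::matchPattern(
        Biostrings::DNAString("GGGTTBCCCCATTCRG"),
        Biostrings::DNAString(seq),
        max.mismatch = b, fixed = FALSE
      )
      expect_identical(got$start, as.integer(Biostrings::start(m)) - 1L)
    }
  }
})

make_operon <- function(fwd, rev, igs_len, flank = 50) {
  x <- site_free_flank(flank, c(fwd, rev))
  y <- site_free_flank(flank, c(fwd, rev))
  mid <- site_free_flank(igs_len, c(fwd, rev))
  paste0(x, fwd, mid, reverse_complement(rev), y)
}

test_that("amplify_record recovers a planted operon with exact geometry", {
  set.seed(31)
  seq <- make_operon(itsf, itsreub, igs_len = 300)
  ps <- primer_set("test", itsf, itsreub)
  amp <- amplify_record(seq, ps, max_mismatch = 0)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$strand, "+")
  expect_identical(amp$inner_length, 300L)
  expect_identical(
    amp$full_length,
    300L + nchar(itsf) + nchar(itsreub)
  )
  expect_identical(amp$full_length,
                   amp$inner_length + nchar(itsf) + nchar(itsreub))
  expect_true(amp$fwd_end <= amp$rev_start)
})

test_that("a forward site without a reverse site yields no amplicon", {
  set.seed(32)
  x <- site_free_flank(100, c(itsf, itsreub))
  y <- site_free_flank(300, c(itsf, itsreub))
  seq <- paste0(x, itsf, y)
  ps <- primer_set("test", itsf, itsreub)
  expect_identical(nrow(amplify_record(seq, ps, 3)), 0L)
})

test_that("a one-mismatch reverse site appears only once the budget allows", {
  set.seed(33)
  rev1 <- corrupt_window(itsreub, itsreub, 1)
  x <- site_free_flank(60, c(itsf, itsreub))
  mid <- site_free_flank(250, c(itsf, itsreub))
  y <- site_free_flank(60, c(itsf, itsreub))
  seq <- paste0(x, itsf, mid, reverse_complement(rev1), y)
  ps <- primer_set("test", itsf, itsreub)
  expect_identical(nrow(amplify_record(seq, ps, 0)), 0L)
  amp <- amplify_record(seq, ps, 1)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$rev_mismatches, 1L)
  expect_identical(amp$fwd_mismatches, 0L)
})

test_that("product length bounds filter amplicons", {
  set.seed(34)
  seq <- make_operon(itsf, itsreub, igs_len = 300)
  ps <- primer_set("test", itsf, itsreub)
  expect_identical(
    nrow(amplify_record(seq, ps, 0, min_full_length = 400,
                        max_full_length = 2000)),
    0L
  )
  expect_identical(
    nrow(amplify_record(seq, ps, 0, min_full_length = 100,
                        max_full_length = 200)),
    0L
  )
})

test_that("amplification is strand-symmetric", {
  set.seed(35)
  ps <- primer_set("test", itsf, itsreub)
  for (rep in 1:4) {
    seq <- make_operon(itsf, itsreub, igs_len = sample(150:400, 1))
    a_fwd <- amplify_record(seq, ps, 1)
    a_rc <- amplify_record(reverse_complement(seq), ps, 1)
    key <- function(a) {
      df <- as.data.frame(a[, c("inner_length", "fwd_mismatches",
                                "rev_mismatches")])
      df[do.call(order, df), , drop = FALSE]
    }
    expect_equal(key(a_fwd), key(a_rc), ignore_attr = TRUE)
    expect_setequal(a_rc$strand, "-")
  }
})

test_that("amplify_database sweeps are nested across budgets", {
  fx <- small_planted_db()
  amp <- amplify_database(fx$db$records, fx$primer_sets, budgets = 0:3)
  ids <- lapply(0:3, function(b) amplified_ids(amp, budget = b))
  for (b in 1:3) {
    expect_true(all(ids[[b]] %in% ids[[b + 1]]))
  }
})

test_that("amplify_database results match the per-record ground truth", {
  fx <- small_planted_db()
  gt <- fx$db$ground_truth$records
  amp <- amplify_database(fx$db$records, fx$primer_sets, budgets = 0:3)
  for (b in 0:3) {
    want <- sort(gt$record_id[!is.na(gt$min_budget) & gt$min_budget <= b])
    expect_identical(sort(amplified_ids(amp, budget = b)), want)
  }
  # planted product lengths are reproduced exactly
  at3 <- dplyr::filter(tibble::as_tibble(amp), budget == 3)
  merged <- dplyr::inner_join(at3, gt, by = c("record_id", "primer_set"),
                              suffix = c("", "_gt"))
  expect_identical(merged$inner_length, merged$inner_length_gt)
  expect_identical(merged$full_length, merged$full_length_gt)
  expect_identical(merged$fwd_mismatches, merged$fwd_mismatches_gt)
})

test_that("amplify_database flags the shortest product as primary", {
  set.seed(36)
  # two reverse sites downstream: two products, the shorter one primary
  x <- site_free_flank(60, c(itsf, itsreub))
  m1 <- site_free_flank(150, c(itsf, itsreub))
  m2 <- site_free_flank(200, c(itsf, itsreub))
  y <- site_free_flank(60, c(itsf, itsreub))
  seq <- paste0(x, itsf, m1, reverse_complement(itsreub), m2,
                reverse_complement(itsreub), y)
  db <- tibble::tibble(record_id = "r1", sequence = seq)
  amp <- amplify_database(db, primer_set("test", itsf, itsreub),
                          budgets = 0)
  expect_identical(nrow(amp), 2L)
  expect_identical(amp$primary, amp$full_length == min(amp$full_length))
})

test_that("duplicate record ids are rejected by name", {
  db <- tibble::tibble(record_id = c("a", "a"),
                       sequence = c("ACGT", "ACGT"))
  expect_error(
    amplify_database(db, primer_set("t", itsf, itsreub)),
    "duplicate record_id: a"
  )
})

test_that("an empty database yields empty results at every budget", {
  db <- tibble::tibble(record_id = character(), sequence = character())
  amp <- amplify_database(db, primer_set("t", itsf, itsreub), budgets = 0:2)
  expect_identical(nrow(amp), 0L)
  expect_identical(attr(amp, "budgets"), 0:2)
})
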