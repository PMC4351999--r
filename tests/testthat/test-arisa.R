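test_that("binning assigns peaks to half-open 2-bp bins anchored at range start", {
  fp <- tibble::tibble(
    sample_id = "s1",
    fragment_length = c(100.4, 101.6, 103, 1499, 99.9),
    abundance = c(5, 0, 2, 1, 10)
  )
  otu <- bin_fragments(fp)
  m <- otu_matrix(otu)
  expect_identical(unname(m["s1", "bin_100"]), 5)
  expect_identical(unname(m["s1", "bin_102"]), 2)
  expect_identical(unname(m["s1", "bin_1498"]), 1)
  expect_identical(ncol(m), 3L) # 99.9 dropped, 101.6 merged into bin_100
  expect_identical(richness(m["s1", ]), 3L)
  # boundary peak goes to the upper bin
  otu2 <- bin_fragments(tibble::tibble(sample_id = "s", fragment_length = 102,
                                       abundance = 1))
  expect_identical(colnames(otu_matrix(otu2)), "bin_102")
})

test_that("binning conserves in-range total abundance", {
  set.seed(5)
  fp <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 50),
    fragment_length = runif(100, 80, 1600),
    abundance = rexp(100)
  )
  otu <- bin_fragments(fp)
  in_range <- fp$fragment_length >= 100 & fp$fragment_length < 1500
  want <- tapply(fp$abundance[in_range], fp$sample_id[in_range], sum)
  m <- otu_matrix(otu)
  expect_equal(unname(rowSums(m)[names(want)]), as.vector(want))
})

test_that("binning rejects negative abundances and drops empty samples", {
  expect_error(
    bin_fragments(tibble::tibble(sample_id = "s", fragment_length = 200,
                                 abundance = -1)),
    "negative"
  )
  fp <- tibble::tibble(sample_id = c("ok", "empty"),
                       fragment_length = c(200, 50), abundance = c(1, 1))
  expect_warning(otu <- bin_fragments(fp), "empty")
  expect_identical(otu$sample_id, "ok")
})

test_that("shannon and richness have their closed forms", {
  for (n in c(2, 5, 64)) {
    expect_equal(shannon(rep(3, n)), log(n), tolerance = 1e-12)
  }
  expect_identical(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), log(4) - 0.5 * log(2), tolerance = 1e-12)
  expect_equal(shannon(rep(1, 16), base = 2), 4, tolerance = 1e-12)
  expect_identical(richness(c(1, 0, 2, 0, 3)), 3L)
  expect_error(shannon(c(0, 0)), "zero")
  expect_error(richness(c(-1, 2)), "non-negative")
  # agreement with vegan on random profiles
  set.seed(6)
  for (rep in 1:10) {
    x <- rexp(20) * rbinom(20, 1, 0.7)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")))
  }
})

test_that("bray_curtis and jaccard match direct evaluation and vegan", {
  expect_identical(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(jaccard(c(1, 2, 0), c(4, 5, 0)), 0)
  expect_identical(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_identical(jaccard(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(0, 1, 2)), 4 / 6)
  expect_equal(jaccard(c(2, 1, 0), c(0, 1, 2)), 1 - 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(jaccard(c(1, 2), c(1, 2, 3)), "equal length")

  set.seed(7)
  m <- matrix(rexp(60) * rbinom(60, 1, 0.6), nrow = 6)
  m[rowSums(m) == 0, 1] <- 1
  vb <- as.matrix(vegan::vegdist(m, "bray"))
  vj <- as.matrix(vegan::vegdist(m, "jaccard", binary = TRUE))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(bray_curtis(m[i, ], m[j, ]), vb[i, j])
      expect_equal(jaccard(m[i, ], m[j, ]), vj[i, j])
    }
  }
})

test_that("dissimilarity_matrix wires methods through vegdist", {
  set.seed(8)
  otu <- bin_fragments(tibble::tibble(
    sample_id = rep(c("a", "b", "c"), each = 10),
    fragment_length = runif(30, 100, 1500),
    abundance = rexp(30)
  ))
  d <- dissimilarity_matrix(otu, "bray")
  expect_s3_class(d, "dist")
  expect_identical(attr(d, "Size"), 3L)
  m <- otu_matrix(otu)
  expect_equal(as.matrix(d)["a", "b"], bray_curtis(m["a", ], m["b", ]))
})

test_that("ANOSIM matches a hand-checkable exhaustive oracle", {
  # 4 samples, groups {1,2} vs {3,4}; distances chosen with clean ranks
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1 # within a
  d[3, 4] <- d[4, 3] <- 0.2 # within b
  d[1, 3] <- d[3, 1] <- 0.7
  d[1, 4] <- d[4, 1] <- 0.8
  d[2, 3] <- d[3, 2] <- 0.9
  d[2, 4] <- d[4, 2] <- 0.6
  g <- c("a", "a", "b", "b")
  ex <- exhaustive_anosim(d, g)
  fit <- anosim_test(d, g, n_perm = 999, seed = 1)
  expect_equal(fit$statistic, ex$observed)
  expect_equal(fit$statistic, 1) # all between > all within
  # permutation p agrees with exact enumeration within Monte-Carlo error
  expect_lt(abs(fit$p_value - ex$p_exact), 0.08)
  # and with vegan's implementation of the same statistic
  vg <- vegan::anosim(as.dist(d), g, permutations = 99)
  expect_equal(fit$statistic, unname(vg$statistic))
})

test_that("ANOSIM R agrees with the independent rank implementation", {
  set.seed(9)
  for (rep in 1:10) {
    n <- 8
    m <- matrix(rexp(n * 12), nrow = n)
    d <- as.matrix(vegan::vegdist(m, "bray"))
    g <- rep(c("x", "y"), each = 4)
    fit <- anosim_test(d, g, n_perm = 0)
    expect_equal(fit$statistic, brute_anosim_R(d, g))
    expect_gte(fit$statistic, -1)
    expect_lte(fit$statistic, 1)
  }
})

test_that("ANOSIM permutation p is bit-reproducible under a fixed seed", {
  set.seed(10)
  m <- matrix(rexp(96), nrow = 8)
  d <- vegan::vegdist(m, "bray")
  g <- rep(c("x", "y"), each = 4)
  f1 <- anosim_test(d, g, n_perm = 499, seed = 123)
  f2 <- anosim_test(d, g, n_perm = 499, seed = 123)
  expect_identical(f1$p_value, f2$p_value)
  expect_identical(f1$perm_stats, f2$perm_stats)
  # RNG state of the caller is untouched
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(anosim_test(d, g, n_perm = 99, seed = 5))
  expect_identical(runif(1), before)
})

test_that("ANOSIM validates its inputs", {
  d <- as.dist(matrix(c(0, 1, 1, 0), 2))
  expect_error(anosim_test(d, c("a", "b")), "at least 2")
  m <- matrix(runif(16), 4)
  expect_error(anosim_test(m, rep("a", 4)), "symmetric|zero")
})

test_that("ANOSIM is centered near zero under the null", {
  # modest replicate count here; the full null study runs in acceptance
  stats <- vapply(1:20, function(s) {
    prof <- generate_community_profiles(
      community_spec(n_per_group = 4, n_otus = 30, effect_size = 0,
                     seed = 1000 + s)
    )
    otu <- bin_fragments(prof$fingerprints)
    d <- dissimilarity_matrix(otu, "bray")
    g <- stats::setNames(prof$groups$group, prof$groups$sample_id)
    anosim_test(d, g, n_perm = 0)$statistic
  }, numeric(1))
  expect_lt(abs(mean(stats)), 0.1)
})

test_that("NMDS embeds easy geometries and validates dimensions", {
  # 3 equidistant points embed exactly in the plane
  d <- matrix(1, 3, 3) - diag(3)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  fit <- nmds_ordination(d, k = 2, seed = 4)
  expect_lt(fit$stress, 1e-6)
  expect_identical(tidy(fit)$sample_id, c("a", "b", "c"))
  expect_equal(colMeans(fit$points), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(nmds_ordination(d, k = 3), "at least")
})

test_that("duplicate samples land on coincident NMDS coordinates", {
  set.seed(12)
  m <- matrix(rexp(50), nrow = 5)
  m <- rbind(m, m[5, ]) # duplicate the last sample
  d <- vegan::vegdist(m, "bray")
  fit <- nmds_ordination(d, k = 2, seed = 3)
  expect_equal(fit$points[5, ], fit$points[6, ], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("NMDS stress does not increase with added dimensions", {
  set.seed(13)
  m <- matrix(rexp(120), nrow = 10)
  d <- vegan::vegdist(m, "bray")
  stress <- vapply(1:3, function(k) {
    nmds_ordination(d, k = k, seed = 21, try = 20)$stress
  }, numeric(1))
  expect_true(all(diff(stress) <= 1e-6))
})

test_that("compare_primer_sets computes Pearson r with t-test p-values", {
  st <- function(r, s) {
    tibble::tibble(sample_id = paste0("s", seq_along(r)),
                   richness = r, shannon = s)
  }
  a <- st(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(compare_primer_sets(a, a)$estimate, c(1, 1))
  b <- st(-c(1, 2, 3, 4), -c(1, 2, 3, 4))
  expect_equal(compare_primer_sets(a, b)$estimate, c(-1, -1))
  cmp <- compare_primer_sets(a, st(c(1, 3, 2, 4), c(1, 3, 2, 4)))
  expect_equal(cmp$estimate, c(0.8, 0.8))
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(cmp$p_value, rep(ct$p.value, 2))
  expect_error(
    compare_primer_sets(a, st(c(2, 2, 2, 2), c(1, 2, 3, 4))),
    "zero variance"
  )
  expect_error(compare_primer_sets(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(compare_primer_sets(a, st(1:4, 1:4)[c(1, 2, 3, 3), ]),
               "identical sample sets")
})

test_that("diversity_stats summarises per sample", {
  fp <- tibble::tibble(
    sample_id = rep(c("a", "b"), c(3, 1)),
    fragment_length = c(110, 120, 130, 500),
    abundance = c(1, 1, 1, 5)
  )
  st <- diversity_stats(bin_fragments(fp))
  expect_identical(st$richness, c(3L, 1L))
  expect_equal(st$shannon, c(log(3), 0))
})
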