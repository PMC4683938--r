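test_that("diversity metrics match hand arithmetic", {
  # one marker, genotypes AA / Aa / aa
  gm <- toy_gm(matrix(c(0L, 1L, 2L), 3, 1))
  part <- stats::setNames(rep("p1", 3), gm$sample_ids)
  div <- diversity_metrics(gm, part)
  expect_equal(div$maf_mean, 0.5)
  expect_equal(div$h_obs, 1 / 3)
  expect_equal(div$h_exp, 0.5)
  expect_identical(div$n_fixed, 0L)

  # population fixed at every marker
  gm <- toy_gm(matrix(0L, 4, 5))
  div <- diversity_metrics(gm, stats::setNames(rep("p", 4),
                                               gm$sample_ids))
  expect_equal(div$maf_mean, 0)
  expect_equal(div$h_obs, 0)
  expect_equal(div$h_exp, 0)
  expect_identical(div$n_fixed, 5L)

  # H_obs == H_exp at every marker -> t = 0, p = 1
  gm <- toy_gm(matrix(c(0L, 1L, 1L, 2L), 4, 6))
  div <- diversity_metrics(gm, stats::setNames(rep("p", 4),
                                               gm$sample_ids))
  expect_equal(div$t_het, 0)
  expect_equal(div$p_het, 1)

  # unbiased switch scales H_exp by 2n/(2n-1)
  gm <- toy_gm(matrix(c(0L, 1L, 2L), 3, 1))
  p1 <- stats::setNames(rep("p", 3), gm$sample_ids)
  expect_equal(diversity_metrics(gm, p1, unbiased = TRUE)$h_exp,
               0.5 * 6 / 5)
})

test_that("Weir-Cockerham theta and f behave at the extremes", {
  # opposite fixation at every locus -> theta = 1
  gm <- toy_gm(rbind(matrix(0L, 5, 20), matrix(2L, 5, 20)))
  fs <- wc_fstatistics(gm, two_pop_partition(gm, 5))
  expect_equal(fs$theta, 1)

  # one population duplicated as two "populations": the estimator's
  # sampling-variance correction assumes independent samples, so the
  # expectation is the small negative bias -1/(2n-1), not exactly 0
  sim <- balding_nichols(1500, fst = c(0.1), n_samples = 20, seed = 8)
  d <- sim$genotypes$dosages
  gm <- toy_gm(rbind(d, d))
  fs <- wc_fstatistics(gm, two_pop_partition(gm, 20))
  expect_equal(fs$theta, -1 / (2 * 20 - 1), tolerance = 0.05)
  expect_lt(abs(fs$theta), 0.05)

  # one population split at random into two halves -> theta ~ 0
  sim <- balding_nichols(2000, fst = 0.1, n_samples = 40, seed = 8)
  fs2 <- wc_fstatistics(sim$genotypes,
                        two_pop_partition(sim$genotypes, 20))
  expect_lt(abs(fs2$theta), 0.01)

  expect_error(wc_fstatistics(toy_gm(matrix(0L, 6, 4)),
                              two_pop_partition(toy_gm(matrix(0L, 6, 4)), 3)),
               "monomorphic")
})

test_that("per-locus theta matches the independently coded W&C oracle", {
  set.seed(21)
  sim <- balding_nichols(40, fst = c(0.05, 0.15, 0.3),
                         n_samples = c(9, 14, 6), seed = 31,
                         missing_rate = 0.1)
  gm <- sim$genotypes
  fs <- wc_fstatistics(gm, sim$partition)
  idx <- herdvar:::pop_indices(gm, sim$partition)
  for (l in seq_len(ncol(gm$dosages))) {
    counts <- lapply(idx, function(rows) {
      col <- gm$dosages[rows, l]
      col <- col[!is.na(col)]
      c(sum(col == 0), sum(col == 1), sum(col == 2))
    })
    counts <- counts[vapply(counts, sum, numeric(1)) > 0]
    if (length(counts) < 2) next
    comp <- wc_oracle_locus(counts)
    denom <- sum(comp)
    if (!is.finite(denom) || denom == 0) {
      expect_true(is.na(fs$per_locus_theta[l]))
    } else {
      expect_equal(unname(fs$per_locus_theta[l]),
                   unname(comp["a"] / denom), tolerance = 1e-12)
    }
  }
  # multi-locus estimators are ratios of summed components
  a <- fs$components$a; b <- fs$components$b; cc <- fs$components$c
  use <- is.finite(a + b + cc) & abs(a + b + cc) > 0
  expect_equal(fs$theta, sum(a[use]) / sum((a + b + cc)[use]),
               tolerance = 1e-12)
  expect_equal(fs$f, 1 - sum(cc[use]) / sum((b + cc)[use]),
               tolerance = 1e-12)
})

test_that("statistics are invariant to allele relabeling", {
  sim <- balding_nichols(300, fst = c(0.05, 0.1), n_samples = c(10, 10),
                         seed = 12)
  gm <- sim$genotypes
  flip <- gm
  flip$dosages <- 2L - flip$dosages
  flip <- genotype_matrix(flip$dosages, gm$markers, gm$sample_ids)
  part <- sim$partition
  expect_equal(wc_fstatistics(gm, part)$theta,
               wc_fstatistics(flip, part)$theta, tolerance = 1e-12)
  d1 <- diversity_metrics(gm, part); d2 <- diversity_metrics(flip, part)
  expect_equal(d1$h_obs, d2$h_obs)
  expect_equal(d1$n_fixed, d2$n_fixed)
  expect_equal(d1$maf_mean, d2$maf_mean)
})

test_that("Nei's distance matches hand arithmetic and its boundaries", {
  expect_equal(nei_distance(c(0.4, 0.7), c(0.4, 0.7)), 0)
  # single locus, p = 0.8 vs 0.3
  jx <- 0.8^2 + 0.2^2; jy <- 0.3^2 + 0.7^2
  jxy <- 0.8 * 0.3 + 0.2 * 0.7
  expect_equal(nei_distance(0.8, 0.3), -log(jxy / sqrt(jx * jy)),
               tolerance = 1e-12)
  expect_equal(nei_distance(0.8, 0.3), 0.5024, tolerance = 1e-4)
  expect_identical(nei_distance(1, 0), Inf)  # opposite fixation
  expect_error(nei_distance(NA_real_, NA_real_), "no loci")
  # D >= 0 for random frequency vectors
  set.seed(2)
  for (i in 1:20) {
    x <- runif(50); y <- runif(50)
    expect_gte(nei_distance(x, y), 0)
  }
})

test_that("pairwise F_ST bootstrap gives calibrated significance", {
  # identical populations: non-significant
  sim <- balding_nichols(800, fst = c(0, 0), n_samples = c(15, 15),
                         seed = 14)
  ds <- pairwise_fst(sim$genotypes, sim$partition, n_boot = 99, seed = 3)
  expect_gte(ds$p_value[1, 2], 0.2)

  # clearly differentiated pair: theta recovered, significant
  sim <- balding_nichols(5000, fst = c(0.15, 0.15),
                         n_samples = c(20, 20), seed = 15)
  ds <- pairwise_fst(sim$genotypes, sim$partition, n_boot = 99, seed = 3)
  expect_gt(ds$fst[1, 2], 0.10)
  expect_lt(ds$fst[1, 2], 0.20)
  expect_lte(ds$p_value[1, 2], 0.01)
  expect_identical(ds$fst, t(ds$fst))
  expect_equal(diag(ds$fst), stats::setNames(c(0, 0), sim$partition |>
                                               levels()))

  # same seed -> bit-identical bootstrap
  ds2 <- pairwise_fst(sim$genotypes, sim$partition, n_boot = 99, seed = 3)
  expect_identical(ds$p_value, ds2$p_value)

  # n_boot = 1 under the (1 + k)/(n + 1) convention
  ds1 <- pairwise_fst(sim$genotypes, sim$partition, n_boot = 1, seed = 3)
  expect_true(ds1$p_value[1, 2] %in% c(0.5, 1))
})

test_that("F_ST scan flags an engineered fixed difference", {
  sim <- balding_nichols(999, fst = c(0, 0), n_samples = c(80, 80),
                         seed = 16)
  gm <- sim$genotypes
  d <- gm$dosages
  d[, 500] <- rep(c(0L, 2L), each = 80)  # fixed difference
  gm <- genotype_matrix(d, gm$markers, gm$sample_ids)
  sc <- fst_scan(gm, sim$partition, "pop1", "pop2")
  expect_identical(sc$outliers$marker, gm$markers$id[500])
  expect_identical(sc$outliers$chromosome, gm$markers$chromosome[500])

  # symmetric in the two populations
  sc2 <- fst_scan(gm, sim$partition, "pop2", "pop1")
  expect_equal(sc$scan$theta, sc2$scan$theta)
  expect_equal(sc$threshold, sc2$threshold)

  # all markers identical theta -> sd 0, strict threshold, no outliers
  gm0 <- toy_gm(rbind(matrix(0L, 4, 5), matrix(2L, 4, 5)))
  sc0 <- fst_scan(gm0, two_pop_partition(gm0, 4), "A", "B")
  expect_identical(nrow(sc0$outliers), 0L)
})

test_that("theta recovers the generating F on Balding-Nichols data", {
  sim <- balding_nichols(5000, fst = c(0.05, 0.05),
                         n_samples = c(25, 25), seed = 17)
  fs <- wc_fstatistics(sim$genotypes, sim$partition)
  expect_equal(fs$theta, 0.05, tolerance = 0.2)  # ~3 MC SEs at L = 5000
  expect_true(fs$theta >= -0.01 && fs$theta <= 1)
  expect_true(fs$f >= -1 && fs$f <= 1)
})
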