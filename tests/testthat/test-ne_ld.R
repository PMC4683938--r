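test_that("composite r2 matches hand covariance arithmetic", {
  # 4 samples, both loci (0,0,2,2): cov = 4/3, Delta = 2/3, p = q = 0.5;
  # plain denominator 0.25 * 0.25, Weir denominator adds D_A = 0.25
  x <- c(0L, 0L, 2L, 2L)
  expect_equal(composite_r2(x, x, denominator = "plain"),
               (2 / 3)^2 / (0.25 * 0.25), tolerance = 1e-12)
  r2 <- composite_r2(x, x)
  expect_equal(r2, (2 / 3)^2 / (0.5 * 0.5), tolerance = 1e-12)
  expect_gt(r2, 1)  # retained, not clipped

  # locus paired with itself under HWE-balanced dosages (D_A = 0 there,
  # so both denominators coincide)
  y <- c(0L, 1L, 1L, 2L)
  expect_equal(composite_r2(y, y),
               (stats::var(y) / 2)^2 / (0.25 * 0.25), tolerance = 1e-12)
  expect_equal(composite_r2(y, y), composite_r2(y, y, "plain"))

  # symmetry and allele-relabel invariance
  z <- c(1L, 0L, 2L, 1L)
  expect_equal(composite_r2(y, z), composite_r2(z, y))
  expect_equal(composite_r2(y, z), composite_r2(2L - y, z),
               tolerance = 1e-12)

  # monomorphic on shared samples -> excluded, not zero
  expect_true(is.na(composite_r2(c(0L, 0L, 0L, 0L), y)))
  expect_true(is.na(composite_r2(c(0L, NA, NA, NA), y)))

  # independent loci, large n: r2 on the 1/n scale
  set.seed(5)
  r2s <- replicate(200, composite_r2(rbinom(400, 2, 0.5),
                                     rbinom(400, 2, 0.5)))
  expect_lt(mean(r2s), 3 / 400)
  expect_gt(mean(r2s), 1 / 3 / 400)
})

test_that("chromosome mean r2 equals the brute-force pair loop", {
  sim <- balding_nichols(10, fst = 0.02, n_samples = 12, seed = 19,
                         n_chromosomes = 1, missing_rate = 0.15)
  gm <- sim$genotypes
  res <- mean_r2_chromosome(gm, "1", maf_min = 0)
  d <- gm$dosages
  nn <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nn)
  elig <- which(nn >= 2 & pmin(p, 1 - p) >= 0)
  vals <- c(); ns <- c()
  for (i in seq_along(elig)[-length(elig)])
    for (j in seq(i + 1, length(elig))) {
      r2 <- composite_r2(d[, elig[i]], d[, elig[j]])
      if (!is.na(r2)) {
        vals <- c(vals, r2)
        ns <- c(ns, sum(!is.na(d[, elig[i]]) & !is.na(d[, elig[j]])))
      }
    }
  expect_equal(res$mean_r2, mean(vals), tolerance = 1e-12)
  expect_identical(res$n_pairs, length(vals))
  expect_equal(res$S_harmonic, 1 / mean(1 / ns), tolerance = 1e-12)

  # 2 loci -> one pair; all below the MAF cut-off -> undefined
  expect_null(mean_r2_chromosome(gm, "1", maf_min = 0.51))
  gm2 <- subset(gm, markers = gm$markers$id[1:2])
  expect_identical(mean_r2_chromosome(gm2, "1", maf_min = 0)$n_pairs, 1L)
})

test_that("Waples bias correction inverts its own expectation", {
  # r2_drift = 1/300 on the S >= 30 branch
  s <- 50
  expect_equal(ne_from_r2(1 / 300 + 1 / s + 3.19 / s^2, s), 97.8853,
               tolerance = 1e-4)

  # exactly the sampling expectation -> no drift signal
  expect_identical(ne_from_r2(1 / s + 3.19 / s^2, s), Inf)

  # algebraic inversion: E_drift(Ne) = 1/(3 Ne) - 0.69/Ne^2
  for (ne in c(10, 50, 97, 500)) {
    r2 <- (1 / (3 * ne) - 0.69 / ne^2) + 1 / s + 3.19 / s^2
    expect_equal(ne_from_r2(r2, s), ne, tolerance = 1e-6)
  }
  # S < 30 branch inversion: E_drift(Ne) = 0.308/(2 Ne) ... via quadratic
  s2 <- 20
  for (ne in c(10, 50, 200)) {
    r2d <- (0.308 - 0.52 / ne) / ne  # exact inverse of the branch
    expect_equal(ne_from_r2(r2d + 0.0018 + 0.907 / s2 + 4.44 / s2^2, s2),
                 ne, tolerance = 1e-6)
  }

  # monotone: more LD -> smaller Ne
  # stay inside the real-root region of the quadratic
  r2s <- seq(0.025, 0.06, by = 0.0025)
  nes <- vapply(r2s, ne_from_r2, numeric(1), S = 50)
  expect_true(all(diff(nes) < 0))
  expect_error(ne_from_r2(Inf, 50), "non-finite")
})

test_that("genome Ne averages per-chromosome estimates", {
  wf <- wright_fisher_forward(N = 50, S = 50, L = 29 * 30, n_chrom = 29,
                              generations = 20, seed = 23)
  est <- ne_genome(wf$genotypes)
  expect_gt(est$ne, 25)
  expect_lt(est$ne, 100)
  expect_identical(nrow(est$per_chromosome) - sum(!is.finite(
    est$per_chromosome$ne)), est$n_chromosomes_used)
  expect_identical(est$mating, "random")

  # two chromosomes carrying identical data -> sd = 0
  gm <- wf$genotypes
  sel <- gm$markers$chromosome == "1"
  d <- cbind(gm$dosages[, sel], gm$dosages[, sel])
  mk <- rbind(gm$markers[sel, ], gm$markers[sel, ])
  mk$id <- paste0("m", seq_len(nrow(mk)))
  mk$chromosome <- rep(c("1", "2"), each = sum(sel))
  dup <- genotype_matrix(d, mk, gm$sample_ids)
  est2 <- ne_genome(dup)
  expect_equal(est2$sd, 0)

  # partition routing: population subset must be honoured
  sim <- korean_like_scenario(seed = 33, n_markers = 580,
                              missing_rate = 0)
  est_m <- ne_genome(sim$genotypes, sim$partition, "island1")
  expect_s3_class(est_m, "ne_estimate")
})

test_that("heterozygosity decay follows the geometric law", {
  fc <- project_heterozygosity(0.5, 25, 0)
  expect_identical(nrow(fc$trajectory), 1L)
  expect_equal(fc$trajectory$H, 0.5)

  # halving times at the study's island Ne values
  expect_identical(project_heterozygosity(0.306, 7, 50)$halving_time, 10)
  expect_identical(project_heterozygosity(0.3, 11, 50)$halving_time, 15)

  fc <- project_heterozygosity(0.306, 7, 5)
  expect_equal(fc$trajectory$H[2], 0.306 * 13 / 14, tolerance = 1e-12)
  expect_true(all(diff(fc$trajectory$H) < 0))

  expect_identical(project_heterozygosity(0.4, Inf, 10)$halving_time, Inf)
  expect_error(project_heterozygosity(0.4, 0.5, 10), "exceed")
})
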