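test_that("PED parsing follows the minor-allele dosage convention", {
  ped <- c("f1 s1 0 0 0 -9 A G A A",
           "f2 s2 0 0 0 -9 G G 0 0",
           "f3 s3 0 0 0 -9 A A A C")
  map <- c("1 m1 0 100", "1 m2 0 200")
  pd <- tempfile(); mp <- tempfile()
  writeLines(ped, pd); writeLines(map, mp)
  gm <- read_plink_text(pd, mp)

  # m1: alleles A (3 copies) / G (3 copies) tie -> count G (lexico larger)
  expect_identical(gm$markers$allele_b[1], "G")
  expect_identical(unname(gm$dosages[, 1]), c(1L, 2L, 0L))
  # m2: C is minor; "0 0" is missing
  expect_identical(gm$markers$allele_b[2], "C")
  expect_identical(unname(gm$dosages[, 2]), c(0L, NA, 1L))
  expect_identical(gm$sample_ids, c("s1", "s2", "s3"))

  # re-reading the same file reproduces the same allele_b choice
  gm2 <- read_plink_text(pd, mp)
  expect_identical(gm$dosages, gm2$dosages)
  expect_identical(gm$markers$allele_b, gm2$markers$allele_b)
})

test_that("malformed PED input is a hard error naming the problem", {
  mp <- tempfile(); writeLines(c("1 m1 0 100"), mp)
  ragged <- tempfile()
  writeLines(c("f s1 0 0 0 -9 A A", "f s2 0 0 0 -9 A"), ragged)
  expect_error(read_plink_text(ragged, mp), "line 2")

  triallelic <- tempfile()
  writeLines(c("f s1 0 0 0 -9 A C", "f s2 0 0 0 -9 A G"), triallelic)
  expect_error(read_plink_text(triallelic, mp), ">2 alleles")

  dup <- tempfile()
  writeLines(c("f s1 0 0 0 -9 A C", "f s1 0 0 0 -9 A A"), dup)
  expect_error(read_plink_text(dup, mp), "duplicate sample id")

  expect_error(read_plink_text(tempfile(), mp), "not found")
})

test_that("write -> read round-trips dosages, marker and sample order", {
  pd <- tempfile(); mp <- tempfile()

  # hand-built 2x2 toy, canonical coding
  gm <- toy_gm(matrix(c(1L, 0L, NA, 2L), 2, 2))
  gm <- canonicalize_alleles(gm)
  write_plink_text(gm, pd, mp)
  back <- read_plink_text(pd, mp)
  expect_identical(back$dosages, gm$dosages)
  expect_identical(back$markers$id, gm$markers$id)
  expect_identical(back$sample_ids, gm$sample_ids)

  # property: random simulated matrices (generators emit canonical coding)
  for (seed in 1:5) {
    sim <- balding_nichols(60, fst = c(0.05, 0.1), n_samples = c(8, 6),
                           seed = seed, missing_rate = 0.1)
    write_plink_text(sim$genotypes, pd, mp)
    back <- read_plink_text(pd, mp)
    expect_identical(back$dosages, sim$genotypes$dosages)
    expect_identical(back$markers$id, sim$genotypes$markers$id)
    expect_identical(back$sample_ids, sim$genotypes$sample_ids)
  }

  # canonicalization is idempotent and makes arbitrary matrices round-trip
  gm <- random_gm(10, 40, seed = 42)
  cg <- canonicalize_alleles(gm)
  expect_identical(canonicalize_alleles(cg)$dosages, cg$dosages)
  write_plink_text(cg, pd, mp)
  expect_identical(read_plink_text(pd, mp)$dosages, cg$dosages)

  # missing dosage is written as "0 0"
  gm <- toy_gm(matrix(c(NA, 1L), 2, 1))
  write_plink_text(gm, pd, mp)
  expect_match(readLines(pd)[1], " 0 0$")

  # empty matrix (0 samples) -> valid empty PED, MAP still lists markers
  gm0 <- genotype_matrix(matrix(integer(0), 0, 2), toy_markers(2),
                         character(0))
  write_plink_text(gm0, pd, mp)
  expect_length(readLines(pd), 0)
  expect_length(readLines(mp), 2)
})

test_that("subset preserves order, composes, and rejects unknown ids", {
  gm <- random_gm(12, 30, seed = 3)

  expect_identical(subset(gm, samples = gm$sample_ids,
                          markers = gm$markers$id)$dosages, gm$dosages)

  sub <- subset(gm, samples = c("s2", "s5", "s9"))
  expect_identical(sub$sample_ids, c("s2", "s5", "s9"))

  # subset-then-subset equals the combined subset
  a <- subset(subset(gm, samples = paste0("s", 1:8)),
              markers = paste0("m", c(3, 7, 11)))
  b <- subset(gm, samples = paste0("s", 1:8),
              markers = paste0("m", c(3, 7, 11)))
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$markers, b$markers)

  expect_error(subset(gm, samples = "nope"), "nope")
  expect_error(subset(gm, markers = "m999"), "m999")
})

test_that("3-population fixture subsets to partition-sized populations", {
  sim <- balding_nichols(100, fst = c(0.02, 0.1, 0.1),
                         n_samples = c(10, 6, 8), seed = 2)
  part <- sim$partition
  ids <- names(part)[part == "pop2"]
  expect_identical(nrow(subset(sim$genotypes, samples = ids)$dosages), 6L)
})

test_that("dosage TSV round-trips", {
  gm <- random_gm(6, 15, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_dosage_tsv(gm, path)
  back <- read_dosage_tsv(path, markers = gm$markers)
  expect_identical(back$dosages, gm$dosages)
})

test_that("genotype_matrix validates its invariants", {
  expect_error(toy_gm(matrix(3L, 2, 2)), "0, 1, 2 or NA")
  expect_error(genotype_matrix(matrix(0L, 2, 2), toy_markers(2),
                               c("s1", "s1")), "duplicate sample")
  mk <- toy_markers(2); mk$id <- c("m", "m")
  expect_error(genotype_matrix(matrix(0L, 2, 2), mk, c("s1", "s2")),
               "duplicate marker")
  mk <- toy_markers(2); mk$quality <- c(0.5, NA)
  expect_error(genotype_matrix(matrix(0L, 2, 2), mk, c("s1", "s2")),
               "quality")
})
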