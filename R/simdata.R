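# marker metadata for L markers spread over n_chrom chromosomes in
# contiguous blocks, 1-based positions at a fixed spacing
sim_markers <- function(l, n_chrom, spacing = 100000L) {
  chrom <- rep(seq_len(n_chrom), length.out = l)
  chrom <- sort(chrom)
  pos <- unlist(lapply(table(chrom), function(k) seq_len(k) * spacing),
                use.names = FALSE)
  data.frame(id = sprintf("snp%06d", seq_len(l)),
             chromosome = as.character(chrom),
             position = as.integer(pos),
             allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
}

sim_sample_ids <- function(pop_names, n_samples)
  unlist(lapply(seq_along(pop_names), function(k)
    sprintf("%s_%03d", pop_names[k], seq_len(n_samples[k]))))

# apply uniform missingness and return canonical-coded matrix + partition
finish_dataset <- function(dos, markers, pop_names, n_samples,
                           missing_rate, rng) {
  ids <- sim_sample_ids(pop_names, n_samples)
  if (missing_rate > 0) {
    drop <- rng$runif(length(dos)) < missing_rate
    dos[drop] <- NA_integer_
  }
  gm <- canonicalize_alleles(genotype_matrix(dos, markers, ids))
  partition <- stats::setNames(rep(pop_names, n_samples), ids)
  list(genotypes = gm, partition = population_partition(partition, gm))
}

#' Simulate diverging populations under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `[ancestral[1], ancestral[2]]`; each population's frequency is a Beta
#' draw with mean p and variance `F p (1 - p)` (`F = 0` reproduces the
#' ancestral frequency exactly); genotypes are Binomial(2, p_k). The
#' generating divergences are the expected Weir-Cockerham F_ST, giving
#' closed-form ground truth for estimator-recovery tests.
#'
#' @param n_markers total marker count.
#' @param fst per-population divergence values in `[0, 1)` (length = number
#'   of populations).
#' @param n_samples per-population diploid sample sizes.
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param n_chromosomes chromosomes the markers are spread over
#'   (default 29, autosome count of cattle).
#' @param pop_names population labels.
#' @param ancestral range of the ancestral frequency distribution.
#' @param missing_rate probability that any genotype call is missing.
#' @return list with `genotypes` ([genotype_matrix()], canonical allele
#'   coding), `partition`, and `truth` (generating parameters, expected
#'   pairwise F_ST, expected heterozygosity, seed).
#' @export
balding_nichols <- function(n_markers, fst, n_samples, seed,
                            n_chromosomes = 29,
                            pop_names = paste0("pop", seq_along(fst)),
                            ancestral = c(0.05, 0.95),
                            missing_rate = 0) {
  stopifnot(length(fst) == length(n_samples), all(fst >= 0), all(fst < 1),
            missing_rate >= 0, missing_rate < 1)
  rng <- new_rng(seed)
  k <- length(fst)
  p_anc <- rng$runif(n_markers, ancestral[1L], ancestral[2L])
  dos <- matrix(NA_integer_, sum(n_samples), n_markers)
  row0 <- 0L
  pop_freqs <- matrix(NA_real_, k, n_markers)
  for (g in seq_len(k)) {
    f <- fst[g]
    pk <- if (f == 0) p_anc else
      rng$rbeta(n_markers, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    pop_freqs[g, ] <- pk
    dos[row0 + seq_len(n_samples[g]), ] <-
      matrix(rng$rbinom(n_samples[g] * n_markers, 2L,
                        rep(pk, each = n_samples[g])),
             n_samples[g], n_markers)
    row0 <- row0 + n_samples[g]
  }
  markers <- sim_markers(n_markers, n_chromosomes)
  out <- finish_dataset(dos, markers, pop_names, n_samples,
                        missing_rate, rng)
  pair_fst <- outer(fst, fst, function(a, b) (a + b) / 2)
  dimnames(pair_fst) <- list(pop_names, pop_names)
  diag(pair_fst) <- 0
  out$truth <- list(model = "balding_nichols", fst = fst,
                    n_samples = n_samples,
                    ancestral_freq = p_anc, pop_freqs = pop_freqs,
                    expected_pairwise_fst = pair_fst,
                    expected_h_exp = mean(2 * p_anc * (1 - p_anc)),
                    ancestral_freq_range = ancestral,
                    missing_rate = missing_rate, seed = seed)
  out
}

# one generation of diploid random mating with distinct parents per
# offspring; h1/h2 are N x L 0/1 haplotype matrices, c the recombination
# fraction between adjacent within-chromosome markers
wf_generation <- function(h1, h2, chrom, c_rec, rng) {
  n <- nrow(h1); l <- ncol(h1)
  gamete <- function(parents) {
    if (c_rec >= 0.5) {
      pick <- matrix(rng$runif(n * l) < 0.5, n, l)
    } else {
      # Markov switch process along each chromosome
      sw <- matrix(rng$runif(n * l) < c_rec, n, l)
      starts <- match(unique(chrom), chrom)
      sw[, starts] <- matrix(rng$runif(n * length(starts)) < 0.5,
                             n, length(starts))
      pick <- t(apply(sw, 1L, cumsum)) %% 2L == 1L
    }
    a <- h1[parents, , drop = FALSE]
    b <- h2[parents, , drop = FALSE]
    a[pick] <- b[pick]
    a
  }
  p1 <- rng$sample_int(n, n, replace = TRUE)
  # second parent distinct from the first
  p2 <- rng$sample_int(n, n, replace = TRUE)
  clash <- which(p2 == p1)
  while (length(clash)) {
    p2[clash] <- rng$sample_int(n, length(clash), replace = TRUE)
    clash <- clash[p2[clash] == p1[clash]]
  }
  list(h1 = gamete(p1), h2 = gamete(p2))
}

#' Forward Wright-Fisher simulation of a diploid population
#'
#' Simulates `generations` of random mating (two distinct parents per
#' offspring) in a census-N diploid population, starting from linkage
#' equilibrium at uniform initial frequencies, then samples S individuals
#' without replacement. Drift generates both allele-frequency change and
#' the background LD that the composite-r2 Ne estimator measures.
#'
#' @param N census (= effective, under this mating scheme) population size.
#' @param S sample size (<= N).
#' @param L total marker count.
#' @param n_chrom number of unlinked chromosomes.
#' @param generations generations of drift (>= 1).
#' @param seed integer seed.
#' @param init_freq range of initial allele frequencies.
#' @param recomb recombination fraction between adjacent markers within a
#'   chromosome (default 0.5: unlinked markers; chromosomes are always
#'   independent).
#' @param missing_rate probability a genotype call is missing.
#' @return list with `genotypes`, `truth` (N, S, generations, expected
#'   heterozygosity retention `(1 - 1/(2N))^generations`, seed).
#' @export
wright_fisher_forward <- function(N, S, L, n_chrom = 29, generations = 20,
                                  seed = 1, init_freq = c(0.1, 0.9),
                                  recomb = 0.5, missing_rate = 0) {
  stopifnot(N >= 2, generations >= 1)
  if (S > N) stop("sample size S exceeds census N")
  rng <- new_rng(seed)
  markers <- sim_markers(L, n_chrom)
  chrom <- markers$chromosome
  p0 <- rng$runif(L, init_freq[1L], init_freq[2L])
  h1 <- matrix(rng$runif(N * L) < rep(p0, each = N), N, L)
  h2 <- matrix(rng$runif(N * L) < rep(p0, each = N), N, L)
  for (t in seq_len(generations)) {
    gen <- wf_generation(h1, h2, chrom, recomb, rng)
    h1 <- gen$h1; h2 <- gen$h2
  }
  take <- rng$sample_int(N, S, replace = FALSE)
  dos <- matrix(as.integer(h1[take, , drop = FALSE]) +
                  as.integer(h2[take, , drop = FALSE]), S, L)
  final_freq <- colMeans(dos) / 2   # sampled allele frequency, pre-recoding
  out <- finish_dataset(dos, markers, "pop1", S, missing_rate, rng)
  out$truth <- list(model = "wright_fisher", N = N, S = S, L = L,
                    generations = generations,
                    h_retention = (1 - 1 / (2 * N))^generations,
                    init_freq = init_freq, init_freqs = p0,
                    final_freq = final_freq, seed = seed)
  out
}

#' Island-model scenario shaped like the Korean cattle study
#'
#' One large "mainland" population (40 samples) and two small drifted
#' "island" populations (20 samples each), all descending from a common
#' ancestral allele-frequency pool and diverging by forward Wright-Fisher
#' drift. Island census sizes and drift times are chosen so the expected
#' island-island F_ST is about 0.035 and mainland-island about 0.015-0.02,
#' the regime of the mainland/island cattle varieties; the small island
#' census simultaneously produces the strong background LD (small Ne) and
#' elevated fixed-marker counts that the study reports.
#'
#' @param seed integer seed.
#' @param n_markers marker count (default 29000, full chip scale; lower
#'   for quick runs).
#' @param n_chromosomes chromosomes (default 29).
#' @param missing_rate sporadic missing-call rate (default 0.005).
#' @return list with `genotypes`, `partition`, `truth` (per-population
#'   census sizes, drift generations, expected divergences and pairwise
#'   F_ST, seed).
#' @export
korean_like_scenario <- function(seed, n_markers = 29000,
                                 n_chromosomes = 29, missing_rate = 0.005) {
  pops <- data.frame(
    name = c("mainland", "island1", "island2"),
    N = c(600L, 60L, 60L),
    S = c(40L, 20L, 20L),
    generations = c(4L, 4L, 4L),
    stringsAsFactors = FALSE)
  rng <- new_rng(seed)
  markers <- sim_markers(n_markers, n_chromosomes)
  chrom <- markers$chromosome
  p_anc <- rng$runif(n_markers, 0.05, 0.95)

  dos <- matrix(NA_integer_, sum(pops$S), n_markers)
  row0 <- 0L
  for (k in seq_len(nrow(pops))) {
    n <- pops$N[k]
    h1 <- matrix(rng$runif(n * n_markers) < rep(p_anc, each = n),
                 n, n_markers)
    h2 <- matrix(rng$runif(n * n_markers) < rep(p_anc, each = n),
                 n, n_markers)
    for (t in seq_len(pops$generations[k])) {
      gen <- wf_generation(h1, h2, chrom, 0.5, rng)
      h1 <- gen$h1; h2 <- gen$h2
    }
    take <- rng$sample_int(n, pops$S[k], replace = FALSE)
    dos[row0 + seq_len(pops$S[k]), ] <-
      as.integer(h1[take, , drop = FALSE]) +
      as.integer(h2[take, , drop = FALSE])
    row0 <- row0 + pops$S[k]
  }
  out <- finish_dataset(dos, markers, pops$name, pops$S,
                        missing_rate, rng)
  f_k <- 1 - (1 - 1 / (2 * pops$N))^pops$generations
  pair <- outer(f_k, f_k, function(a, b) (a + b) / 2)
  dimnames(pair) <- list(pops$name, pops$name)
  diag(pair) <- 0
  out$truth <- list(model = "island_wright_fisher",
                    populations = pops, divergence_f = f_k,
                    expected_pairwise_fst = pair,
                    expected_h0 = mean(2 * p_anc * (1 - p_anc)),
                    missing_rate = missing_rate, seed = seed)
  out
}

#' Write a simulated dataset to disk
#'
#' Emits PLINK PED/MAP, a two-column population TSV and a JSON truth
#' manifest next to them.
#'
#' @param sim a list from [balding_nichols()], [wright_fisher_forward()]
#'   or [korean_like_scenario()].
#' @param prefix output path prefix (writes `<prefix>.ped`, `.map`,
#'   `.pops.tsv`, `.truth.json`).
#' @export
write_simulated_dataset <- function(sim, prefix) {
  fam <- if (!is.null(sim$partition))
    as.character(sim$partition)[match(sim$genotypes$sample_ids,
                                      names(sim$partition))]
  else NULL
  write_plink_text(sim$genotypes, paste0(prefix, ".ped"),
                   paste0(prefix, ".map"), family = fam)
  if (!is.null(sim$partition))
    utils::write.table(
      data.frame(sample_id = names(sim$partition),
                 population = as.character(sim$partition)),
      paste0(prefix, ".pops.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  jsonlite::write_json(sim$truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}
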