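# choose(n, k) ratio C(num, g)/C(den, g), exact in double for small inputs,
# log-space above N = 500 to avoid overflow. C(x, g) = 0 when x < g.
choose_ratio <- function(num, den, g) {
  den <- rep_len(den, length(num))
  out <- numeric(length(num))
  pos <- num >= g
  if (any(pos)) {
    if (max(den) <= 500) {
      out[pos] <- choose(num[pos], g) / choose(den[pos], g)
    } else {
      out[pos] <- exp(lchoose(num[pos], g) - lchoose(den[pos], g))
    }
  }
  out
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (Hurlbert/Kalinowski rarefaction):
#' `A_R = sum_a [1 - C(N - N_a, g) / C(N, g)]` where `N_a` is the count of
#' allele a and `N` the total gene copies.
#'
#' @param allele_counts non-negative integer vector of per-allele gene-copy
#'   counts at the locus.
#' @param g standardized number of gene copies, `1 <= g <= N`.
#' @return Expected allele count (for biallelic data in `[1, 2]`).
#' @examples
#' rarefied_allele_richness(c(10, 10), 10)  # 2 - 2/choose(20, 10)
#' @export
rarefied_allele_richness <- function(allele_counts, g) {
  stopifnot(all(allele_counts >= 0), g >= 1)
  n <- sum(allele_counts)
  if (g > n) stop("g (", g, ") exceeds gene copies at locus (", n, ")")
  counts <- allele_counts[allele_counts > 0]
  sum(1 - choose_ratio(n - counts, n, g))
}

#' Rarefied private allelic richness at one locus
#'
#' With `Q(k, a) = 1 - C(N_k - N_ka, g)/C(N_k, g)` the probability that
#' allele a appears in a g-copy subsample from population k, the expected
#' number of alleles private to the focal population's subsample is
#' `pA_R = sum_a Q(focal, a) * prod_{k != focal} (1 - Q(k, a))`.
#'
#' @param counts_by_population list (one element per population) of
#'   per-allele gene-copy count vectors, all over the same allele order.
#' @param focal_pop index or name of the focal population.
#' @param g standardized gene-copy count; every population must have at
#'   least `g` copies at the locus.
#' @return Expected private allele count.
#' @export
rarefied_private_richness <- function(counts_by_population, focal_pop, g) {
  counts <- do.call(rbind, counts_by_population)
  if (is.character(focal_pop))
    focal_pop <- match(focal_pop, names(counts_by_population))
  totals <- rowSums(counts)
  if (any(totals < g))
    stop("population(s) with fewer than g = ", g, " gene copies")
  q <- matrix(0, nrow(counts), ncol(counts))
  for (k in seq_len(nrow(counts)))
    q[k, ] <- 1 - choose_ratio(totals[k] - counts[k, ], totals[k], g)
  others <- setdiff(seq_len(nrow(counts)), focal_pop)
  prod_absent <- apply(1 - q[others, , drop = FALSE], 2L, prod)
  sum(q[focal_pop, ] * prod_absent)
}

#' Rarefaction allelic-richness table
#'
#' Per-population allelic richness (A_R) and private allelic richness
#' (pA_R), rarefied to a common number of gene copies `g` so that unequal
#' sample sizes do not bias the comparison. `g` defaults to the largest
#' even value no greater than the minimum non-missing gene-copy count over
#' all populations and loci; loci where any population falls below `g` are
#' skipped for all populations (their count is reported).
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param g optional gene-copy count (>= 2).
#' @return data.frame of class `rarefaction_result`: population, g, `a_r`,
#'   `a_r_sd`, `pa_r`, `pa_r_sd`, `loci_used`; attribute `loci_skipped`.
#' @export
richness_table <- function(gm, partition, g = NULL) {
  ft <- allele_freq_table(gm, partition)
  copies <- 2 * ft$n                      # populations x loci gene copies
  count_b <- ft$n1 + 2 * ft$n2
  count_a <- copies - count_b
  if (is.null(g)) {
    g <- 2 * floor(min(copies) / 2)
  }
  if (g < 2) stop("g must be at least 2 (got ", g, ")")
  usable <- colSums(copies >= g) == nrow(copies)
  if (!any(usable)) stop("no locus has >= g gene copies in every population")
  k <- nrow(copies)
  single_pop <- k < 2
  rows <- lapply(seq_len(k), function(pop) {
    ar <- vapply(which(usable), function(l)
      rarefied_allele_richness(c(count_a[pop, l], count_b[pop, l]), g),
      numeric(1))
    pa <- if (single_pop) rep(NA_real_, sum(usable)) else
      vapply(which(usable), function(l) {
        cl <- lapply(seq_len(k), function(kk)
          c(count_a[kk, l], count_b[kk, l]))
        rarefied_private_richness(cl, pop, g)
      }, numeric(1))
    data.frame(population = ft$populations[pop], g = g,
               a_r = mean(ar), a_r_sd = stats::sd(ar),
               pa_r = mean(pa), pa_r_sd = stats::sd(pa),
               loci_used = sum(usable), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "loci_skipped") <- sum(!usable)
  class(out) <- c("rarefaction_result", "data.frame")
  out
}
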