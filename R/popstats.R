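#' Per-population allele frequencies and genotype counts
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition (see [population_partition()]).
#' @return list of class `allele_freq_table` with per-population matrices
#'   (populations x markers): `p` (frequency of `allele_b`), `n`
#'   (non-missing sample count), `n0`, `n1`, `n2` (genotype counts by
#'   dosage) and `h_obs` (observed heterozygote fraction).
#' @export
allele_freq_table <- function(gm, partition) {
  idx <- pop_indices(gm, partition)
  l <- ncol(gm$dosages)
  k <- length(idx)
  mk_mat <- function() matrix(NA_real_, k, l,
                              dimnames = list(names(idx), gm$markers$id))
  n <- mk_mat(); n0 <- mk_mat(); n1 <- mk_mat(); n2 <- mk_mat()
  for (g in seq_len(k)) {
    d <- gm$dosages[idx[[g]], , drop = FALSE]
    n0[g, ] <- colSums(d == 0L, na.rm = TRUE)
    n1[g, ] <- colSums(d == 1L, na.rm = TRUE)
    n2[g, ] <- colSums(d == 2L, na.rm = TRUE)
    n[g, ] <- n0[g, ] + n1[g, ] + n2[g, ]
  }
  p <- (n1 + 2 * n2) / (2 * n)
  h_obs <- n1 / n
  structure(list(p = p, n = n, n0 = n0, n1 = n1, n2 = n2, h_obs = h_obs,
                 populations = names(idx)),
            class = "allele_freq_table")
}

#' Per-population diversity metrics
#'
#' For each population: mean minor-allele frequency, observed and expected
#' heterozygosity (H_exp = 2p(1-p) per locus, or its small-sample unbiased
#' version `2n/(2n-1) * 2p(1-p)`), the count of fixed markers (p = 0 or 1),
#' the within-population inbreeding coefficient F_IS (ratio-of-sums
#' `1 - sum(H_obs)/sum(H_s)` with the Nei-Chesser unbiased gene diversity),
#' and a paired two-sided t-test across markers of H_obs - H_exp.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param unbiased use the `2n/(2n-1)` correction for the reported H_exp?
#' @return data.frame of class `diversity_table`, one row per population.
#' @export
diversity_metrics <- function(gm, partition, unbiased = FALSE) {
  ft <- allele_freq_table(gm, partition)
  out <- lapply(seq_along(ft$populations), function(g) {
    n <- ft$n[g, ]; p <- ft$p[g, ]; ho <- ft$h_obs[g, ]
    keep <- n > 0
    if (!any(keep)) stop("population ", ft$populations[g],
                         " has no genotyped markers")
    n <- n[keep]; p <- p[keep]; ho <- ho[keep]
    maf <- pmin(p, 1 - p)
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * 2 * n / (2 * n - 1)
    # Nei-Chesser unbiased within-population gene diversity for F_IS
    hs <- n / (n - 1) * (2 * p * (1 - p) - ho / (2 * n))
    ok <- n > 1 & is.finite(hs)
    fis <- if (sum(hs[ok]) > 0) 1 - sum(ho[ok]) / sum(hs[ok]) else NA_real_
    diff <- ho - he
    tt <- if (length(diff) > 1L && isTRUE(stats::sd(diff) > 0))
      stats::t.test(ho, he, paired = TRUE)
    else list(statistic = 0, p.value = 1)
    data.frame(population = ft$populations[g],
               n_samples = max(n),
               maf_mean = mean(maf), maf_sd = stats::sd(maf),
               h_obs = mean(ho), h_obs_sd = stats::sd(ho),
               h_exp = mean(he),
               t_het = unname(tt$statistic), p_het = tt$p.value,
               n_fixed = sum(p == 0 | p == 1),
               f_is = fis,
               n_markers = length(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("diversity_table", "data.frame")
  out
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for
# populations with unequal sample sizes; rows of freq-table matrices are
# populations, columns loci. Returns a list of per-locus component vectors.
wc_components <- function(ft, pops = NULL) {
  rows <- if (is.null(pops)) seq_along(ft$populations)
          else match(pops, ft$populations)
  if (anyNA(rows)) stop("unknown population(s): ",
                        paste(pops[is.na(rows)], collapse = ", "))
  n <- ft$n[rows, , drop = FALSE]
  p <- ft$p[rows, , drop = FALSE]
  h <- ft$h_obs[rows, , drop = FALSE]
  use <- n > 0
  r <- colSums(use)
  nbar <- colSums(n) / r
  p[!use] <- 0; h[!use] <- 0
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = nrow(p)))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(a + b + c_)
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham F-statistics
#'
#' Multi-locus ratio-of-components estimators over the per-locus variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals) of Weir & Cockerham (1984),
#' using the unequal-sample-size formulation: theta = sum(a)/sum(a+b+c) and
#' f = 1 - sum(c)/sum(b+c). Loci where all components vanish (monomorphic)
#' or are undefined are excluded from the sums; negative per-locus values
#' are retained.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param pops optional subset of population labels (default all).
#' @return list with `theta`, `f`, `per_locus_theta` (named vector, `NA`
#'   where undefined), and `n_loci_used`.
#' @export
wc_fstatistics <- function(gm, partition, pops = NULL) {
  ft <- allele_freq_table(gm, partition)
  if (is.null(pops)) pops <- ft$populations
  if (length(pops) < 2L) stop("theta needs at least two populations")
  comp <- wc_components(ft, pops)
  denom <- comp$a + comp$b + comp$c
  use <- is.finite(denom) & abs(denom) > 0
  if (!any(use)) stop("all loci monomorphic or undefined across the subset")
  theta <- sum(comp$a[use]) / sum(denom[use])
  bc <- comp$b[use] + comp$c[use]
  f <- 1 - sum(comp$c[use]) / sum(bc)
  per_locus <- ifelse(use, comp$a / denom, NA_real_)
  names(per_locus) <- gm$markers$id
  list(theta = theta, f = f, per_locus_theta = per_locus,
       n_loci_used = sum(use),
       components = list(a = comp$a, b = comp$b, c = comp$c))
}

#' Nei's standard genetic distance between two frequency vectors
#'
#' For biallelic loci with allele-b frequencies `x` and `y`:
#' `J_X = mean(x^2 + (1-x)^2)`, `J_Y` likewise,
#' `J_XY = mean(x y + (1-x)(1-y))`, identity `I = J_XY / sqrt(J_X J_Y)` and
#' `D = -ln I`. Loci with an undefined frequency in either population are
#' dropped.
#'
#' @param freqs_x,freqs_y numeric vectors of allele-b frequencies.
#' @return Nei's D (non-negative; `Inf` when I = 0).
#' @export
nei_distance <- function(freqs_x, freqs_y) {
  if (length(freqs_x) != length(freqs_y))
    stop("frequency vectors differ in length")
  ok <- is.finite(freqs_x) & is.finite(freqs_y)
  if (!any(ok)) stop("no loci with defined frequencies in both populations")
  x <- freqs_x[ok]; y <- freqs_y[ok]
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  jxy <- mean(x * y + (1 - x) * (1 - y))
  i <- jxy / sqrt(jx * jy)
  if (i <= 0) return(Inf)
  max(0, -log(i))
}

#' Pairwise F_ST and Nei's D with locus-bootstrap significance
#'
#' Point theta per population pair via [wc_fstatistics()]; significance by
#' resampling loci with replacement and recomputing theta, with the
#' one-sided p-value `(1 + #\{theta* <= 0\}) / (n_boot + 1)` for the test of
#' theta > 0.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param n_boot bootstrap replicates (paper-scale default 100).
#' @param seed integer seed for the locus bootstrap.
#' @return list of class `distance_set` with symmetric matrices `fst`,
#'   `nei_d`, `p_value` and the replicate count.
#' @export
pairwise_fst <- function(gm, partition, n_boot = 100, seed = 1) {
  stopifnot(n_boot >= 1)
  ft <- allele_freq_table(gm, partition)
  pops <- ft$populations
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  nei <- fst
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  rng <- new_rng(seed)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    comp <- wc_components(ft, pops[c(i, j)])
    denom <- comp$a + comp$b + comp$c
    use <- which(is.finite(denom) & abs(denom) > 0)
    if (length(use) == 0L)
      stop("no usable loci for pair ", pops[i], "/", pops[j])
    theta <- sum(comp$a[use]) / sum(denom[use])
    a <- comp$a[use]; d <- denom[use]
    nboot_le0 <- 0L
    for (b in seq_len(n_boot)) {
      idx <- rng$resample(length(use))
      tb <- sum(a[idx]) / sum(d[idx])
      if (is.finite(tb) && tb <= 0) nboot_le0 <- nboot_le0 + 1L
    }
    fst[i, j] <- fst[j, i] <- theta
    pv[i, j] <- pv[j, i] <- (1 + nboot_le0) / (n_boot + 1)
    nei[i, j] <- nei[j, i] <- nei_distance(ft$p[i, ], ft$p[j, ])
  }
  structure(list(fst = fst, nei_d = nei, p_value = pv,
                 n_boot = n_boot, populations = pops),
            class = "distance_set")
}

#' @export
print.distance_set <- function(x, ...) {
  cat("pairwise distances over", length(x$populations), "populations (",
      x$n_boot, "bootstrap replicates )\n")
  cat("F_ST above the diagonal, Nei's D below:\n")
  print(round(combined_distance_matrix(x), 4))
  invisible(x)
}

# Table-3 layout: F_ST upper triangle, Nei's D lower triangle
combined_distance_matrix <- function(ds) {
  m <- ds$nei_d
  m[upper.tri(m)] <- ds$fst[upper.tri(ds$fst)]
  diag(m) <- 0
  m
}

#' Write a distance set as a square TSV
#'
#' F_ST in the upper triangle, Nei's D in the lower.
#'
#' @param ds a `distance_set` from [pairwise_fst()].
#' @param path output path.
#' @export
write_distance_set <- function(ds, path) {
  utils::write.table(combined_distance_matrix(ds), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(NULL)
}

#' Marker-wise F_ST scan between two populations
#'
#' Per-marker Weir-Cockerham theta with the empirical significance
#' threshold mean + 3 sd over defined markers; outliers are markers
#' strictly above the threshold, reported with chromosome and position.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param pop_a,pop_b population labels.
#' @param n_sd threshold width (default 3).
#' @return list with `scan` (data.frame: marker, chromosome, position,
#'   theta), `threshold`, and `outliers` (subset of `scan`).
#' @export
fst_scan <- function(gm, partition, pop_a, pop_b, n_sd = 3) {
  ft <- allele_freq_table(gm, partition)
  comp <- wc_components(ft, c(pop_a, pop_b))
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(is.finite(denom) & abs(denom) > 0, comp$a / denom,
                  NA_real_)
  def <- which(!is.na(theta))
  if (length(def) < 2L) stop("fewer than 2 markers with defined theta")
  thr <- mean(theta[def]) + n_sd * stats::sd(theta[def])
  scan <- data.frame(marker = gm$markers$id,
                     chromosome = gm$markers$chromosome,
                     position = gm$markers$position,
                     theta = theta, stringsAsFactors = FALSE)
  list(scan = scan, threshold = thr,
       outliers = scan[!is.na(theta) & theta > thr, , drop = FALSE])
}

#' Write an F_ST scan as BED-like TSV
#'
#' @param scan result of [fst_scan()].
#' @param path output path.
#' @export
write_fst_scan <- function(scan, path) {
  tab <- scan$scan
  utils::write.table(
    data.frame(chrom = tab$chromosome, start = tab$position,
               end = tab$position, theta = tab$theta),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
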