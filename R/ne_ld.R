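#' Burrows composite linkage disequilibrium r-squared for one locus pair
#'
#' For unphased diploid genotypes the composite disequilibrium is
#' `Delta = cov(x, y) / 2` (sample covariance, n-1 denominator, over
#' samples non-missing at both loci). The default r-squared follows the
#' Burrows estimator as implemented in the LD-Ne literature, normalizing
#' by Weir's composite variances that include the within-locus
#' Hardy-Weinberg disequilibrium `D_A = P_AA - p^2`:
#' `r2 = Delta^2 / ((p(1-p) + D_A)(q(1-q) + D_B))`.
#' The published sample-size bias correction ([ne_from_r2()]) is
#' calibrated for exactly this estimator; the plain normalization
#' `p(1-p) q(1-q)` is available via `denominator = "plain"`. All
#' frequencies come from the shared (pairwise-complete) samples. Values
#' above 1 are possible and retained.
#'
#' @param x,y integer dosage vectors for the two loci (`NA` = missing).
#' @param denominator `"weir"` (default) or `"plain"`.
#' @return r-squared, or `NA` when fewer than 2 shared samples or either
#'   locus is monomorphic on the shared samples.
#' @export
composite_r2 <- function(x, y, denominator = c("weir", "plain")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  p <- mean(x) / 2
  q <- mean(y) / 2
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) return(NA_real_)
  delta <- stats::cov(x, y) / 2
  vx <- p * (1 - p)
  vy <- q * (1 - q)
  if (denominator == "weir") {
    vx <- vx + mean(x == 2L) - p^2
    vy <- vy + mean(y == 2L) - q^2
  }
  if (vx <= 0 || vy <= 0) return(NA_real_)
  delta^2 / (vx * vy)
}

# Vectorized within-chromosome pairwise composite r2 with per-pair
# pairwise-complete frequencies; returns upper-triangle vectors.
pairwise_composite_r2 <- function(d, denominator = "weir") {
  l <- ncol(d)
  m <- !is.na(d)
  x0 <- d
  x0[!m] <- 0
  storage.mode(x0) <- "double"
  mm <- matrix(as.double(m), nrow(d), l)
  hom <- matrix(as.double(d == 2L & m), nrow(d), l)
  n <- crossprod(mm)                       # shared sample counts
  sx <- crossprod(x0, mm)                  # [i,j] = sum x_i over shared(i,j)
  sh <- crossprod(hom, mm)                 # [i,j] = # {x_i == 2} over shared
  cross <- crossprod(x0)                   # [i,j] = sum x_i x_j over shared
  up <- upper.tri(n)
  nij <- n[up]
  mx <- sx[up] / nij                       # mean of locus i on shared
  my <- t(sx)[up] / nij                    # mean of locus j on shared
  covxy <- (cross[up] - nij * mx * my) / (nij - 1)
  p <- mx / 2; q <- my / 2
  vx <- p * (1 - p)
  vy <- q * (1 - q)
  if (denominator == "weir") {
    vx <- vx + sh[up] / nij - p^2
    vy <- vy + t(sh)[up] / nij - q^2
  }
  denom <- vx * vy
  r2 <- (covxy / 2)^2 / denom
  bad <- nij < 2 | p <= 0 | p >= 1 | q <= 0 | q >= 1 | denom <= 0
  r2[bad] <- NA_real_
  list(r2 = r2, n = nij)
}

#' Mean composite r-squared over one chromosome
#'
#' Unweighted mean of [composite_r2()] across all within-chromosome locus
#' pairs passing the allele-frequency cut-off, with the harmonic-mean
#' shared sample size used downstream for the sampling-bias correction.
#'
#' @param gm a [genotype_matrix()] already restricted to one population.
#' @param chromosome chromosome label.
#' @param maf_min minimum minor-allele frequency for a locus to enter
#'   (default 0.05).
#' @param denominator r2 normalization, see [composite_r2()].
#' @return list with `mean_r2`, `n_pairs`, `S_harmonic`; `NULL` when the
#'   chromosome has no eligible pairs.
#' @export
mean_r2_chromosome <- function(gm, chromosome, maf_min = 0.05,
                               denominator = c("weir", "plain")) {
  denominator <- match.arg(denominator)
  sel <- which(gm$markers$chromosome == as.character(chromosome))
  if (length(sel) < 2L) return(NULL)
  d <- gm$dosages[, sel, drop = FALSE]
  nn <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nn)
  maf <- pmin(p, 1 - p)
  keep <- nn >= 2 & !is.na(maf) & maf >= maf_min
  if (sum(keep) < 2L) return(NULL)
  pr <- pairwise_composite_r2(d[, keep, drop = FALSE], denominator)
  ok <- !is.na(pr$r2)
  if (!any(ok)) return(NULL)
  list(mean_r2 = mean(pr$r2[ok]),
       n_pairs = sum(ok),
       S_harmonic = 1 / mean(1 / pr$n[ok]))
}

#' Effective population size from mean adjusted r-squared
#'
#' Waples (2006) bias-corrected LD estimator for random mating. The
#' sampling expectation is subtracted from the observed mean r2 and the
#' drift signal inverted through the corresponding quadratic:
#' for S >= 30, `r2' = r2 - (1/S + 3.19/S^2)` and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`;
#' for S < 30, `r2' = r2 - (0.0018 + 0.907/S + 4.44/S^2)` and
#' `Ne = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2')`.
#'
#' @param mean_r2 mean composite r-squared.
#' @param S (harmonic mean) sample size.
#' @return Ne estimate; `Inf` when the drift signal is non-positive or the
#'   discriminant negative (no evidence of finite Ne).
#' @export
ne_from_r2 <- function(mean_r2, S) {
  if (!is.finite(mean_r2) || !is.finite(S)) stop("non-finite input")
  stopifnot(mean_r2 > 0, S >= 2)
  if (S >= 30) {
    r2d <- mean_r2 - (1 / S + 3.19 / S^2)
    if (r2d <= 0) return(Inf)
    disc <- 1 / 9 - 2.76 * r2d
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2d)
  } else {
    r2d <- mean_r2 - (0.0018 + 0.907 / S + 4.44 / S^2)
    if (r2d <= 0) return(Inf)
    disc <- 0.308^2 - 2.08 * r2d
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2d)
  }
}

#' Genome-wide LD effective population size
#'
#' Ne is estimated per chromosome from the mean composite r-squared
#' ([mean_r2_chromosome()], [ne_from_r2()]) and averaged across
#' chromosomes; the genome estimate is the arithmetic mean (or harmonic,
#' on request) with the across-chromosome standard deviation as its
#' dispersion, infinite chromosome estimates counted separately.
#'
#' @param gm a [genotype_matrix()].
#' @param partition optional population partition.
#' @param population population label to analyse (required with a
#'   partition; otherwise all samples are used).
#' @param maf_min allele-frequency cut-off (default 0.05).
#' @param mean_type `"arithmetic"` (default) or `"harmonic"` genome average.
#' @return list of class `ne_estimate`: `ne` (genome mean), `sd`,
#'   `per_chromosome` data.frame (chromosome, mean_r2, n_pairs,
#'   S_harmonic, ne), `n_infinite`, `mating` = "random".
#' @export
ne_genome <- function(gm, partition = NULL, population = NULL,
                      maf_min = 0.05, mean_type = c("arithmetic", "harmonic")) {
  mean_type <- match.arg(mean_type)
  if (!is.null(partition)) {
    if (is.null(population)) stop("population required with a partition")
    part <- population_partition(partition, gm)
    ids <- names(part)[part == population]
    if (length(ids) == 0L) stop("population not found: ", population)
    gm <- subset(gm, samples = ids)
  }
  chroms <- unique(gm$markers$chromosome)
  rows <- lapply(chroms, function(ch) {
    res <- mean_r2_chromosome(gm, ch, maf_min)
    if (is.null(res)) return(NULL)
    data.frame(chromosome = ch, mean_r2 = res$mean_r2,
               n_pairs = res$n_pairs, S_harmonic = res$S_harmonic,
               ne = ne_from_r2(res$mean_r2, res$S_harmonic),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no chromosome with a defined Ne estimate")
  finite <- tab$ne[is.finite(tab$ne)]
  if (length(finite) == 0L)
    stop("all chromosome estimates infinite (no drift signal)")
  ne <- if (mean_type == "arithmetic") mean(finite)
        else 1 / mean(1 / finite)
  structure(list(ne = ne,
                 sd = if (length(finite) > 1L) stats::sd(finite) else 0,
                 per_chromosome = tab,
                 n_infinite = sum(!is.finite(tab$ne)),
                 n_chromosomes_used = length(finite),
                 mating = "random"),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne = %.1f +/- %.1f over %d chromosomes (%d infinite), random mating\n",
              x$ne, x$sd, x$n_chromosomes_used, x$n_infinite))
  invisible(x)
}

#' Project heterozygosity decay
#'
#' Expected heterozygosity under pure drift decays geometrically,
#' `H_t = H_0 (1 - 1/(2 Ne))^t`. The halving time is the smallest integer
#' t with `H_t <= H_0 / 2`.
#'
#' @param H0 initial heterozygosity in `[0, 1]`.
#' @param Ne effective population size (> 0.5; may be `Inf`).
#' @param t_max forecast horizon in generations (default 50).
#' @return list of class `decay_forecast`: `trajectory` data.frame
#'   (generation, H), `halving_time`, `H0`, `Ne`.
#' @export
project_heterozygosity <- function(H0, Ne, t_max = 50) {
  stopifnot(H0 >= 0, H0 <= 1, t_max >= 0)
  if (!is.infinite(Ne) && Ne <= 0.5) stop("Ne must exceed 0.5")
  ratio <- if (is.infinite(Ne)) 1 else 1 - 1 / (2 * Ne)
  t <- 0:t_max
  traj <- data.frame(generation = t, H = H0 * ratio^t)
  halving <- if (ratio >= 1) Inf else {
    th <- log(0.5) / log(ratio)
    t0 <- ceiling(th - 1e-9)
    # guard the integer boundary explicitly
    while (ratio^t0 > 0.5 + 1e-15) t0 <- t0 + 1L
    t0
  }
  structure(list(trajectory = traj, halving_time = halving,
                 H0 = H0, Ne = Ne),
            class = "decay_forecast")
}

#' @export
print.decay_forecast <- function(x, ...) {
  cat(sprintf("heterozygosity decay: H0 = %.3f, Ne = %.1f, halving in %s generations\n",
              x$H0, x$Ne, format(x$halving_time)))
  invisible(x)
}
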