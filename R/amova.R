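#' One-level analysis of molecular variance
#'
#' Partitions squared Euclidean distances between (mean-imputed) dosage
#' vectors into among- and within-population components:
#' `SS_total = sum_{i<j} d2_ij / N`, `SS_within = sum_g sum_{i<j in g}
#' d2_ij / n_g`, `SS_among = SS_total - SS_within`, with
#' `sigma2_w = MS_within` and `sigma2_a = (MS_among - MS_within) / n0`,
#' `n0 = (N - sum n_g^2 / N) / (k - 1)`. Significance comes from permuting
#' sample labels across populations: `p = (1 + #{sigma2_a* >= sigma2_a}) /
#' (n_perm + 1)`.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition (k >= 2 populations, each with
#'   >= 2 samples).
#' @param n_perm number of label permutations (paper-scale default 1000).
#' @param seed integer seed for the permutations.
#' @return list of class `amova_result` with the sums of squares, degrees
#'   of freedom, mean squares, variance components (raw and truncated),
#'   percentages, `F_value = MS_among / MS_within`, permutation p-value.
#' @export
amova_one_level <- function(gm, partition, n_perm = 1000, seed = 1) {
  part <- population_partition(partition, gm)
  idx <- pop_indices(gm, part)
  k <- length(idx)
  if (k < 2L) stop("AMOVA needs at least two populations")
  sizes <- lengths(idx)
  if (any(sizes < 2L)) stop("every population needs >= 2 samples")
  n_tot <- sum(sizes)

  d <- gm$dosages
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss)) d[miss] <- mu[miss[, 2L]]
  ord <- unlist(idx, use.names = FALSE)
  d2 <- as.matrix(stats::dist(d[ord, , drop = FALSE]))^2
  labels <- rep.int(seq_len(k), sizes)

  ss_for <- function(lab) {
    ss_w <- 0
    for (g in seq_len(k)) {
      rows <- which(lab == g)
      ss_w <- ss_w + sum(d2[rows, rows]) / (2 * length(rows))
    }
    ss_w
  }
  ss_total <- sum(d2) / (2 * n_tot)
  ss_within <- ss_for(labels)
  ss_among <- ss_total - ss_within

  df_among <- k - 1L
  df_within <- n_tot - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (n_tot - sum(sizes^2) / n_tot) / df_among
  sigma2_w <- ms_within
  sigma2_a_raw <- (ms_among - ms_within) / n0
  sigma2_a <- max(0, sigma2_a_raw)
  pct_among <- 100 * sigma2_a / (sigma2_a + sigma2_w)

  rng <- new_rng(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    lab <- labels[rng$permute(n_tot)]
    ss_w <- ss_for(lab)
    s2a <- ((ss_total - ss_w) / df_among - ss_w / df_within) / n0
    if (s2a >= sigma2_a_raw) exceed <- exceed + 1L
  }
  structure(list(
    ss = c(among = ss_among, within = ss_within, total = ss_total),
    df = c(among = df_among, within = df_within, total = n_tot - 1L),
    ms = c(among = ms_among, within = ms_within),
    sigma2 = c(among = sigma2_a, within = sigma2_w),
    sigma2_among_raw = sigma2_a_raw,
    percent = c(among = pct_among, within = 100 - pct_among),
    F_value = ms_among / ms_within,
    p_value = (1 + exceed) / (n_perm + 1),
    n_permutations = n_perm,
    n0 = n0),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (one level):\n")
  print(as.data.frame(x))
  cat(sprintf("F-value = %.2f, permutation p = %.4g (%d permutations)\n",
              x$F_value, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
as.data.frame.amova_result <- function(x, ...) {
  data.frame(
    source = c("Between populations", "Within populations", "Total"),
    ss = unname(x$ss),
    df = unname(x$df),
    ms = c(unname(x$ms), NA),
    variance_pct = c(unname(x$percent), 100),
    stringsAsFactors = FALSE)
}

#' Write an AMOVA table as TSV
#'
#' @param x an `amova_result`.
#' @param path output path.
#' @export
write_amova <- function(x, path) {
  tab <- as.data.frame(x)
  tab$F_value <- c(x$F_value, NA, NA)
  tab$p_value <- c(x$p_value, NA, NA)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
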