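# shared fixtures and independent oracles, built in code at test time

toy_markers <- function(l, chrom = "1") {
  data.frame(id = paste0("m", seq_len(l)),
             chromosome = rep_len(chrom, l),
             position = seq_len(l) * 1000L,
             allele_a = "A", allele_b = "G",
             stringsAsFactors = FALSE)
}

toy_gm <- function(dosages, chrom = "1") {
  dosages <- as.matrix(dosages)
  genotype_matrix(dosages, toy_markers(ncol(dosages), chrom),
                  paste0("s", seq_len(nrow(dosages))))
}

random_gm <- function(n, l, seed, missing_rate = 0.05) {
  set.seed(seed)
  p <- runif(l, 0.05, 0.95)
  d <- matrix(rbinom(n * l, 2L, rep(p, each = n)), n, l)
  d[matrix(runif(n * l) < missing_rate, n, l)] <- NA_integer_
  toy_gm(d, chrom = as.character(rep_len(1:3, l)))
}

two_pop_partition <- function(gm, n1) {
  ids <- gm$sample_ids
  stats::setNames(rep(c("A", "B"), c(n1, length(ids) - n1)), ids)
}

# --- independent oracles ----------------------------------------------------

# exact-combinatorics HWE enumeration (choose(), no log-space shortcut)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    choose(n, h) * choose(n - h, hr) * 2^h / 1
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# literal scalar Weir & Cockerham (1984) components for one locus;
# counts: list per population of c(n0, n1, n2) genotype counts
wc_oracle_locus <- function(counts) {
  r <- length(counts)
  n <- vapply(counts, sum, numeric(1))
  p <- vapply(counts, function(k) (k[2] + 2 * k[3]) / (2 * sum(k)),
              numeric(1))
  h <- vapply(counts, function(k) k[2] / sum(k), numeric(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# two-loop VanRaden GRM
grm_oracle <- function(d, p) {
  n <- nrow(d)
  mu <- colMeans(d, na.rm = TRUE)   # mean allele count
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  g <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    g[i, j] <- sum((d[i, ] - 2 * p) * (d[j, ] - 2 * p)) / denom
  g
}

# literal AMOVA sums from an explicit pairwise squared-distance loop
amova_oracle <- function(d, labels) {
  n <- nrow(d)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d2[i, j] <- sum((d[i, ] - d[j, ])^2)
  groups <- unique(labels)
  k <- length(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in groups) {
    rows <- which(labels == g)
    for (i in rows) for (j in rows)
      if (i < j) ss_within <- ss_within + d2[i, j] / length(rows)
  }
  ss_among <- ss_total - ss_within
  sizes <- table(labels)
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (n - k)
  list(ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       sigma2_a = (ms_among - ms_within) / n0, sigma2_w = ms_within)
}

# expected subsample allelic richness by exhaustive enumeration of g-subsets
rarefaction_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2L, function(idx) length(unique(copies[idx]))))
}

# per-allele presence probability in a g-subset, by enumeration
presence_prob_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  vapply(seq_along(counts), function(a)
    mean(apply(subs, 2L, function(idx) a %in% copies[idx])), numeric(1))
}

# greedy Ward merge sequence from explicit ESS-increase evaluation
ward_oracle_merge_heights <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(clusters) - 1))
      for (j in seq(i + 1, length(clusters))) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        # Lance-Williams Ward height = 2 * ESS increase
        dd <- 2 * length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}
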