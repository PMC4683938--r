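#' VanRaden genomic relationship matrix (method 1)
#'
#' Missing dosages are replaced by the per-marker mean allele count,
#' dosages centered by twice the reference frequency (`Z = M - 2p`) and
#' `G = Z Z' / (2 sum p (1 - p))`. Monomorphic markers contribute to
#' neither numerator nor denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param freqs optional per-marker reference allele-b frequencies (named
#'   or in marker order); default computed from the analysed samples.
#' @return list of class `grm`: `G` (samples x samples), `n_markers`,
#'   `freqs`.
#' @export
build_grm <- function(gm, freqs = NULL) {
  d <- gm$dosages
  storage.mode(d) <- "double"
  nn <- colSums(!is.na(d))
  own_p <- colSums(d, na.rm = TRUE) / (2 * pmax(nn, 1L))
  p <- if (is.null(freqs)) own_p else as.numeric(freqs)
  if (length(p) != ncol(d)) stop("frequency vector length mismatch")
  poly <- nn > 0 & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  # mean imputation of missing allele counts (within the analysed samples)
  mu <- 2 * own_p[poly]
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss)) d[miss] <- mu[miss[, 2L]]
  z <- sweep(d, 2L, 2 * p, "-")
  g <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(g) <- list(gm$sample_ids, gm$sample_ids)
  structure(list(G = g, n_markers = sum(poly), freqs = p), class = "grm")
}

#' Per-population GRM summaries
#'
#' Builds the genomic relationship matrix within each population (its own
#' allele frequencies, mirroring per-breed reporting) and summarizes the
#' mean diagonal and mean upper-triangle off-diagonal.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param pooled_freqs use allele frequencies pooled over all samples
#'   instead of within-population frequencies?
#' @return data.frame: population, n, `g_diag`, `g_offdiag` (NA for
#'   populations of one).
#' @export
grm_summaries <- function(gm, partition, pooled_freqs = FALSE) {
  idx <- pop_indices(gm, partition)
  pool_p <- if (pooled_freqs) {
    d <- gm$dosages
    colSums(d, na.rm = TRUE) / (2 * pmax(colSums(!is.na(d)), 1L))
  } else NULL
  rows <- lapply(names(idx), function(pop) {
    sub <- subset(gm, samples = gm$sample_ids[idx[[pop]]])
    g <- build_grm(sub, freqs = if (pooled_freqs)
      pool_p else NULL)$G
    off <- if (nrow(g) > 1L) mean(g[upper.tri(g)]) else NA_real_
    data.frame(population = pop, n = nrow(g),
               g_diag = mean(diag(g)), g_offdiag = off,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag putatively related pairs from a GRM
#'
#' @param grm a `grm` from [build_grm()].
#' @param threshold off-diagonal relationship cut-off (default 0.25,
#'   roughly half-sib level).
#' @return data.frame of flagged pairs (sample_1, sample_2, relationship).
#' @export
relationship_check <- function(grm, threshold = 0.25) {
  g <- grm$G
  idx <- which(upper.tri(g) & g > threshold, arr.ind = TRUE)
  data.frame(sample_1 = rownames(g)[idx[, 1L]],
             sample_2 = colnames(g)[idx[, 2L]],
             relationship = g[idx], stringsAsFactors = FALSE)
}

#' Principal components from a genomic relationship matrix
#'
#' Eigendecomposition of G with components ordered by descending
#' eigenvalue; each component's sign is fixed so that its
#' largest-magnitude loading is positive. Explained-variance fractions are
#' eigenvalues over the sum of positive eigenvalues.
#'
#' @param grm a `grm` from [build_grm()].
#' @param n_components number of components (<= samples).
#' @return list with `coordinates` (samples x components, scaled by
#'   sqrt(eigenvalue)) and `explained` (variance fractions).
#' @export
pca_from_grm <- function(grm, n_components = 2) {
  g <- grm$G
  if (any(!is.finite(g))) stop("non-finite entries in G")
  stopifnot(n_components >= 1, n_components <= nrow(g))
  eig <- eigen(g, symmetric = TRUE)
  val <- pmax(eig$values, 0)
  vec <- eig$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- sweep(vec, 2L, sqrt(val[seq_len(n_components)]), "*")
  rownames(coords) <- rownames(g)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coordinates = coords,
       explained = val[seq_len(n_components)] / sum(val))
}

#' Write a GRM as TSV with a sample-id header
#'
#' @param grm a `grm`.
#' @param path output path.
#' @export
write_grm <- function(grm, path) {
  utils::write.table(grm$G, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(NULL)
}
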