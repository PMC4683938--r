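#' Population allele-frequency matrix
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @return populations x markers matrix of allele-b frequencies; markers
#'   with any population entirely missing are dropped (count in attribute
#'   `"dropped"`).
#' @export
frequency_matrix <- function(gm, partition) {
  ft <- allele_freq_table(gm, partition)
  if (any(rowSums(ft$n) == 0))
    stop("population with no genotyped data: ",
         paste(ft$populations[rowSums(ft$n) == 0], collapse = ", "))
  keep <- colSums(ft$n == 0) == 0
  out <- ft$p[, keep, drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Ward minimum-variance clustering of populations
#'
#' Agglomerative clustering on squared Euclidean distances between
#' frequency rows, merged by the Lance-Williams update for Ward's
#' criterion; ties are broken deterministically by the first minimal pair
#' in cluster-creation order. The result is ultrametric (heights
#' non-decreasing towards the root).
#'
#' @param freq_table populations x markers numeric matrix (rownames =
#'   population labels), e.g. from [frequency_matrix()].
#' @return list of class `population_tree`: `hclust` (base-R hclust
#'   structure), `phylo` (ape tree, branch lengths = height differences),
#'   `supports` (NULL until [bootstrap_support()]), `n_boot`.
#' @export
ward_tree <- function(freq_table) {
  x <- as.matrix(freq_table)
  if (any(!is.finite(x))) stop("non-finite frequencies")
  n <- nrow(x)
  if (n < 2L) stop("need at least two populations")
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("pop", seq_len(n))

  d <- as.matrix(stats::dist(x))^2          # squared Euclidean
  active <- seq_len(n)                      # current cluster columns in d
  id <- -seq_len(n)                         # hclust coding: negatives = leaves
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      dij <- d[active[i], active[j]]
      if (dij < bestd - 1e-15) { bestd <- dij; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    ci <- active[i]; cj <- active[j]
    pair <- sort(c(id[ci], id[cj]))
    merge[step, ] <- pair
    height[step] <- bestd
    # Lance-Williams update for Ward (squared-distance scale)
    ni <- size[ci]; nj <- size[cj]
    for (k in setdiff(active, c(ci, cj))) {
      nk <- size[k]
      d_new <- ((ni + nk) * d[ci, k] + (nj + nk) * d[cj, k] -
                  nk * bestd) / (ni + nj + nk)
      d[ci, k] <- d[k, ci] <- d_new
    }
    size[ci] <- ni + nj
    id[ci] <- step
    active <- setdiff(active, cj)
  }

  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge),
                       labels = labels, method = "ward",
                       dist.method = "squared euclidean"),
                  class = "hclust")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy, supports = NULL,
                 n_boot = 0L, labels = labels),
            class = "population_tree")
}

# leaf ordering compatible with the merge matrix (for plotting only)
hclust_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

# leaf-label sets of all internal clusters of an hclust merge matrix
merge_clades <- function(merge, labels) {
  sets <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    grab <- function(node) if (node < 0L) labels[-node] else sets[[node]]
    sets[[s]] <- sort(c(grab(merge[s, 1L]), grab(merge[s, 2L])))
  }
  vapply(sets, paste, character(1), collapse = "\r")
}

#' Marker-bootstrap support for the Ward population tree
#'
#' Resamples markers with replacement, recomputes population frequencies
#' and the Ward tree, and scores each internal node of the point-estimate
#' tree by the percentage of replicates containing the same leaf set as a
#' cluster.
#'
#' @param gm a [genotype_matrix()].
#' @param partition population partition.
#' @param n_boot bootstrap replicates (paper-scale default 10000).
#' @param seed integer seed.
#' @return A `population_tree` whose `supports` (percent, in merge order)
#'   are also attached as node labels of the `phylo` component.
#' @export
bootstrap_support <- function(gm, partition, n_boot = 10000, seed = 1) {
  stopifnot(n_boot >= 1)
  freq <- frequency_matrix(gm, partition)
  tree <- ward_tree(freq)
  obs <- merge_clades(tree$hclust$merge, tree$labels)
  counts <- integer(length(obs))
  rng <- new_rng(seed)
  l <- ncol(freq)
  for (b in seq_len(n_boot)) {
    cols <- rng$resample(l)
    tb <- ward_tree(freq[, cols, drop = FALSE])
    counts <- counts + obs %in% merge_clades(tb$hclust$merge, tb$labels)
  }
  support <- 100 * counts / n_boot
  tree$supports <- support
  tree$n_boot <- n_boot
  tree$phylo <- annotate_supports(tree$phylo, tree$hclust, support,
                                  tree$labels)
  tree
}

# attach supports (in hclust merge order) as phylo node labels, matched by
# clade leaf set; the root gets 100 by convention
annotate_supports <- function(phy, hc, support, labels) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  kids <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) kids[[i]] <- phy$tip.label[i]
  # resolve descendant leaf sets bottom-up
  repeat {
    done <- TRUE
    for (node in seq.int(ntip + 1L, ntip + nnode)) {
      if (!is.null(kids[[node]])) next
      ch <- phy$edge[phy$edge[, 1L] == node, 2L]
      if (all(!vapply(kids[ch], is.null, logical(1)))) {
        kids[[node]] <- sort(unlist(kids[ch]))
      } else done <- FALSE
    }
    if (done) break
  }
  node_sets <- vapply(kids[seq.int(ntip + 1L, ntip + nnode)],
                      paste, character(1), collapse = "\r")
  merge_sets <- merge_clades(hc$merge, labels)
  idx <- match(node_sets, merge_sets)
  phy$node.label <- ifelse(is.na(idx), "", format(support[idx]))
  phy
}

#' @export
print.population_tree <- function(x, ...) {
  cat("population tree over", length(x$labels), "populations")
  if (x$n_boot > 0L) cat(" (", x$n_boot, "bootstrap replicates )")
  cat("\n")
  print(x$phylo)
  invisible(x)
}

#' Serialize a population tree as Newick
#'
#' Branch lengths are Ward-height differences; internal node labels carry
#' bootstrap support (percent) when present.
#'
#' @param tree a `population_tree`.
#' @param path output path.
#' @return the Newick string, invisibly.
#' @export
write_population_tree <- function(tree, path) {
  nw <- ape::write.tree(tree$phylo)
  writeLines(nw, path)
  invisible(nw)
}
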