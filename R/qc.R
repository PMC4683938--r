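#' Quality-control configuration
#'
#' Thresholds mirror common SNP-chip practice for small-population studies:
#' marker and sample call rates over 95%, per-marker quality (median GC
#' proxy) over 0.6, marker heterozygosity within 3 standard deviations of
#' the across-marker mean, and a Hardy-Weinberg exact-test cut-off of 1e-16,
#' with sex-chromosome/unmapped markers dropped first.
#'
#' @param min_marker_call_rate,min_sample_call_rate call-rate fractions in
#'   `[0, 1]`.
#' @param min_quality minimum per-marker quality score; only applied when the
#'   genotype matrix carries quality scores.
#' @param het_sd_window width of the heterozygosity filter in standard
#'   deviations.
#' @param hwe_alpha Hardy-Weinberg exact-test p-value cut-off in `(0, 1)`.
#' @param drop_nonautosomal drop markers whose chromosome label is not a
#'   positive integer (sex chromosomes, "0"/unmapped)?
#' @param hwe_by_population test Hardy-Weinberg within each population
#'   (requires a partition in [apply_qc()]); default pools all samples.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(min_marker_call_rate = 0.95,
                      min_sample_call_rate = 0.95,
                      min_quality = 0.6,
                      het_sd_window = 3,
                      hwe_alpha = 1e-16,
                      drop_nonautosomal = TRUE,
                      hwe_by_population = FALSE) {
  stopifnot(min_marker_call_rate >= 0, min_marker_call_rate <= 1,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            het_sd_window > 0, hwe_alpha > 0, hwe_alpha < 1)
  structure(list(min_marker_call_rate = min_marker_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 min_quality = min_quality,
                 het_sd_window = het_sd_window,
                 hwe_alpha = hwe_alpha,
                 drop_nonautosomal = isTRUE(drop_nonautosomal),
                 hwe_by_population = isTRUE(hwe_by_population)),
            class = "qc_config")
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' p-value sums the probabilities of every heterozygote count (same margin,
#' matching parity) whose conditional probability does not exceed that of
#' the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("no genotyped samples")
  nA <- 2 * n_AA + n_Aa
  na_ <- 2 * n - nA
  rare <- min(nA, na_)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | margin) up to the common normalizing constant
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) + lfactorial(n) -
      lfactorial(h) - lfactorial(hom_rare) - lfactorial(hom_common)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with margin")
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# observed heterozygote fraction per marker (missing excluded per marker)
marker_het_fraction <- function(gm) {
  d <- gm$dosages
  colSums(d == 1L, na.rm = TRUE) / pmax(colSums(!is.na(d)), 1L)
}

#' Flag markers with outlying heterozygosity
#'
#' Marks markers whose observed heterozygote fraction lies outside
#' `mean +/- window * sd`, both computed across all markers.
#'
#' @param gm a [genotype_matrix()].
#' @param window width in standard deviations (default 3).
#' @return logical vector, `TRUE` = marker flagged as outlier.
#' @export
heterozygosity_outlier_filter <- function(gm, window = 3) {
  het <- marker_het_fraction(gm)
  if (length(het) < 2L) return(rep(FALSE, length(het)))
  s <- stats::sd(het)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(het)))
  m <- mean(het)
  het < m - window * s | het > m + window * s
}

#' Apply the full marker/sample QC cascade
#'
#' Filters are applied in a fixed order, each on the currently retained
#' data: non-autosomal/unmapped markers, marker call rate, sample call rate,
#' marker quality (if scores present), heterozygosity outliers, and finally
#' the Hardy-Weinberg exact test. The report itemizes removals per step.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [qc_config()].
#' @param partition optional population partition; required when
#'   `config$hwe_by_population` is `TRUE` (the marker is dropped if the test
#'   fails in any population).
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (class `qc_report`).
#' @export
apply_qc <- function(gm, config = qc_config(), partition = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  steps <- list()
  note <- function(step, axis, removed) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, axis = axis, removed = removed,
      stringsAsFactors = FALSE)
  }
  in_dim <- dim(gm$dosages)

  drop_markers <- function(gm, bad, step) {
    note(step, "marker", sum(bad))
    if (any(bad)) gm <- subset(gm, markers = gm$markers$id[!bad])
    if (ncol(gm$dosages) == 0L) {
      rep <- qc_report(steps, in_dim, dim(gm$dosages))
      stop(structure(class = c("herdvar_qc_error", "error", "condition"),
                     list(message = paste0("all markers removed at step '",
                                           step, "'"),
                          call = sys.call(-1L), report = rep)))
    }
    gm
  }

  if (config$drop_nonautosomal) {
    aut <- grepl("^[0-9]+$", gm$markers$chromosome) &
      suppressWarnings(as.integer(gm$markers$chromosome)) > 0L
    gm <- drop_markers(gm, !aut, "nonautosomal")
  }

  cr <- colMeans(!is.na(gm$dosages))
  gm <- drop_markers(gm, cr < config$min_marker_call_rate,
                     "marker_call_rate")

  scr <- rowMeans(!is.na(gm$dosages))
  bad_s <- scr < config$min_sample_call_rate
  note("sample_call_rate", "sample", sum(bad_s))
  if (any(bad_s)) gm <- subset(gm, samples = gm$sample_ids[!bad_s])
  if (nrow(gm$dosages) == 0L) stop("all samples removed by call-rate filter")

  if (!all(is.na(gm$markers$quality))) {
    gm <- drop_markers(gm, gm$markers$quality < config$min_quality,
                       "quality")
  } else {
    note("quality", "marker", 0L)
  }

  gm <- drop_markers(gm, heterozygosity_outlier_filter(gm, config$het_sd_window),
                     "heterozygosity")

  hwe_p_for <- function(d) {
    apply(d, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) return(1)
      hwe_exact_test(sum(col == 0L), sum(col == 1L), sum(col == 2L))
    })
  }
  if (config$hwe_by_population) {
    if (is.null(partition))
      stop("hwe_by_population requires a partition")
    idx <- pop_indices(gm, partition)
    pmat <- vapply(idx, function(i) hwe_p_for(gm$dosages[i, , drop = FALSE]),
                   numeric(ncol(gm$dosages)))
    pvals <- apply(as.matrix(pmat), 1L, min)
  } else {
    pvals <- hwe_p_for(gm$dosages)
  }
  gm <- drop_markers(gm, pvals < config$hwe_alpha, "hwe")

  list(genotypes = gm, report = qc_report(steps, in_dim, dim(gm$dosages)))
}

qc_report <- function(steps, in_dim, out_dim) {
  tab <- do.call(rbind, steps)
  structure(list(steps = tab,
                 input = c(samples = in_dim[1L], markers = in_dim[2L]),
                 retained = c(samples = out_dim[1L], markers = out_dim[2L])),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$input["samples"], "samples x", x$input["markers"],
      "markers in;", x$retained["samples"], "x", x$retained["markers"],
      "retained\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) x$steps

#' Serialize a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
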