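#' Construct a genotype matrix object
#'
#' The in-memory genotype model consumed by every analysis in the package:
#' a samples x markers dosage matrix (counts of `allele_b`, values 0/1/2,
#' `NA` = missing) plus marker metadata and sample identifiers.
#'
#' @param dosages integer matrix, samples in rows, markers in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param markers data.frame with columns `id`, `chromosome`, `position`,
#'   `allele_a`, `allele_b` and optionally `quality` (score in `[0, 1]`,
#'   present for all markers or none).
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `markers`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'          dimnames = list(NULL, c("m1", "m2"))),
#'   data.frame(id = c("m1", "m2"), chromosome = c("1", "2"),
#'              position = c(100L, 200L), allele_a = "A", allele_b = "G"),
#'   c("s1", "s2"))
#' dim(gm)
#' @export
genotype_matrix <- function(dosages, markers, sample_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  sample_ids <- as.character(sample_ids)

  required <- c("id", "chromosome", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0L)
    stop("marker metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"quality" %in% names(markers)) markers$quality <- NA_real_
  markers$id <- as.character(markers$id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position <- as.integer(markers$position)
  markers$allele_a <- as.character(markers$allele_a)
  markers$allele_b <- as.character(markers$allele_b)
  markers$quality <- as.numeric(markers$quality)

  if (nrow(dosages) != length(sample_ids))
    stop("dosage rows (", nrow(dosages), ") != number of sample ids (",
         length(sample_ids), ")")
  if (ncol(dosages) != nrow(markers))
    stop("dosage columns (", ncol(dosages), ") != number of markers (",
         nrow(markers), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids: ",
         paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (any(markers$position < 0L, na.rm = TRUE))
    stop("negative marker positions")
  qc_na <- is.na(markers$quality)
  if (any(qc_na) && !all(qc_na))
    stop("quality must be present for all markers or none")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")

  rownames(dosages) <- sample_ids
  colnames(dosages) <- markers$id
  rownames(markers) <- NULL
  structure(list(dosages = dosages, markers = markers,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "markers\n")
  n_chr <- length(unique(x$markers$chromosome))
  miss <- mean(is.na(x$dosages))
  cat("  chromosomes:", n_chr,
      " missing:", sprintf("%.2f%%", 100 * miss), "\n")
  invisible(x)
}

#' Population partition
#'
#' Validates a sample -> population assignment against a genotype matrix.
#'
#' @param x named character vector (`names` = sample ids, values = population
#'   labels) or a two-column data.frame (`sample_id`, `population`).
#' @param gm optional `genotype_matrix` to validate membership against.
#' @return named factor mapping sample id to population label.
#' @export
population_partition <- function(x, gm = NULL) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("partition data.frame needs two columns")
    out <- stats::setNames(as.character(x[[2L]]), as.character(x[[1L]]))
  } else {
    if (is.null(names(x))) stop("partition vector must be named by sample id")
    out <- stats::setNames(as.character(x), names(x))
  }
  if (anyDuplicated(names(out)))
    stop("duplicate sample ids in partition")
  if (!is.null(gm)) {
    unknown <- setdiff(names(out), gm$sample_ids)
    if (length(unknown))
      stop("partition samples absent from genotype matrix: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (any(table(out) < 1L)) stop("empty population in partition")
  factor(out)[names(out)]
}

# split sample indices of gm by population, in partition order
pop_indices <- function(gm, partition) {
  partition <- population_partition(partition, gm)
  ids <- intersect(gm$sample_ids, names(partition))
  lapply(split(ids, partition[ids], drop = TRUE),
         function(s) match(s, gm$sample_ids))
}

#' Read genotypes from PLINK text files
#'
#' Parses whitespace-delimited PED/MAP files into a [genotype_matrix()].
#' Dosages count copies of `allele_b`, defined per marker as the minor
#' allele (ties broken towards the lexicographically larger label), so the
#' coding is deterministic for a given file. `0 0` genotypes become missing.
#'
#' @param ped_path path to the PED file (6 header columns then two allele
#'   columns per marker).
#' @param map_path path to the MAP file (chromosome, id, genetic position,
#'   bp position).
#' @param quality optional numeric vector of per-marker quality scores.
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, quality = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4L) stop("MAP file must have 4 columns")
  l <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  a1 <- matrix("0", n, l)
  a2 <- matrix("0", n, l)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * l)
      stop("PED line ", i, " has ", length(f), " fields, expected ",
           6L + 2L * l)
    ids[i] <- f[2L]
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1L, 2L * l, by = 2L)]
    a2[i, ] <- g[seq(2L, 2L * l, by = 2L)]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample id in PED: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  dos <- matrix(NA_integer_, n, l)
  allele_a <- character(l)
  allele_b <- character(l)
  for (j in seq_len(l)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("marker ", map[j, 2L], " has >2 alleles: ",
           paste(alleles, collapse = ", "))
    if (length(alleles) == 0L) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      allele_a[j] <- alleles; allele_b[j] <- "0"
      dos[, j] <- ifelse(a1[, j] == "0" | a2[, j] == "0", NA_integer_, 0L)
      next
    }
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    # dosage counts the minor allele; lexicographically larger label on ties
    b <- if (cnt[1L] < cnt[2L]) alleles[1L] else alleles[2L]
    a <- setdiff(alleles, b)
    allele_a[j] <- a; allele_b[j] <- b
    d <- (a1[, j] == b) + (a2[, j] == b)
    d[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    dos[, j] <- as.integer(d)
  }

  markers <- data.frame(id = map[[2L]], chromosome = map[[1L]],
                        position = as.integer(map[[4L]]),
                        allele_a = allele_a, allele_b = allele_b,
                        stringsAsFactors = FALSE)
  if (!is.null(quality)) markers$quality <- as.numeric(quality)
  genotype_matrix(dos, markers, ids)
}

#' Write genotypes to PLINK text files
#'
#' Inverse of [read_plink_text()]: emits a whitespace-delimited PED (family
#' id = sample id, remaining pedigree columns zero) and the matching MAP.
#' Missing dosages become `0 0`. Re-reading the output yields identical
#' dosages in identical order.
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @param family optional vector of family labels (e.g. population) written
#'   to PED column 1.
#' @export
write_plink_text <- function(gm, ped_path, map_path, family = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  utils::write.table(
    data.frame(mk$chromosome, mk$id, 0L, mk$position),
    map_path, quote = FALSE, sep = " ",
    row.names = FALSE, col.names = FALSE)

  n <- nrow(gm$dosages); l <- ncol(gm$dosages)
  if (is.null(family)) family <- gm$sample_ids
  a <- mk$allele_a; b <- mk$allele_b
  # fall back to a placeholder so dosage-0 genotypes are still writable
  a[a == "0"] <- "A"
  b[b == "0"] <- "B"
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- gm$dosages[i, ]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, b, a))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2L, b, a))
    lines[i] <- paste(c(family[i], gm$sample_ids[i], "0", "0", "0", "-9",
                        as.vector(rbind(g1, g2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(NULL)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples optional character vector of sample ids to keep (order
#'   preserved as in `x`).
#' @param markers optional character vector of marker ids to keep.
#' @param ... unused.
#' @return A [genotype_matrix()] restricted to the requested entries.
#' @export
subset.genotype_matrix <- function(x, samples = NULL, markers = NULL, ...) {
  si <- seq_along(x$sample_ids)
  mi <- seq_len(nrow(x$markers))
  if (!is.null(samples)) {
    unknown <- setdiff(samples, x$sample_ids)
    if (length(unknown))
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    si <- which(x$sample_ids %in% samples)
  }
  if (!is.null(markers)) {
    unknown <- setdiff(markers, x$markers$id)
    if (length(unknown))
      stop("unknown marker id(s): ", paste(unknown, collapse = ", "))
    mi <- which(x$markers$id %in% markers)
  }
  genotype_matrix(x$dosages[si, mi, drop = FALSE],
                  x$markers[mi, , drop = FALSE],
                  x$sample_ids[si])
}

#' Canonicalize allele coding
#'
#' Recodes each marker so that `allele_b` (the counted allele) is the minor
#' allele, with ties broken towards the lexicographically larger label —
#' exactly the coding [read_plink_text()] infers from a file. A matrix in
#' canonical coding therefore round-trips bit-identically through
#' [write_plink_text()] / [read_plink_text()]. All statistics in the
#' package are invariant to this relabeling.
#'
#' @param gm a [genotype_matrix()].
#' @return The recoded [genotype_matrix()], with attribute `"flipped"`
#'   giving the marker ids whose coding was swapped.
#' @export
canonicalize_alleles <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  nn <- colSums(!is.na(d))
  cb <- colSums(d, na.rm = TRUE)
  ca <- 2L * nn - cb
  swap_tie <- gm$markers$allele_a > gm$markers$allele_b
  flip <- (cb > ca) | (cb == ca & swap_tie)
  flip[nn == 0L] <- FALSE
  if (any(flip)) {
    d[, flip] <- 2L - d[, flip, drop = FALSE]
    mk <- gm$markers
    tmp <- mk$allele_a[flip]
    mk$allele_a[flip] <- mk$allele_b[flip]
    mk$allele_b[flip] <- tmp
    gm <- genotype_matrix(d, mk, gm$sample_ids)
  }
  attr(gm, "flipped") <- gm$markers$id[flip]
  gm
}

#' Read/write the internal TSV dosage-matrix format
#'
#' A plain TSV with a header of marker ids and one row per sample (first
#' column `sample_id`); used for small fixtures. Marker metadata beyond ids
#' is synthesized (single chromosome, consecutive positions) unless given.
#'
#' @param path file path.
#' @param markers optional full marker metadata data.frame.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path, markers = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  dos <- as.matrix(tab[, -1L, drop = FALSE])
  if (is.null(markers))
    markers <- data.frame(id = colnames(dos), chromosome = "1",
                          position = seq_len(ncol(dos)),
                          allele_a = "A", allele_b = "B",
                          stringsAsFactors = FALSE)
  genotype_matrix(dos, markers, ids)
}

#' @rdname read_dosage_tsv
#' @param gm a [genotype_matrix()] to serialize.
#' @export
write_dosage_tsv <- function(gm, path) {
  tab <- data.frame(sample_id = gm$sample_ids, gm$dosages,
                    check.names = FALSE)
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}
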