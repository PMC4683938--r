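#' Pipeline run configuration
#'
#' Bundles inputs and analysis settings with the study-scale defaults:
#' 100 locus-bootstrap replicates for F_ST significance, 10,000 marker
#' bootstraps for the tree, 1000 AMOVA permutations, and a 50-generation
#' heterozygosity forecast horizon.
#'
#' @param ped,map paths to PLINK text genotypes.
#' @param pops path to a two-column sample/population TSV.
#' @param out_dir output directory (created if absent).
#' @param qc a [qc_config()].
#' @param maf_min allele-frequency cut-off for the Ne estimator.
#' @param n_boot_fst,n_boot_tree,n_perm_amova replicate counts.
#' @param forecast_horizon generations to project heterozygosity over.
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(ped, map, pops, out_dir,
                       qc = qc_config(), maf_min = 0.05,
                       n_boot_fst = 100, n_boot_tree = 10000,
                       n_perm_amova = 1000, forecast_horizon = 50,
                       seed = 1) {
  stopifnot(n_boot_fst >= 1, n_boot_tree >= 1, n_perm_amova >= 1,
            forecast_horizon >= 0)
  structure(list(ped = ped, map = map, pops = pops, out_dir = out_dir,
                 qc = qc, maf_min = maf_min, n_boot_fst = n_boot_fst,
                 n_boot_tree = n_boot_tree, n_perm_amova = n_perm_amova,
                 forecast_horizon = forecast_horizon, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' QC, per-population diversity, pairwise F_ST / Nei's D with bootstrap
#' significance, per-pair F_ST scans, LD-based Ne with heterozygosity
#' forecasts, rarefaction richness, per-population GRM summaries with PCA,
#' AMOVA, and the Ward allele-frequency tree — each stage written as plain
#' TSV/JSON/Newick under `config$out_dir`, plus a JSON manifest recording
#' the seed and stage timings. Populations are analysed jointly for
#' distances/AMOVA/tree and independently for diversity, Ne and GRM
#' summaries.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging?
#' @return invisible list with every stage result.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    res
  }
  out <- function(f) file.path(config$out_dir, f)

  gm <- stage("read", read_plink_text(config$ped, config$map))
  pops_tab <- utils::read.table(config$pops, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  partition <- population_partition(pops_tab, gm)

  qcres <- stage("qc", apply_qc(gm, config$qc, partition))
  gm <- qcres$genotypes
  partition <- partition[names(partition) %in% gm$sample_ids]
  write_qc_report(qcres$report, out("qc_report.tsv"))

  div <- stage("diversity", diversity_metrics(gm, partition))
  rich <- stage("richness", richness_table(gm, partition))
  grms <- stage("grm", grm_summaries(gm, partition))
  div_full <- merge(merge(div, rich, by = "population"), grms,
                    by = "population")
  utils::write.table(div_full, out("diversity_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  dist <- stage("fst", pairwise_fst(gm, partition, config$n_boot_fst,
                                    seed = config$seed))
  write_distance_set(dist, out("distance_matrix.tsv"))
  utils::write.table(dist$p_value, out("fst_pvalues.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  pop_names <- levels(partition)
  stage("fst_scan", {
    for (i in seq_along(pop_names)[-length(pop_names)])
      for (j in seq((i + 1L), length(pop_names))) {
        sc <- fst_scan(gm, partition, pop_names[i], pop_names[j])
        write_fst_scan(sc, out(sprintf("fst_scan_%s_%s.tsv",
                                       pop_names[i], pop_names[j])))
      }
    NULL
  })

  ne_list <- stage("ne", lapply(stats::setNames(pop_names, pop_names),
    function(p) tryCatch(
      ne_genome(gm, partition, p, maf_min = config$maf_min),
      error = function(e) NULL)))
  ne_tab <- do.call(rbind, lapply(pop_names, function(p) {
    est <- ne_list[[p]]
    data.frame(population = p,
               ne = if (is.null(est)) NA_real_ else est$ne,
               ne_sd = if (is.null(est)) NA_real_ else est$sd,
               n_chromosomes = if (is.null(est)) 0L
               else est$n_chromosomes_used,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ne_tab, out("ne_estimates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  forecasts <- stage("forecast", lapply(pop_names, function(p) {
    est <- ne_list[[p]]
    if (is.null(est) || !is.finite(est$ne)) return(NULL)
    h0 <- div$h_obs[div$population == p]
    fc <- project_heterozygosity(h0, est$ne, config$forecast_horizon)
    utils::write.table(fc$trajectory,
                       out(sprintf("forecast_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fc
  }))

  am <- stage("amova", amova_one_level(gm, partition,
                                       config$n_perm_amova,
                                       seed = config$seed))
  write_amova(am, out("amova.tsv"))

  tree <- stage("tree", bootstrap_support(gm, partition,
                                          config$n_boot_tree,
                                          seed = config$seed))
  write_population_tree(tree, out("tree.nwk"))

  pca <- stage("pca", {
    g <- build_grm(gm)
    pc <- pca_from_grm(g, n_components = min(4L, nrow(g$G)))
    utils::write.table(
      data.frame(sample_id = rownames(pc$coordinates),
                 population = as.character(partition[
                   rownames(pc$coordinates)]),
                 pc$coordinates),
      out("pca_coordinates.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    pc
  })

  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("herdvar")),
                   r_version = R.version.string,
                   n_samples = nrow(gm$dosages),
                   n_markers = ncol(gm$dosages),
                   populations = pop_names,
                   settings = config[c("maf_min", "n_boot_fst",
                                       "n_boot_tree", "n_perm_amova",
                                       "forecast_horizon")],
                   timings = timings)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(genotypes = gm, partition = partition,
                 qc = qcres$report, diversity = div_full,
                 distances = dist, ne = ne_list, forecasts = forecasts,
                 amova = am, tree = tree, pca = pca,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Minimal subcommand interface: `run` executes [run_full_analysis()] on
#' PED/MAP inputs, `simulate` writes an island-scenario dataset.
#' Invoke from a script as `herdvar_cli(commandArgs(TRUE))`.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the result of the dispatched command.
#' @export
herdvar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: herdvar <command> [options]",
    "  run      --ped F --map F --pops F --out DIR [--seed N]",
    "           [--maf-min X] [--boot-fst N] [--boot-tree N]",
    "           [--perm-amova N] [--horizon N]",
    "  simulate --out PREFIX [--seed N] [--markers N]",
    sep = "\n")
  if (length(args) == 0L) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1L]
  opts <- args[-1L]
  getopt <- function(flag, default = NULL) {
    i <- which(opts == flag)
    if (length(i) == 0L) return(default)
    opts[i[1L] + 1L]
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  if (cmd == "run") {
    cfg <- run_config(
      ped = getopt("--ped"), map = getopt("--map"),
      pops = getopt("--pops"), out_dir = getopt("--out"),
      maf_min = num(getopt("--maf-min", "0.05")),
      n_boot_fst = num(getopt("--boot-fst", "100")),
      n_boot_tree = num(getopt("--boot-tree", "10000")),
      n_perm_amova = num(getopt("--perm-amova", "1000")),
      forecast_horizon = num(getopt("--horizon", "50")),
      seed = num(getopt("--seed", "1")))
    invisible(run_full_analysis(cfg))
  } else if (cmd == "simulate") {
    sim <- korean_like_scenario(
      seed = num(getopt("--seed", "1")),
      n_markers = num(getopt("--markers", "29000")))
    write_simulated_dataset(sim, getopt("--out"))
    invisible(sim)
  } else {
    cat(usage, "\n")
    stop("unknown command: ", cmd)
  }
}
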