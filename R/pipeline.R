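# Config handling: a config is a plain named list, or a path to a JSON file
# holding one. Missing entries fall back to the defaults below.

default_config <- function() {
  list(
    pool = list(K = 40, L = 300, mu = 1.5, alpha = 1),
    cohort = list(n_ancient = 41, n_modern = 808, loss = 0,
                  miss_rate = 0.01, end_bias = 4, deam_rate = 0.005),
    morpho = list(n_big = 20, n_small = 20, mean_big = c(30, 42),
                  mean_small = c(22, 32), sd = 1.5, rho = 0.6,
                  element = "astragalus"),
    policy = "complete_deletion",
    n_reps = 10000,
    epsilon = 0,
    n_perms = 10000,
    seed = NULL,
    out_dir = "."
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a named list or a JSON file path")
  merged <- utils::modifyList(default_config(), config)
  if (is.null(merged$seed)) stopf("config must set an integer 'seed'")
  merged
}

# Fixed per-stage seed offsets: one user-facing seed, reproducible stages.
stage_seed <- function(seed, stage) {
  off <- c(pool = 11L, cohort = 22L, morpho = 33L, temporal = 44L,
           permutation = 55L)
  as.integer(seed) + off[[stage]]
}

#' Generate a complete synthetic dataset on disk
#'
#' Simulates a haplotype pool, draws ancient/modern cohorts with the
#' configured lineage loss and damage, and simulates an osteometric table,
#' writing `alignment.fasta`, `samples.tsv`, `measurements.tsv` and a
#' `simulate_config.json` echo into `out_dir`. Output is byte-identical for
#' equal seeds.
#'
#' @param config Named list or path to a JSON config; recognised entries:
#'   `pool` (`K`, `L`, `mu`, `alpha`), `cohort` (`n_ancient`, `n_modern`,
#'   `loss`, `miss_rate`, `end_bias`, `deam_rate`), `morpho`
#'   (see [simulate_morphometrics()]), `seed` (required), `out_dir`.
#' @return Invisibly, a named list of the written file paths.
#' @export
pipeline_simulate <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pool <- do.call(simulate_pool, c(cfg$pool, list(seed = stage_seed(cfg$seed, "pool"))))
  aset <- do.call(sample_cohorts,
                  c(list(pool = pool), cfg$cohort,
                    list(seed = stage_seed(cfg$seed, "cohort"))))
  mor <- do.call(simulate_morphometrics,
                 c(cfg$morpho, list(seed = stage_seed(cfg$seed, "morpho"))))
  paths <- list(fasta = file.path(cfg$out_dir, "alignment.fasta"),
                meta = file.path(cfg$out_dir, "samples.tsv"),
                measurements = file.path(cfg$out_dir, "measurements.tsv"),
                config = file.path(cfg$out_dir, "simulate_config.json"))
  write_alignment(aset, paths$fasta, paths$meta)
  utils::write.table(
    data.frame(id = mor$data$id, element = mor$element,
               x_mm = mor$data$x, y_mm = mor$data$y),
    paths$measurements, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cfg[c("pool", "cohort", "morpho", "seed")],
                       paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full temporal-diversity analysis
#'
#' Reads an alignment + metadata (and optionally a measurement table), then
#' runs the stages in order: per-stratum diversity summaries, the
#' bootstrap-rarefaction temporal comparison, haplotype networks
#' (minimum-spanning and two-layer temporal), and — when measurements are
#' supplied — size-group classification with permutation tests. Writes
#' `report.json` plus per-stage artifacts (`haplotypes.tsv`,
#' `network.graphml`, `temporal_network.graphml`) into `out_dir`, and an
#' `analysis.log` recording package version, seed and policy. The report body
#' carries no timestamps, so reruns with equal seeds are byte-identical.
#'
#' @param config Named list or JSON path; entries: `fasta`, `meta`
#'   (required paths), `measurements` (optional path), `partitions`
#'   (see [temporal_diversity_test()]; default all-samples), `policy`,
#'   `n_reps`, `epsilon`, `n_perms`, `seed` (required), `out_dir`.
#' @return Invisibly, the report list.
#' @export
pipeline_analyze <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$fasta) || is.null(cfg$meta))
    stopf("config must set 'fasta' and 'meta' input paths")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  aset <- stage("io", read_alignment(cfg$fasta, cfg$meta))
  div <- stage("diversity", {
    lapply(stats::setNames(STRATA, STRATA), function(s)
      unclass(diversity_summary(subset(aset, stratum = s), cfg$policy)))
  })
  tc <- stage("temporal_comparison",
              temporal_diversity_test(aset, partitions = cfg$partitions,
                                      n_reps = cfg$n_reps,
                                      seed = stage_seed(cfg$seed, "temporal"),
                                      policy = cfg$policy))
  nets <- stage("networks", {
    ht <- call_haplotypes(aset, cfg$policy)
    msn <- build_msn(ht, epsilon = cfg$epsilon)
    tn <- build_temporal(ht)
    write_results(ht, file.path(cfg$out_dir, "haplotypes.tsv"), "tsv")
    export_network(msn, file.path(cfg$out_dir, "network.graphml"), "graphml")
    export_network(tn, file.path(cfg$out_dir, "temporal_network.graphml"), "graphml")
    list(msn = msn, temporal = tn)
  })
  morpho <- NULL
  if (!is.null(cfg$measurements)) {
    morpho <- stage("morphometrics", {
      md <- read_measurements(cfg$measurements)
      gr <- classify_size_groups(md)
      test_group_difference(md, gr, n_perms = cfg$n_perms,
                            seed = stage_seed(cfg$seed, "permutation"))
    })
  }
  report <- list(
    seed = cfg$seed, policy = cfg$policy, n_reps = cfg$n_reps,
    diversity = div,
    temporal = lapply(unclass(tc), function(r)
      list(partition = r$partition, m = r$m, n_reps = r$n_reps,
           seed = r$seed,
           Hd = list(observed = r$stats$Hd$observed,
                     percentile = r$stats$Hd$percentile),
           S = list(observed = r$stats$S$observed,
                    percentile = r$stats$S$percentile))),
    network = list(n_haplotypes = nrow(nets$msn$nodes),
                   n_edges = nrow(nets$msn$edges),
                   shared = unname(nets$temporal$counts[["shared"]]),
                   private_ancient = unname(nets$temporal$counts[["private_ancient"]]),
                   private_modern = unname(nets$temporal$counts[["private_modern"]])),
    morphometrics = if (!is.null(morpho))
      list(n_big = sum(morpho$assignment == "big"),
           n_small = sum(morpho$assignment == "small"),
           tests = morpho$tests)
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(sprintf("haplodiv %s", as.character(utils::packageVersion("haplodiv"))),
               sprintf("seed: %d", cfg$seed),
               sprintf("policy: %s", cfg$policy),
               sprintf("run completed: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(cfg$out_dir, "analysis.log"))
  invisible(report)
}

#' Print a human-readable summary of an analysis report
#'
#' Reads the `report.json` written by [pipeline_analyze()] and prints the
#' per-cohort diversity statistics, the bootstrap percentiles (flagging any
#' ancient percentile above 95 as a diversity-loss signal), the haplotype
#' sharing counts and, if present, the morphometric test results.
#'
#' @param report_path Path to a `report.json`.
#' @return Invisibly, the report list.
#' @export
pipeline_report <- function(report_path) {
  if (!file.exists(report_path)) stopf("report file not found: %s", report_path)
  rep <- jsonlite::read_json(report_path, simplifyVector = TRUE)
  cat("=== temporal diversity report ===\n")
  for (s in names(rep$diversity)) {
    d <- rep$diversity[[s]]
    cat(sprintf("%-8s n = %d  h = %d  Hd = %.4f  S = %d  pi = %.5f\n",
                s, d$n, d$h, d$Hd, d$S, d$pi))
  }
  tp <- rep$temporal
  for (nm in names(tp)) {
    r <- tp[[nm]]
    flag <- function(p) if (p > 95) "  ** diversity loss signal (percentile > 95)" else ""
    cat(sprintf("partition '%s' (m = %d, %d reps):\n", r$partition, r$m, r$n_reps))
    cat(sprintf("  Hd = %.4f at percentile %.1f%s\n",
                r$Hd$observed, r$Hd$percentile, flag(r$Hd$percentile)))
    cat(sprintf("  S  = %d at percentile %.1f%s\n",
                as.integer(r$S$observed), r$S$percentile, flag(r$S$percentile)))
  }
  nw <- rep$network
  cat(sprintf("haplotypes: %d total; shared = %d, private ancient = %d, private modern = %d\n",
              nw$n_haplotypes, nw$shared, nw$private_ancient, nw$private_modern))
  if (!is.null(rep$morphometrics)) {
    mo <- rep$morphometrics
    cat(sprintf("morphometrics: big = %d, small = %d; p-values: %s\n",
                mo$n_big, mo$n_small,
                paste(sprintf("%s=%.3g", mo$tests$statistic, mo$tests$p_value),
                      collapse = ", ")))
  }
  invisible(rep)
}
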