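# End-to-end orchestration: simulate -> call-cnv -> popstats -> ld ->
# correlate -> report, written as one reproducible bundle with a
# machine-readable manifest.  Identical config + seed must give a
# byte-identical bundle, so nothing time-dependent is ever written.

#' Build a validated run configuration
#'
#' @param seed integer seed governing every stochastic stage
#'   (mandatory; there is no wall-clock fallback).
#' @param out_dir output directory (created if absent).
#' @param populations list of [population_model]s (test populations).
#' @param reference the reference [population_model] (the pool every
#'   comparison is measured against).
#' @param sim_params an [acgh_sim_params].
#' @param detect_params a [detection_params].
#' @param r2_one_style forwarded to [write_population_summary()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed, out_dir, populations, reference,
                       sim_params = acgh_sim_params(),
                       detect_params = detection_params(),
                       r2_one_style = "1") {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed is mandatory and must be an integer")
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, TRUE, "population_model")),
            inherits(reference, "population_model"),
            inherits(sim_params, "acgh_sim_params"),
            inherits(detect_params, "detection_params"))
  structure(list(seed = seed, out_dir = out_dir, populations = populations,
                 reference = reference, sim_params = sim_params,
                 detect_params = detect_params, r2_one_style = r2_one_style),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON block mirrors [run_config()]: `seed`, `out_dir`,
#' `reference` and `populations` entries each carrying `name`, `n`,
#' `haplotype_freqs` (4 values, `+A +G -A -G` order), plus optional
#' `sim_params` and `detect_params` objects overriding the defaults.
#'
#' @param path JSON file.
#' @param out_dir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_pop <- function(p) population_model(p$name, p$n, unlist(p$haplotype_freqs))
  pops <- if (is.data.frame(cfg$populations)) {
    lapply(seq_len(nrow(cfg$populations)), function(i)
      population_model(cfg$populations$name[i], cfg$populations$n[i],
                       unlist(cfg$populations$haplotype_freqs[i])))
  } else lapply(cfg$populations, mk_pop)
  sim <- do.call(acgh_sim_params, as.list(cfg$sim_params %||% list()))
  det <- do.call(detection_params, as.list(cfg$detect_params %||% list()))
  run_config(seed = cfg$seed,
             out_dir = out_dir %||% cfg$out_dir %||% ".",
             populations = pops, reference = mk_pop(cfg$reference),
             sim_params = sim, detect_params = det,
             r2_one_style = cfg$r2_one_style %||% "1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_fingerprint <- function(config) {
  canon <- list(
    seed = config$seed,
    populations = lapply(config$populations, function(p)
      list(name = p$name, n = p$n_individuals,
           haplotype_freqs = unname(p$haplotype_freqs))),
    reference = list(name = config$reference$name,
                     n = config$reference$n_individuals,
                     haplotype_freqs = unname(config$reference$haplotype_freqs)),
    sim_params = unclass(config$sim_params),
    detect_params = unclass(config$detect_params))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA)
  unname(md5sum(tmp))
}

#' Observed pooled log2 ratio over an interval
#'
#' Mean dye-swap-combined signal of the probes inside a genomic
#' interval: the pooled-intensity readout used in the concordance
#' analysis against individual genotyping.
#'
#' @param probes a [probe_table].
#' @param interval list with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return numeric scalar (NA when no probe falls inside).
#' @export
pooled_log2_over_interval <- function(probes, interval) {
  inside <- probes$chrom == interval$chrom &
    probes$start >= interval$start & probes$start < interval$end
  if (!any(inside)) return(NA_real_)
  mean(combined_signal(probes)[inside])
}

#' Run the full pipeline
#'
#' Stages: (1) simulate genotypes and pooled aCGH comparisons;
#' (2) call regions per comparison with the rule-based and windowed
#' callers and keep the two-caller consensus; (3) per-population
#' genotype/allele/HWE/LD summaries with attached pooled intensities;
#' (4) Spearman correlation of pooled log2 against deleted-allele
#' frequency; (5) formatted report and run manifest.  Any stage
#' failure aborts the run and removes partial outputs.
#'
#' Bundle contents under `config$out_dir`: `genotypes.tsv`,
#' `probes_<comparison>.tsv`, `truth.bed`, `consensus.bed`,
#' `regions.tsv`, `summary.tsv`, `ld.tsv`, `correlation.json`,
#' `manifest.json`, `config_resolved.json`.
#'
#' @param config a [run_config].
#' @return invisibly, a list with the in-memory stage results
#'   (`genotypes`, `probes`, `truth`, `consensus`, `summaries`,
#'   `ld`, `correlation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(fun, file, ...) {
    path <- file.path(config$out_dir, file)
    fun(..., path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    s <- simulate_pool_acgh(config$populations, config$reference,
                            config$sim_params, config$seed)
    emit(function(x, p) write_genotype_table(x, p), "genotypes.tsv", s$genotypes)
    for (cmp in names(s$probes))
      emit(function(x, p) write_probe_table(x, p),
           paste0("probes_", cmp, ".tsv"), s$probes[[cmp]])
    emit(function(x, p) write_regions_bed(x, p), "truth.bed", s$truth)
    s
  })

  calls <- stage("call-cnv", {
    per_cmp <- lapply(sim$probes, function(pt) {
      a <- call_rule_based(pt, config$detect_params)
      b <- call_window(pt, config$detect_params)
      cnv_consensus(a, b, config$detect_params$concordance_overlap)
    })
    cons <- do.call(rbind, lapply(per_cmp, as.data.frame))
    cons <- cnv_regions(if (!is.null(cons)) cons else data.frame())
    emit(function(x, p) write_regions_bed(x, p), "consensus.bed", cons)
    emit(function(x, p) {
      con <- file(p, "wb"); on.exit(close(con))
      write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                  row.names = FALSE, eol = "\n")
    }, "regions.tsv", cons)
    cons
  })

  summaries <- stage("popstats", {
    pooled <- vapply(sim$probes, pooled_log2_over_interval,
                     numeric(1), interval = config$sim_params$deletion_interval)
    names(pooled) <- sub("_vs_.*$", "", names(sim$probes))
    s <- population_summaries(sim$genotypes, pooled_log2 = pooled)
    emit(function(x, p) write_population_summary(x, p, config$r2_one_style),
         "summary.tsv", s)
    s
  })

  ld <- stage("ld", {
    tab <- ld_table(sim$genotypes)
    emit(function(x, p) {
      con <- file(p, "wb"); on.exit(close(con))
      write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    }, "ld.tsv", tab)
    tab
  })

  correlation <- stage("correlate", {
    have <- !is.na(summaries$pooled_log2) & !is.na(summaries$cnv_minus_pct)
    res <- if (sum(have) >= 3L)
      spearman_correlation(summaries$pooled_log2[have],
                           summaries$cnv_minus_pct[have])
    else list(rho = NA_real_, p_value = NA_real_, n = sum(have))
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA),
         "correlation.json",
         list(rho = res$rho, abs_rho = abs(res$rho), p_value = res$p_value,
              n = res$n))
    res
  })

  manifest <- stage("report", {
    emit(function(x, p) {
      con <- file(p, "wb"); on.exit(close(con))
      writeLines(x, con)
    }, "report.txt", format_population_summary(summaries, config$r2_one_style))
    files <- sort(list.files(config$out_dir, full.names = TRUE))
    files <- files[!basename(files) %in% c("manifest.json", "config_resolved.json")]
    man <- list(
      package = "lcepop",
      version = as.character(packageVersion("lcepop")),
      seed = config$seed,
      parameter_hash = config_fingerprint(config),
      files = lapply(files, function(f)
        list(name = basename(f), md5 = unname(md5sum(f)))))
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA),
         "config_resolved.json", config_as_list(config))
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA),
         "manifest.json", man)
    man
  })

  invisible(list(genotypes = sim$genotypes, probes = sim$probes,
                 truth = sim$truth, consensus = calls, summaries = summaries,
                 ld = ld, correlation = correlation, manifest = manifest))
}

config_as_list <- function(config) {
  list(seed = config$seed, out_dir = config$out_dir,
       populations = lapply(config$populations, function(p)
         list(name = p$name, n = p$n_individuals,
              haplotype_freqs = unname(p$haplotype_freqs))),
       reference = list(name = config$reference$name,
                        n = config$reference$n_individuals,
                        haplotype_freqs = unname(config$reference$haplotype_freqs)),
       sim_params = unclass(config$sim_params),
       detect_params = unclass(config$detect_params),
       r2_one_style = config$r2_one_style)
}
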