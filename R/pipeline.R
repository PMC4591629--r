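#' Pipeline run configuration
#'
#' All thresholds of the workflow at their standard defaults (biallelic
#' control-ratio bounds 0.3-0.7, site deviation 0.15, ChIP depth fold 2,
#' minimum allelic reads 4 for RNA / 5 for ChIP, FPKM gate 5, total
#' silencing band 30-60 %, 10 kb metaprofile flanks), plus generator
#' settings and the single seed every stage draws from. Round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param seed Integer master seed.
#' @param stages Stages to run, in order, among `"simulate"`, `"allelic"`,
#'   `"stats"`, `"chip"`, `"hic"`.
#' @param simulation Named list of [sim_params()] arguments (the seed is
#'   injected from `seed`).
#' @param mode Allelic mode, `"rna"` or `"chip"`.
#' @param thresholds Named list overriding individual threshold defaults.
#' @return A `run_config` object (named list).
#' @examples
#' cfg <- run_config(seed = 7, simulation = list(n_genes = 20))
#' cfg$thresholds$deviation
#' @export
run_config <- function(seed = 1L, stages = c("simulate", "allelic", "stats",
                                             "chip", "hic"),
                       simulation = list(), mode = "rna",
                       thresholds = list()) {
  def <- list(
    biallelic_low = 0.3, biallelic_high = 0.7,
    deviation = 0.15, fold = 2,
    min_reads_rna = 4, min_reads_chip = 5,
    fpkm_min = 5, band_low = 30, band_high = 60,
    allelic_threshold = 30, max_dist = 30e6,
    chip_window_size = 2e5, flank = 1e4,
    n_body_bins = 20, n_flank_bins = 5,
    n_bins = 5, n_perm = 10000
  )
  thr <- utils::modifyList(def, thresholds)
  structure(
    list(seed = as.integer(seed), stages = stages,
         simulation = simulation, mode = mode, thresholds = thr),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; the writer returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- x$simulation %||% list()
  if (!is.null(sim$resistant_domains)) {
    sim$resistant_domains <- lapply(sim$resistant_domains, unlist)
  }
  run_config(seed = x$seed %||% 1L,
             stages = unlist(x$stages),
             simulation = sim,
             mode = x$mode %||% "rna",
             thresholds = x$thresholds %||% list())
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Chains simulate, allelic, stats, chip, and hic stages on one
#' configuration, writing standard text outputs into `out_dir` and
#' returning a structured run report. Every stage draws all randomness from
#' the single config seed, so a rerun with the same config is identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file writing.
#' @return A `cisspread_report` list: `seed`, `thresholds`, per-stage record
#'   counts and key statistics, and the allelic attrition table. The
#'   generated data and results are attached in `$data`.
#' @examples
#' rep <- run_pipeline(run_config(seed = 1,
#'                                simulation = list(n_genes = 15),
#'                                stages = c("simulate", "allelic")))
#' rep$stages$allelic$n_regions
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  thr <- config$thresholds
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out_path <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)
  report <- list(seed = config$seed, mode = config$mode, thresholds = thr,
                 stages = list())
  data <- list()

  sim_args <- config$simulation
  sim_args$seed <- config$seed
  params <- do.call(sim_params, sim_args)
  data$params <- params

  if ("simulate" %in% config$stages) {
    data$genes <- simulate_genes(params)
    data$counts <- simulate_allelic_counts(data$genes, params)
    data$expression <- simulate_expression(data$genes, params)
    data$chip <- simulate_chip_windows(params, thr$chip_window_size,
                                       genes = data$genes)
    if (!is.null(out_dir)) {
      write_bed(genes_to_regions(data$genes) |>
                  mutate(strand = data$genes$strand),
                out_path("genes.bed"))
      write_variant_table(data$counts, out_path("variants.tsv"))
      readr::write_tsv(data$genes |> select(-"variant_pos"),
                       out_path("ground_truth.tsv"))
      readr::write_tsv(data$expression, out_path("expression.tsv"))
      me3 <- data$chip |> filter(.data$mark == "H3K27me3")
      write_bedgraph(me3, out_path("k27me3_ctrl.bedGraph"),
                     value_col = "ctrl")
      write_bedgraph(me3, out_path("k27me3_exp.bedGraph"),
                     value_col = "exp")
    }
    report$stages$simulate <- list(
      n_genes = nrow(data$genes),
      n_variants = nrow(data$counts),
      n_chip_windows = sum(data$chip$mark == "H3K27me3")
    )
  }

  if ("allelic" %in% config$stages) {
    min_reads <- if (config$mode == "rna") thr$min_reads_rna else thr$min_reads_chip
    data$allelic <- summarize_allelic(
      data$counts, genes_to_regions(data$genes), mode = config$mode,
      biallelic_low = thr$biallelic_low, biallelic_high = thr$biallelic_high,
      deviation = thr$deviation, fold = thr$fold, min_reads = min_reads)
    attrition <- attr(data$allelic, "attrition")
    if (!is.null(out_dir)) {
      readr::write_tsv(as_tibble(data$allelic), out_path("allelic_summary.tsv"))
      readr::write_tsv(attr(data$allelic, "audit"), out_path("allelic_audit.tsv"))
    }
    report$stages$allelic <- list(
      n_regions = nrow(data$allelic),
      n_pass_gate = sum(data$allelic$min_reads_pass),
      attrition = as.data.frame(attrition)
    )
  }

  if ("stats" %in% config$stages) {
    data$calls <- call_silencing(
      data$expression, allelic = data$allelic,
      fpkm_min = thr$fpkm_min, band_low = thr$band_low,
      band_high = thr$band_high, allelic_threshold = thr$allelic_threshold)
    data$proportion_test <- proportion_vs_genome(
      data$calls, call = "in_band", max_dist = thr$max_dist)
    data$decay_test <- distance_decay_test(
      data$calls, call = "allelic_silenced", n_bins = thr$n_bins,
      n_perm = thr$n_perm, seed = config$seed + 10L)
    if (!is.null(out_dir)) {
      readr::write_tsv(data$calls, out_path("silencing_calls.tsv"))
      jsonlite::write_json(
        list(proportion_vs_genome = as.list(tidy(data$proportion_test)),
             distance_decay = as.list(tidy(data$decay_test))),
        out_path("stats_report.json"), auto_unbox = TRUE, digits = NA)
    }
    report$stages$stats <- list(
      n_calls = nrow(data$calls),
      proportion_p = data$proportion_test$p_value,
      decay_p = data$decay_test$p_value
    )
  }

  if ("chip" %in% config$stages) {
    me3 <- data$chip |> filter(.data$mark == "H3K27me3")
    arms <- tibble(
      arm = c("p", "q"),
      start = c(0, params$centromere_pos),
      end = c(params$centromere_pos, params$chrom_length))
    data$arm_summary <- arm_change_summary(
      me3$ctrl, me3$exp, windows = me3[, c("start", "end")], arms = arms)
    on_arm <- me3$on_arm
    data$gain_correlation <- baseline_gain_correlation(
      me3$ctrl[on_arm], (me3$exp - me3$ctrl)[on_arm])
    if (!is.null(out_dir)) {
      readr::write_tsv(data$arm_summary, out_path("arm_summary.tsv"))
      write_bedgraph(me3 |> mutate(delta = .data$exp - .data$ctrl),
                     out_path("k27me3_delta.bedGraph"), value_col = "delta")
    }
    report$stages$chip <- list(
      arm_summary = as.data.frame(data$arm_summary[, 1:5]),
      baseline_gain_rho = data$gain_correlation$statistic
    )
  }

  if ("hic" %in% config$stages) {
    data$hic <- simulate_hic(params)
    data$hic_1mb <- rebin_contacts(data$hic, 1e6)
    data$anchor <- anchor_profile(data$hic_1mb, params$integration_pos)
    if (!is.null(out_dir)) {
      readr::write_tsv(as_tibble(data$anchor), out_path("anchor_profile.tsv"))
      write_bedgraph(as_tibble(data$anchor) |>
                       mutate(chrom = params$chrom),
                     out_path("anchor_profile.bedGraph"),
                     value_col = "contacts")
    }
    report$stages$hic <- list(
      n_bins_input = data$hic$n_bins,
      n_bins_1mb = data$hic_1mb$n_bins,
      anchor_bin = attr(data$anchor, "anchor_bin"),
      mass = sum(data$hic_1mb$matrix)
    )
  }

  report$data <- data
  if (!is.null(out_dir)) {
    slim <- report[c("seed", "mode", "thresholds", "stages")]
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(report) <- "cisspread_report"
  report
}

#' @export
print.cisspread_report <- function(x, ...) {
  cat(sprintf("<cisspread_report> seed %d, mode %s\n", x$seed, x$mode))
  for (st in names(x$stages)) {
    cat(sprintf("  %-9s %s\n", st,
                paste(names(x$stages[[st]])[1:min(3, length(x$stages[[st]]))],
                      collapse = ", ")))
  }
  invisible(x)
}
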