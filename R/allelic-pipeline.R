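#' Full allele-specific silencing workflow over regions of interest
#'
#' Runs the complete per-region workflow on a variant count table:
#' zero-total exclusion, biallelic control-ratio filter, (ChIP mode) depth
#' screen, experimental-condition phasing, region aggregation with one-pass
#' outlier removal, minimum allelic-read gate, and percent allelic
#' silencing. A variant overlapped by several regions contributes to each.
#'
#' Stage order per region: sites with zero total reads in either condition
#' are excluded first; the biallelic filter then the (ChIP-only) 2-fold
#' depth screen follow; surviving sites are phased and aggregated.
#'
#' @param sites Variant count tibble with `chrom`, `pos` (1-based),
#'   `allele_a`, `allele_b`, `ctrl_a`, `ctrl_b`, `exp_a`, `exp_b` (e.g. from
#'   [simulate_allelic_counts()] or [read_variant_table()]).
#' @param regions Region tibble with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open); extra columns such as `distance_to_integration`
#'   are carried through to the output.
#' @param mode `"rna"` (genes; min 4 allelic reads) or `"chip"` (regions of
#'   interest; adds the depth screen; min 5 allelic reads).
#' @param biallelic_low,biallelic_high Inclusive control-ratio bounds.
#' @param deviation Site-vs-region ratio deviation bound.
#' @param fold ChIP depth-screen fold bound.
#' @param min_reads Override of the mode's minimum pooled allelic reads.
#' @param pooling,deviation_scope Passed to [aggregate_region()].
#' @return A tibble with one row per region: all [aggregate_region()]
#'   columns plus `min_reads_pass` and updated `qc_flags`
#'   (`failed_min_reads`, `all_sites_removed`, `no_sites`). Attributes:
#'   `audit` — a per-site tibble recording for every (region, site) pair the
#'   stage at which the site was removed (`"retained"` if never); and
#'   `attrition` — per-stage in/out/rejected counts.
#' @examples
#' p <- sim_params(n_genes = 10, seed = 1)
#' d <- simulate_dataset(p)
#' res <- summarize_allelic(d$counts, genes_to_regions(d$genes))
#' res
#' @export
summarize_allelic <- function(sites, regions,
                              mode = c("rna", "chip"),
                              biallelic_low = 0.3, biallelic_high = 0.7,
                              deviation = 0.15, fold = 2,
                              min_reads = NULL,
                              pooling = c("read_weighted", "mean"),
                              deviation_scope = c("both", "experimental",
                                                  "control")) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  deviation_scope <- match.arg(deviation_scope)
  stopifnot(all(c("chrom", "pos", "ctrl_a", "ctrl_b", "exp_a", "exp_b")
                %in% names(sites)))
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))

  audit <- vector("list", nrow(regions))
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    in_region <- sites$chrom == rg$chrom &
      sites$pos - 1 >= rg$start & sites$pos - 1 < rg$end
    rs <- sites[in_region, , drop = FALSE]
    stage <- rep("retained", nrow(rs))

    nz <- (rs$ctrl_a + rs$ctrl_b) > 0 & (rs$exp_a + rs$exp_b) > 0
    stage[!nz] <- "zero_total"
    cur <- rs[nz, , drop = FALSE]

    if (nrow(cur) > 0) {
      r <- allelic_ratio(cur$ctrl_a, cur$ctrl_b)
      ok <- r >= biallelic_low & r <= biallelic_high
      stage[stage == "retained"][!ok] <- "biallelic"
      cur <- cur[ok, , drop = FALSE]
    }
    if (mode == "chip" && nrow(cur) > 0) {
      cur$.row <- seq_len(nrow(cur))
      kept <- filter_chip_depth(cur, fold = fold)
      ok <- cur$.row %in% kept$.row
      stage[stage == "retained"][!ok] <- "chip_depth"
      cur <- kept
      cur$.row <- NULL
    }
    if (nrow(cur) > 0) {
      cur <- phase_to_cis(cur)
      sc <- silenced_counts(cur)
      ctrl_overall <- pool_ratio(sc$ctrl_sil, sc$ctrl_tot, pooling)
      exp_overall <- pool_ratio(sc$exp_sil, sc$exp_tot, pooling)
      dev_ctrl <- abs(sc$ctrl_sil / sc$ctrl_tot - ctrl_overall)
      dev_exp <- abs(sc$exp_sil / sc$exp_tot - exp_overall)
      keep <- switch(deviation_scope,
        both = dev_ctrl <= deviation & dev_exp <= deviation,
        experimental = dev_exp <= deviation,
        control = dev_ctrl <= deviation
      )
      stage[stage == "retained"][!keep] <- "deviation"
      summ <- aggregate_region(cur, rg$region_id, deviation = deviation,
                               pooling = pooling,
                               deviation_scope = deviation_scope)
    } else {
      summ <- aggregate_region(cur[0, ], rg$region_id)
      summ$qc_flags <- if (nrow(rs) == 0) "no_sites" else "all_sites_removed"
      summ$n_sites_initial <- nrow(rs)
    }
    # n_sites_initial counts sites mapped to the region, before any filter
    summ$n_sites_initial <- as.integer(nrow(rs))
    rows[[i]] <- summ
    audit[[i]] <- tibble(region_id = rg$region_id, chrom = rs$chrom,
                         pos = rs$pos, stage_removed = stage)
  }
  out <- bind_rows(rows)
  out$min_reads_pass <- !is.na(out$ctrl_allelic_ratio) &
    min_read_gate(out, mode = mode, min_reads = min_reads)
  out$qc_flags <- ifelse(
    !out$min_reads_pass & !grepl("sites", out$qc_flags),
    paste_flags(out$qc_flags, "failed_min_reads"), out$qc_flags)

  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  out <- left_join(regions[, extra, drop = FALSE], out, by = "region_id")

  audit <- bind_rows(audit)
  attr(out, "audit") <- audit
  attr(out, "attrition") <- audit |>
    dplyr::count(.data$stage_removed, name = "n_sites")
  class(out) <- c("allelic_summary", class(out))
  out
}

paste_flags <- function(existing, flag) {
  ifelse(existing == "", flag, paste(existing, flag, sep = ";"))
}

#' Convert simulated genes to the region table the workflow expects
#'
#' @param genes Tibble from [simulate_genes()].
#' @return Region tibble with `region_id`, `chrom`, `start`, `end`,
#'   `distance_to_integration` (when present).
#' @export
genes_to_regions <- function(genes) {
  out <- tibble(
    region_id = genes$gene_id,
    chrom = genes$chrom,
    start = genes$start,
    end = genes$end
  )
  if ("distance_to_integration" %in% names(genes)) {
    out$distance_to_integration <- genes$distance_to_integration
  }
  if ("true_silencing" %in% names(genes)) {
    out$true_silencing <- genes$true_silencing
  }
  out
}
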