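#' Allelic ratio of two read counts
#'
#' The fraction of reads supporting the first allele,
#' `count_x / (count_x + count_y)`. A site with zero total reads has no
#' defined ratio and must be excluded upstream; it is an error here, never a
#' silent zero.
#'
#' @param count_x,count_y Non-negative read counts (vectorized).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' allelic_ratio(3, 7)
#' @export
allelic_ratio <- function(count_x, count_y) {
  if (any(count_x < 0 | count_y < 0)) abort("read counts must be >= 0.")
  total <- count_x + count_y
  if (any(total == 0)) {
    abort("allelic ratio undefined for sites with zero total reads; exclude them first.")
  }
  count_x / total
}

#' Percent allelic silencing
#'
#' `100 * (control ratio - experimental ratio) / control ratio`, where both
#' ratios are frequencies of the designated silenced allele. Negative values
#' indicate allelic gain.
#'
#' @param ctrl_ratio,exp_ratio Allelic ratios in `[0, 1]` (vectorized).
#' @return Percent silencing (may exceed -100 downwards, capped at 100 above
#'   only by the arithmetic itself).
#' @examples
#' percent_allelic_silencing(0.5, 0.25)
#' @export
percent_allelic_silencing <- function(ctrl_ratio, exp_ratio) {
  if (any(ctrl_ratio == 0)) {
    abort("percent allelic silencing undefined for control ratio 0.")
  }
  100 * (ctrl_ratio - exp_ratio) / ctrl_ratio
}

#' Retain variant sites with a biallelic control ratio
#'
#' Keeps sites whose control-condition allelic ratio (frequency of allele a)
#' lies in `[low, high]`; both bounds inclusive. This is the control-sample
#' heterozygosity screen applied before any phasing.
#'
#' @param sites Tibble with `ctrl_a` and `ctrl_b` count columns.
#' @param low,high Inclusive ratio bounds (defaults 0.3 and 0.7).
#' @return The retained rows, input order preserved.
#' @examples
#' sites <- tibble::tibble(ctrl_a = c(3, 29), ctrl_b = c(7, 71),
#'                         exp_a = 0, exp_b = 0)
#' filter_biallelic(sites)
#' @export
filter_biallelic <- function(sites, low = 0.3, high = 0.7) {
  r <- allelic_ratio(sites$ctrl_a, sites$ctrl_b)
  sites[r >= low & r <= high, , drop = FALSE]
}

#' Designate the cis-silenced allele at each site
#'
#' The allele with fewer reads in the experimental (induced) sample is taken
#' to be silenced in cis with the transgene. Ties are resolved
#' deterministically to allele a and flagged; a tied site has ratio 0.5 in
#' that condition, so pooled estimates are unaffected in expectation.
#'
#' @param sites Tibble with `exp_a` and `exp_b` count columns.
#' @return `sites` with `silenced_allele` ("a"/"b") and logical `phase_tie`
#'   columns appended.
#' @examples
#' phase_to_cis(tibble::tibble(exp_a = c(2, 10), exp_b = c(18, 10)))
#' @export
phase_to_cis <- function(sites) {
  sites |>
    mutate(
      silenced_allele = ifelse(.data$exp_b < .data$exp_a, "b", "a"),
      phase_tie = .data$exp_a == .data$exp_b
    )
}

silenced_counts <- function(sites) {
  a <- sites$silenced_allele == "a"
  tibble(
    ctrl_sil = ifelse(a, sites$ctrl_a, sites$ctrl_b),
    ctrl_tot = sites$ctrl_a + sites$ctrl_b,
    exp_sil = ifelse(a, sites$exp_a, sites$exp_b),
    exp_tot = sites$exp_a + sites$exp_b
  )
}

pool_ratio <- function(sil, tot, pooling) {
  if (pooling == "read_weighted") sum(sil) / sum(tot) else mean(sil / tot)
}

#' Aggregate phased variant sites into a region-level allelic summary
#'
#' Implements the three-step region rule: (i) pool the designated silenced
#' allele across sites per condition to get the overall region ratio
#' (read-weighted by default); (ii) remove sites whose site-level ratio
#' deviates from the overall ratio by more than `deviation` (in either
#' condition under the default scope); (iii) recompute the overall ratio
#' once from the retained sites. The removal is a single pass, not iterated.
#'
#' @param sites Phased tibble (see [phase_to_cis()]) with count columns; all
#'   rows are assumed to belong to the region.
#' @param region_id Identifier recorded in the summary.
#' @param deviation Maximum allowed absolute difference between a site ratio
#'   and the overall region ratio (default 0.15).
#' @param pooling `"read_weighted"` (sum of silenced-allele reads over sum
#'   of all allelic reads) or `"mean"` of site ratios.
#' @param deviation_scope Apply the deviation test in `"both"` conditions
#'   (a site failing in either is removed), or only one.
#' @return One-row tibble: `region_id`, `n_sites_initial`,
#'   `n_sites_retained`, `ctrl_allelic_ratio`, `exp_allelic_ratio`,
#'   `allelic_reads_ctrl`, `allelic_reads_exp`, `percent_allelic_silencing`,
#'   `qc_flags` (semicolon-separated; empty when clean).
#' @examples
#' sites <- phase_to_cis(tibble::tibble(
#'   ctrl_a = c(50, 50, 50), ctrl_b = c(50, 50, 50),
#'   exp_a = c(40, 42, 80), exp_b = c(60, 58, 20)))
#' aggregate_region(sites, "toy")
#' @export
aggregate_region <- function(sites, region_id = "region",
                             deviation = 0.15,
                             pooling = c("read_weighted", "mean"),
                             deviation_scope = c("both", "experimental",
                                                 "control")) {
  pooling <- match.arg(pooling)
  deviation_scope <- match.arg(deviation_scope)
  n0 <- nrow(sites)
  if (n0 == 0) {
    return(allelic_summary_row(region_id, 0L, 0L, NA_real_, NA_real_,
                               0, 0, NA_real_, "all_sites_removed"))
  }
  sc <- silenced_counts(sites)
  ctrl_overall <- pool_ratio(sc$ctrl_sil, sc$ctrl_tot, pooling)
  exp_overall <- pool_ratio(sc$exp_sil, sc$exp_tot, pooling)
  dev_ctrl <- abs(sc$ctrl_sil / sc$ctrl_tot - ctrl_overall)
  dev_exp <- abs(sc$exp_sil / sc$exp_tot - exp_overall)
  keep <- switch(deviation_scope,
    both = dev_ctrl <= deviation & dev_exp <= deviation,
    experimental = dev_exp <= deviation,
    control = dev_ctrl <= deviation
  )
  if (!any(keep)) {
    return(allelic_summary_row(region_id, n0, 0L, NA_real_, NA_real_,
                               0, 0, NA_real_, "all_sites_removed"))
  }
  sck <- sc[keep, , drop = FALSE]
  ctrl_ratio <- pool_ratio(sck$ctrl_sil, sck$ctrl_tot, pooling)
  exp_ratio <- pool_ratio(sck$exp_sil, sck$exp_tot, pooling)
  flags <- character()
  pct <- if (ctrl_ratio == 0) {
    flags <- c(flags, "undefined_percent")
    NA_real_
  } else {
    percent_allelic_silencing(ctrl_ratio, exp_ratio)
  }
  allelic_summary_row(region_id, n0, sum(keep), ctrl_ratio, exp_ratio,
                      sum(sck$ctrl_tot), sum(sck$exp_tot), pct,
                      paste(flags, collapse = ";"))
}

allelic_summary_row <- function(region_id, n0, n1, cr, er, rc, re, pct,
                                flags) {
  tibble(
    region_id = region_id,
    n_sites_initial = as.integer(n0),
    n_sites_retained = as.integer(n1),
    ctrl_allelic_ratio = cr,
    exp_allelic_ratio = er,
    allelic_reads_ctrl = as.numeric(rc),
    allelic_reads_exp = as.numeric(re),
    percent_allelic_silencing = pct,
    qc_flags = flags
  )
}

#' Exclude ChIP variant sites with outlying read depth
#'
#' Single-pass depth screen for ChIP-mode regions: a site's total reads `t`
#' in a condition must satisfy `mean / fold <= t <= mean * fold`, where
#' `mean` is the region's per-site average total in that condition, computed
#' once from all sites (no recompute-and-refilter). A site must pass in both
#' conditions.
#'
#' @param sites Tibble with `ctrl_a`, `ctrl_b`, `exp_a`, `exp_b`; all rows
#'   one region.
#' @param fold Fold-difference bound (default 2).
#' @return The retained rows.
#' @examples
#' s <- tibble::tibble(ctrl_a = c(5, 5, 5, 50), ctrl_b = c(5, 5, 5, 50),
#'                     exp_a = 10, exp_b = 10)
#' filter_chip_depth(s)  # empty: all four fall outside [16.25, 65]
#' @export
filter_chip_depth <- function(sites, fold = 2) {
  if (nrow(sites) == 0) return(sites)
  tc <- sites$ctrl_a + sites$ctrl_b
  te <- sites$exp_a + sites$exp_b
  mc <- mean(tc)
  me <- mean(te)
  keep <- tc >= mc / fold & tc <= mc * fold &
    te >= me / fold & te <= me * fold
  sites[keep, , drop = FALSE]
}

#' Minimum allelic-read gate for a region summary
#'
#' A region is analyzable only with enough allelic information in both
#' conditions: at least 4 pooled allelic reads per gene for RNA-seq, at
#' least 5 per region of interest for ChIP-seq (inclusive bounds).
#'
#' @param summary One or more rows from [aggregate_region()].
#' @param mode `"rna"` or `"chip"`.
#' @param min_reads Override of the mode default.
#' @return Logical vector, `TRUE` where the region passes.
#' @examples
#' min_read_gate(tibble::tibble(allelic_reads_ctrl = 4,
#'                              allelic_reads_exp = 4), "rna")
#' @export
min_read_gate <- function(summary, mode = c("rna", "chip"),
                          min_reads = NULL) {
  mode <- match.arg(mode)
  thr <- min_reads %||% if (mode == "rna") 4 else 5
  summary$allelic_reads_ctrl >= thr & summary$allelic_reads_exp >= thr
}
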