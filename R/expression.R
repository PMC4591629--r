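#' Percent silencing from pyrosequencing allele frequencies
#'
#' `100 * (frequency without induction - frequency after induction) /
#' frequency without induction`; negative values are allelic gain.
#'
#' @param freq_ctrl,freq_exp Allele frequencies in `[0, 1]` (vectorized).
#' @return Percent silencing.
#' @examples
#' pyro_percent_silencing(0.48, 0.24)
#' @export
pyro_percent_silencing <- function(freq_ctrl, freq_exp) {
  if (any(freq_ctrl == 0)) {
    abort("percent silencing undefined for control frequency 0.")
  }
  100 * (freq_ctrl - freq_exp) / freq_ctrl
}

#' Percent reduction in total expression
#'
#' @param fpkm_ctrl,fpkm_exp Expression values (FPKM) per condition.
#' @return Percent reduction, `100 * (ctrl - exp) / ctrl`.
#' @examples
#' total_percent_silencing(10, 6)
#' @export
total_percent_silencing <- function(fpkm_ctrl, fpkm_exp) {
  if (any(fpkm_ctrl == 0)) {
    abort("total percent silencing undefined for control FPKM 0.")
  }
  100 * (fpkm_ctrl - fpkm_exp) / fpkm_ctrl
}

#' Classify a percent reduction into the silencing band
#'
#' Complete silencing of one allele halves total expression, so a stringent
#' 30-60 % total-reduction band (inclusive on both ends) is used to call a
#' gene silencing while excluding larger, likely trans, effects.
#'
#' @param percent Percent total reduction (vectorized).
#' @param low,high Inclusive band bounds (defaults 30 and 60).
#' @return Logical vector.
#' @examples
#' classify_band(c(0, 40, 70))
#' @export
classify_band <- function(percent, low = 30, high = 60) {
  percent >= low & percent <= high
}

#' Gene-level silencing calls from expression and allelic summaries
#'
#' Applies the FPKM gate, computes percent total silencing and its band
#' classification, and (when an allelic summary is joined) flags genes with
#' more than 30 % allelic silencing.
#'
#' @param expression Tibble with `gene_id`, `fpkm_ctrl`, `fpkm_exp` and
#'   optionally `distance_to_integration`.
#' @param allelic Optional [summarize_allelic()] result joined by
#'   `gene_id`/`region_id`.
#' @param fpkm_min Minimum FPKM (default 5) required on `fpkm_gate` scale.
#' @param fpkm_gate Gate on the `"mean"` of conditions (default) or on
#'   `"ctrl"` only.
#' @param band_low,band_high Total-reduction band bounds.
#' @param allelic_threshold Percent allelic silencing above which
#'   `allelic_silenced` is `TRUE` (default 30).
#' @return Tibble of gated genes: `gene_id`, `percent_total_silencing`,
#'   `in_band`, and when allelic data are present
#'   `percent_allelic_silencing` and `allelic_silenced`; other input columns
#'   carried through.
#' @examples
#' expr <- tibble::tibble(gene_id = c("a", "b"), fpkm_ctrl = c(10, 10),
#'                        fpkm_exp = c(6, 10))
#' call_silencing(expr)
#' @export
call_silencing <- function(expression, allelic = NULL,
                           fpkm_min = 5, fpkm_gate = c("mean", "ctrl"),
                           band_low = 30, band_high = 60,
                           allelic_threshold = 30) {
  fpkm_gate <- match.arg(fpkm_gate)
  gate_val <- switch(fpkm_gate,
    mean = (expression$fpkm_ctrl + expression$fpkm_exp) / 2,
    ctrl = expression$fpkm_ctrl
  )
  out <- expression |>
    filter(gate_val >= fpkm_min, .data$fpkm_ctrl > 0) |>
    mutate(
      percent_total_silencing =
        total_percent_silencing(.data$fpkm_ctrl, .data$fpkm_exp),
      in_band = classify_band(.data$percent_total_silencing,
                              band_low, band_high)
    )
  if (!is.null(allelic)) {
    al <- as_tibble(allelic)[, c("region_id", "percent_allelic_silencing")]
    out <- out |>
      left_join(al, by = c(gene_id = "region_id")) |>
      mutate(allelic_silenced =
               !is.na(.data$percent_allelic_silencing) &
               .data$percent_allelic_silencing > allelic_threshold)
  }
  out
}

#' Chi-square test of silencing proportion near the integration site
#'
#' Compares the proportion of silencing calls among genes within `max_dist`
#' of the integration site against the rest of the genome with a 2x2
#' chi-square test (no continuity correction).
#'
#' @param calls Tibble with a logical call column and
#'   `distance_to_integration` (bp, signed or absolute).
#' @param call Name of the logical call column (default `"in_band"`).
#' @param max_dist Distance defining "near" (default 30 Mb).
#' @return A `cisspread_test` object with `statistic`, `p_value`, `table`
#'   (the 2x2 contingency table), and a small-sample `flag` when any
#'   expected cell is below 1. Supports [tidy()] and [glance()].
#' @examples
#' calls <- tibble::tibble(
#'   in_band = rep(c(TRUE, FALSE), c(30, 70)),
#'   distance_to_integration = seq(0, 99e6, length.out = 100))
#' proportion_vs_genome(calls)
#' @export
proportion_vs_genome <- function(calls, call = "in_band", max_dist = 30e6) {
  stopifnot(call %in% names(calls),
            "distance_to_integration" %in% names(calls))
  near <- abs(calls$distance_to_integration) <= max_dist
  if (!any(near) || all(near)) {
    abort("both the near set and the rest of the genome must be non-empty.")
  }
  silenced <- as.logical(calls[[call]])
  tab <- table(
    factor(ifelse(near, "near", "genome"), levels = c("near", "genome")),
    factor(ifelse(silenced, "silenced", "not"),
           levels = c("silenced", "not"))
  )
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  flag <- if (any(ht$expected < 1)) "small_sample" else ""
  new_cisspread_test(
    method = "proportion_vs_genome",
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    df = unname(ht$parameter),
    table = tab,
    flag = flag
  )
}

chisq_bins <- function(silenced_by_bin, n_by_bin, p_overall) {
  exp_s <- n_by_bin * p_overall
  exp_n <- n_by_bin * (1 - p_overall)
  obs_n <- n_by_bin - silenced_by_bin
  sum((silenced_by_bin - exp_s)^2 / exp_s + (obs_n - exp_n)^2 / exp_n)
}

#' Permutation test for distance decay of silencing
#'
#' Tests whether the number of silenced genes decreases with distance from
#' the integration site. Genes are split into `n_bins` equal-count distance
#' bins; the observed statistic is the chi-square of silenced counts across
#' bins (against the pooled proportion), and the null distribution comes
#' from permuting the silenced labels across genes. The empirical p-value
#' uses the +1 correction, `(1 + #{perm >= obs}) / (1 + n_perm)`. A
#' one-sided decreasing-trend statistic (Cochran-Armitage-style score on bin
#' index) is available since the scientific claim is directional.
#'
#' @param calls Tibble with a logical silenced column and
#'   `distance_to_integration`.
#' @param call Name of the logical column (default `"allelic_silenced"`).
#' @param n_bins Number of equal-count distance bins (default 5).
#' @param n_perm Number of label permutations (default 10000).
#' @param statistic `"chisq"` (omnibus) or `"trend"` (one-sided decreasing).
#' @param seed Optional seed for the permutations.
#' @return A `cisspread_test` with `statistic`, `p_value`, `bins` (per-bin
#'   gene and silenced counts), `n_perm`, and `flag` (`"degenerate"` when
#'   all or no genes are silenced, with p = 1). Supports [tidy()]/[glance()]
#'   and [autoplot()].
#' @examples
#' calls <- tibble::tibble(
#'   allelic_silenced = rep(c(TRUE, FALSE), c(10, 40)),
#'   distance_to_integration = c(seq_len(10) * 1e5, seq_len(40) * 1e6))
#' distance_decay_test(calls, n_perm = 200, seed = 1)
#' @export
distance_decay_test <- function(calls, call = "allelic_silenced",
                                n_bins = 5, n_perm = 10000,
                                statistic = c("chisq", "trend"),
                                seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(call %in% names(calls),
            "distance_to_integration" %in% names(calls))
  silenced <- as.logical(calls[[call]])
  d <- abs(calls$distance_to_integration)
  n <- length(d)
  if (n_bins < 2 || n < n_bins) abort("need >= 2 bins with >= 1 gene each.")
  # equal-count bins by distance rank; ties broken by order
  bin <- ceiling(rank(d, ties.method = "first") / (n / n_bins))
  bin <- factor(pmin(bin, n_bins), levels = seq_len(n_bins))
  n_by_bin <- as.vector(table(bin))
  obs_by_bin <- as.vector(tapply(silenced, bin, sum, default = 0))
  bins <- tibble(bin = seq_len(n_bins), n_genes = n_by_bin,
                 n_silenced = obs_by_bin)
  if (all(silenced) || !any(silenced)) {
    return(new_cisspread_test(
      method = paste0("distance_decay_", statistic),
      statistic = 0, p_value = 1, bins = bins, n_perm = n_perm,
      flag = "degenerate"))
  }
  p_overall <- mean(silenced)
  stat_fun <- if (statistic == "chisq") {
    function(s_by_bin) chisq_bins(s_by_bin, n_by_bin, p_overall)
  } else {
    # decreasing trend: more silenced in near bins gives a larger score
    function(s_by_bin) -sum(seq_len(n_bins) * s_by_bin)
  }
  obs <- stat_fun(obs_by_bin)
  run_perm <- function() {
    # indicator matrix (bins x genes) times permuted label matrix
    B <- vapply(seq_len(n_bins), function(b) as.numeric(bin == levels(bin)[b]),
                numeric(n))
    L <- vapply(seq_len(n_perm), function(i) as.numeric(sample(silenced)),
                numeric(n))
    counts <- t(B) %*% L  # n_bins x n_perm silenced counts
    apply(counts, 2, stat_fun)
  }
  perm <- if (is.null(seed)) run_perm() else with_seed(seed, run_perm())
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  new_cisspread_test(
    method = paste0("distance_decay_", statistic),
    statistic = obs, p_value = p, bins = bins, n_perm = n_perm,
    null_distribution = perm, flag = ""
  )
}

#' Correlation with two-sided test and missing-value handling
#'
#' Thin, pairwise-complete wrapper around [stats::cor.test()] returning a
#' tidy-able result; constant input is flagged rather than an error.
#'
#' @param x,y Equal-length numeric vectors (length >= 3 after removing
#'   incomplete pairs).
#' @param method `"spearman"` or `"pearson"`.
#' @return A `cisspread_test` with `statistic` (rho or r), `p_value`, `n`,
#'   and `flag` (`"constant_input"` with `NA` estimate when either vector is
#'   constant).
#' @examples
#' correlate(1:5, c(2, 1, 4, 3, 5))
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(new_cisspread_test(method = paste0("correlate_", method),
                              statistic = NA_real_, p_value = NA_real_,
                              n = length(x), flag = "constant_input"))
  }
  ht <- suppressWarnings(cor.test(x, y, method = method))
  new_cisspread_test(method = paste0("correlate_", method),
                     statistic = unname(ht$estimate),
                     p_value = unname(ht$p.value),
                     n = length(x), flag = "")
}
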