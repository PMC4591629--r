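#' Quantify coverage in fixed-size non-overlapping windows
#'
#' Sums base-level counts into non-overlapping windows tiling the
#' chromosome (partial terminal window kept), then optionally normalizes to
#' counts per million. Coverage is supplied as bedGraph-style intervals
#' whose score is the per-base count; an interval contributes
#' `score * overlap` to each window it overlaps.
#'
#' @param coverage Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `score`.
#' @param window_size Window size in bp (2 kb and 1 Mb are the standard
#'   choices).
#' @param chrom_length Chromosome length; defaults to the last covered base.
#' @param normalize `"cpm"` (counts per million, default) or `"none"`.
#' @return Tibble with `chrom`, `start`, `end`, `window`, `count` (raw sum)
#'   and `value` (normalized signal; equals `count` under `"none"`).
#' @examples
#' cov <- tibble::tibble(chrom = "c", start = 0, end = 10000, score = 1)
#' quantify_windows(cov, 2000, normalize = "none")
#' @export
quantify_windows <- function(coverage, window_size, chrom_length = NULL,
                             normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  if (window_size <= 0) abort("`window_size` must be positive.")
  if (any(coverage$score < 0)) abort("coverage must be non-negative.")
  chrom_length <- chrom_length %||% max(coverage$end)
  n_win <- as.integer(ceiling(chrom_length / window_size))
  acc <- numeric(n_win)
  for (k in seq_len(nrow(coverage))) {
    s <- coverage$start[k]
    e <- min(coverage$end[k], chrom_length)
    if (e <= s) next
    w1 <- floor(s / window_size) + 1
    w2 <- floor((e - 1) / window_size) + 1
    for (w in w1:w2) {
      lo <- max(s, (w - 1) * window_size)
      hi <- min(e, w * window_size)
      acc[w] <- acc[w] + coverage$score[k] * (hi - lo)
    }
  }
  start <- (seq_len(n_win) - 1) * window_size
  value <- if (normalize == "cpm" && sum(acc) > 0) {
    acc / sum(acc) * 1e6
  } else {
    acc
  }
  tibble(
    chrom = coverage$chrom[1] %||% NA_character_,
    start = start,
    end = pmin(start + window_size, chrom_length),
    window = seq_len(n_win),
    count = acc,
    value = value
  )
}

#' Per-chromosome and per-arm change summary with paired t-test
#'
#' Computes per-window signal changes (experimental minus control) and
#' tests them with a paired t-test, for the whole chromosome and for each
#' supplied arm. Windows are assigned to the arm containing their midpoint.
#'
#' @param ctrl,exp Numeric per-window signal vectors on the same windows.
#' @param windows Tibble with `start`, `end` for each window (same order);
#'   required when `arms` is given.
#' @param arms Optional tibble with `arm`, `start`, `end` defining arm
#'   intervals (derive from a centromere position).
#' @return Tibble with one row per scope: `scope`, `n_windows`,
#'   `mean_delta`, `t_stat`, `p_value`, `flag` (`"too_few_windows"` when the
#'   test cannot run).
#' @examples
#' arm_change_summary(c(1, 1, 1, 1, 1), c(2, 2.1, 1.9, 2, 2.2))
#' @export
arm_change_summary <- function(ctrl, exp, windows = NULL, arms = NULL) {
  if (length(ctrl) != length(exp)) {
    abort("`ctrl` and `exp` must cover the same windows.")
  }
  one_scope <- function(scope, idx) {
    d <- exp[idx] - ctrl[idx]
    if (length(d) < 2 || sd(d) == 0) {
      return(tibble(scope = scope, n_windows = length(d),
                    mean_delta = mean(d), t_stat = NA_real_,
                    p_value = if (length(d) >= 2 && sd(d) == 0 &&
                                  mean(d) == 0) 1 else NA_real_,
                    flag = if (length(d) < 2) "too_few_windows"
                           else "constant_delta"))
    }
    ht <- t.test(exp[idx], ctrl[idx], paired = TRUE)
    tibble(scope = scope, n_windows = length(d), mean_delta = mean(d),
           t_stat = unname(ht$statistic), p_value = ht$p.value, flag = "")
  }
  out <- one_scope("chromosome", seq_along(ctrl))
  if (!is.null(arms)) {
    if (is.null(windows)) abort("`windows` is required with `arms`.")
    mid <- (windows$start + windows$end) / 2
    for (i in seq_len(nrow(arms))) {
      idx <- which(mid >= arms$start[i] & mid < arms$end[i])
      out <- bind_rows(out, one_scope(arms$arm[i], idx))
    }
  }
  out
}

interval_mean <- function(tr_start, tr_end, val, from, to) {
  if (to <= from) return(NA_real_)
  ov <- pmax(0, pmin(tr_end, to) - pmax(tr_start, from))
  sum(val * ov) / (to - from)
}

#' Average signal profile across gene bodies and flanks
#'
#' Scales every gene body to `n_body_bins` equal-width bins, adds
#' `n_flank_bins` fixed-width bins over `flank` bp upstream and downstream,
#' orients bins 5' to 3' using the gene strand, and averages across genes.
#' Signal is read from a window track as a per-base density (window value /
#' window width). Genes shorter than `n_body_bins` bases are skipped and
#' recorded in the `skipped` attribute.
#'
#' @param track Tibble with `start`, `end` and one or more signal columns.
#' @param genes Tibble with `start`, `end`, `strand` (BED6 conventions).
#' @param values Names of the signal columns to profile (default: every
#'   numeric column except coordinates).
#' @param flank Flank size in bp (default 10 kb).
#' @param n_body_bins,n_flank_bins Bin counts for body and each flank.
#' @return A `meta_profile` tibble: `bin`, `segment`
#'   (upstream/body/downstream) and one averaged column per signal.
#'   Attribute `n_genes` counts genes used. Supports [autoplot()].
#' @examples
#' track <- tibble::tibble(start = seq(0, 48000, 2000),
#'                         end = seq(2000, 50000, 2000), score = 1)
#' genes <- tibble::tibble(start = 20000, end = 30000, strand = "+")
#' gene_metaprofile(track, genes, values = "score")
#' @export
gene_metaprofile <- function(track, genes, values = NULL,
                             flank = 1e4, n_body_bins = 20,
                             n_flank_bins = 5) {
  values <- values %||%
    setdiff(names(track)[vapply(track, is.numeric, logical(1))],
            c("start", "end", "window"))
  if (length(values) == 0) abort("no signal columns found in `track`.")
  width <- track$end - track$start
  dens <- lapply(values, function(v) track[[v]] / width)
  names(dens) <- values

  n_total <- 2 * n_flank_bins + n_body_bins
  sums <- matrix(0, n_total, length(values),
                 dimnames = list(NULL, values))
  used <- 0L
  skipped <- integer()
  for (g in seq_len(nrow(genes))) {
    gs <- genes$start[g]
    ge <- genes$end[g]
    if (ge - gs < n_body_bins) {
      skipped <- c(skipped, g)
      next
    }
    flank_w <- flank / n_flank_bins
    up <- cbind(gs - flank + (seq_len(n_flank_bins) - 1) * flank_w,
                gs - flank + seq_len(n_flank_bins) * flank_w)
    body_w <- (ge - gs) / n_body_bins
    body <- cbind(gs + (seq_len(n_body_bins) - 1) * body_w,
                  gs + seq_len(n_body_bins) * body_w)
    down <- cbind(ge + (seq_len(n_flank_bins) - 1) * flank_w,
                  ge + seq_len(n_flank_bins) * flank_w)
    bounds <- rbind(up, body, down)
    if (identical(genes$strand[g], "-")) bounds <- bounds[rev(seq_len(n_total)), , drop = FALSE]
    for (v in values) {
      bin_vals <- vapply(seq_len(n_total), function(b) {
        interval_mean(track$start, track$end, dens[[v]],
                      bounds[b, 1], bounds[b, 2])
      }, numeric(1))
      sums[, v] <- sums[, v] + bin_vals
    }
    used <- used + 1L
  }
  if (used == 0) abort("no gene long enough to profile.")
  out <- tibble(
    bin = seq_len(n_total),
    segment = rep(c("upstream", "body", "downstream"),
                  c(n_flank_bins, n_body_bins, n_flank_bins))
  )
  for (v in values) out[[v]] <- sums[, v] / used
  attr(out, "n_genes") <- used
  attr(out, "skipped") <- skipped
  class(out) <- c("meta_profile", class(out))
  out
}

#' Correlation between pre-existing signal and its induced gain
#'
#' The signature observation for H3K27me3 recruitment: the gain upon XIST
#' induction mirrors the pre-existing level. Delegates to [correlate()]
#' (Spearman by default) over matched windows.
#'
#' @param ctrl Per-window baseline (control) signal.
#' @param delta Per-window gain (experimental minus control).
#' @param method Correlation method, `"spearman"` default.
#' @return A `cisspread_test` (see [correlate()]).
#' @examples
#' baseline_gain_correlation(1:10, (1:10) * 2)
#' @export
baseline_gain_correlation <- function(ctrl, delta, method = "spearman") {
  if (length(ctrl) != length(delta)) abort("windows must match.")
  correlate(ctrl, delta, method = method)
}
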