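# Independent brute-force oracles, written as plain loops against the
# stated rules; deliberately kept free of any package internals.

# Full region workflow: zero-total exclusion -> biallelic control-ratio
# filter -> (chip) single-pass 2-fold depth screen -> lower-experimental-
# read phasing -> read-weighted pooling -> one-pass 0.15 deviation removal
# -> recompute -> min-read gate -> percent silencing.
oracle_region_summary <- function(df, mode = "rna",
                                  low = 0.3, high = 0.7, dev = 0.15,
                                  fold = 2) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$ctrl_a[i] + df$ctrl_b[i] == 0 || df$exp_a[i] + df$exp_b[i] == 0) {
      keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df$ctrl_a[i] / (df$ctrl_a[i] + df$ctrl_b[i])
    if (r < low || r > high) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  if (mode == "chip" && nrow(df) > 0) {
    tc <- df$ctrl_a + df$ctrl_b
    te <- df$exp_a + df$exp_b
    mc <- mean(tc)
    me <- mean(te)
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (tc[i] < mc / fold || tc[i] > mc * fold ||
          te[i] < me / fold || te[i] > me * fold) keep[i] <- FALSE
    }
    df <- df[keep, , drop = FALSE]
  }
  empty <- list(n_retained = 0L, ctrl_ratio = NA_real_, exp_ratio = NA_real_,
                reads_ctrl = 0, reads_exp = 0, percent = NA_real_)
  if (nrow(df) == 0) return(empty)
  sil_c <- sil_e <- tot_c <- tot_e <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    sil <- if (df$exp_b[i] < df$exp_a[i]) "b" else "a"
    sil_c[i] <- if (sil == "a") df$ctrl_a[i] else df$ctrl_b[i]
    sil_e[i] <- if (sil == "a") df$exp_a[i] else df$exp_b[i]
    tot_c[i] <- df$ctrl_a[i] + df$ctrl_b[i]
    tot_e[i] <- df$exp_a[i] + df$exp_b[i]
  }
  oc <- sum(sil_c) / sum(tot_c)
  oe <- sum(sil_e) / sum(tot_e)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (abs(sil_c[i] / tot_c[i] - oc) > dev ||
        abs(sil_e[i] / tot_e[i] - oe) > dev) keep[i] <- FALSE
  }
  if (!any(keep)) return(empty)
  oc2 <- sum(sil_c[keep]) / sum(tot_c[keep])
  oe2 <- sum(sil_e[keep]) / sum(tot_e[keep])
  list(n_retained = sum(keep), ctrl_ratio = oc2, exp_ratio = oe2,
       reads_ctrl = sum(tot_c[keep]), reads_exp = sum(tot_e[keep]),
       percent = if (oc2 == 0) NA_real_ else 100 * (oc2 - oe2) / oc2)
}

# Random variant tables spanning many regions, with occasional zero-depth
# sites and ties.
random_region_tables <- function(n_regions, max_sites = 8, seed = 1) {
  set.seed(seed)
  regions <- tibble::tibble(
    region_id = sprintf("r%04d", seq_len(n_regions)),
    chrom = "chrT",
    start = (seq_len(n_regions) - 1) * 1e4,
    end = (seq_len(n_regions) - 1) * 1e4 + 9000
  )
  sites <- do.call(rbind, lapply(seq_len(n_regions), function(i) {
    k <- sample(1:max_sites, 1)
    data.frame(
      chrom = "chrT",
      pos = regions$start[i] + sort(sample.int(8999, k)),
      allele_a = "A", allele_b = "G",
      ctrl_a = rpois(k, 12), ctrl_b = rpois(k, 12),
      exp_a = rpois(k, 9), exp_b = rpois(k, 9)
    )
  }))
  # sprinkle zero-depth sites and exact ties
  z <- sample(nrow(sites), max(1, nrow(sites) %/% 50))
  sites$ctrl_a[z] <- 0
  sites$ctrl_b[z] <- 0
  t2 <- sample(nrow(sites), max(1, nrow(sites) %/% 30))
  sites$exp_b[t2] <- sites$exp_a[t2]
  list(sites = tibble::as_tibble(sites), regions = regions)
}

# Exact permutation p for the decay test by enumerating silenced subsets
# (label arrangements of a binary vector reduce to subsets of fixed size).
oracle_exact_decay_p <- function(silenced, dist, n_bins = 2) {
  n <- length(silenced)
  k <- sum(silenced)
  bin <- ceiling(rank(dist, ties.method = "first") / (n / n_bins))
  bin <- pmin(bin, n_bins)
  n_by_bin <- tabulate(bin, n_bins)
  p_overall <- k / n
  stat <- function(lab) {
    s_by_bin <- tapply(lab, factor(bin, levels = seq_len(n_bins)), sum,
                       default = 0)
    es <- n_by_bin * p_overall
    en <- n_by_bin * (1 - p_overall)
    sum((s_by_bin - es)^2 / es + ((n_by_bin - s_by_bin) - en)^2 / en)
  }
  obs <- stat(silenced)
  subsets <- utils::combn(n, k)
  stats <- apply(subsets, 2, function(idx) {
    lab <- rep(FALSE, n)
    lab[idx] <- TRUE
    stat(lab)
  })
  mean(stats >= obs - 1e-12)
}

# Brute-force per-base window summation.
oracle_window_counts <- function(per_base, window_size) {
  n_win <- ceiling(length(per_base) / window_size)
  out <- numeric(n_win)
  for (b in seq_along(per_base)) {
    w <- floor((b - 1) / window_size) + 1
    out[w] <- out[w] + per_base[b]
  }
  out
}

# Brute-force block sum for contact-matrix rebinning.
oracle_rebin <- function(m, old_size, new_size) {
  fac <- new_size / old_size
  n_new <- ceiling(nrow(m) / fac)
  out <- matrix(0, n_new, n_new)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[floor((i - 1) / fac) + 1, floor((j - 1) / fac) + 1] <-
        out[floor((i - 1) / fac) + 1, floor((j - 1) / fac) + 1] + m[i, j]
    }
  }
  out
}
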