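test_that("gene generation is deterministic, sorted, disjoint and in range", {
  p <- sim_params(n_genes = 50, seed = 1)
  g1 <- simulate_genes(p)
  g2 <- simulate_genes(p)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 50)
  expect_true(all(g1$start >= 0 & g1$end <= p$chrom_length))
  expect_true(all(diff(g1$start) > 0))
  # brute-force pairwise overlap check
  for (i in seq_len(nrow(g1) - 1)) {
    expect_lte(g1$end[i], g1$start[i + 1])
  }
  expect_true(all(lengths(g1$variant_pos) >= 1))
  # every variant inside its gene
  for (i in seq_len(nrow(g1))) {
    expect_true(all(g1$variant_pos[[i]] > g1$start[i] &
                      g1$variant_pos[[i]] <= g1$end[i]))
  }
})

test_that("zero genes give an empty table and too many genes error", {
  expect_equal(nrow(simulate_genes(sim_params(n_genes = 0))), 0)
  expect_error(simulate_genes(sim_params(chrom_length = 1e5, n_genes = 100)),
               "too short")
})

test_that("silencing decay is monotone, halves at the half-life, and is
          zeroed in resistant domains", {
  p <- sim_params(silencing_max = 0.8, silencing_halflife = 5e6,
                  resistant_domains = list(c(2e7, 3e7)))
  d <- seq(0, 4e7, by = 1e6)
  s <- silencing_fraction(d, p)
  expect_equal(s[1], 0.8)
  expect_equal(silencing_fraction(5e6, p), 0.4)
  expect_true(all(diff(s) <= 0))
  pos <- c(2.5e7, 1e7)
  s2 <- silencing_fraction(pos - p$integration_pos, p, pos = pos)
  expect_equal(s2[1], 0)
  expect_gt(s2[2], 0)
})

test_that("allelic counts follow the (1-s)/(2-s) cis-allele frequency", {
  # flat truth at s = 0.5 across many sites: pooled cis frequency ~ 1/3
  p <- sim_params(n_genes = 200, variants_per_gene_mean = 50,
                  silencing_max = 0.5, silencing_halflife = 1e15,
                  depth_mean = 100, seed = 11)
  g <- simulate_genes(p)
  x <- simulate_allelic_counts(g, p)
  expect_gt(nrow(x), 5000)
  cis <- ifelse(x$cis_allele == "a", x$exp_a, x$exp_b)
  tot <- x$exp_a + x$exp_b
  se <- sqrt((1 / 3) * (2 / 3) / sum(tot))
  expect_lt(abs(sum(cis) / sum(tot) - 1 / 3), 3 * se)
  # control condition is balanced
  cis_c <- ifelse(x$cis_allele == "a", x$ctrl_a, x$ctrl_b)
  tot_c <- x$ctrl_a + x$ctrl_b
  expect_lt(abs(sum(cis_c) / sum(tot_c) - 0.5), 3 * sqrt(0.25 / sum(tot_c)))
})

test_that("complete silencing yields zero cis-allele reads", {
  p <- sim_params(n_genes = 20, silencing_max = 1, silencing_halflife = 1e15,
                  seed = 2)
  x <- simulate_allelic_counts(simulate_genes(p), p)
  cis <- ifelse(x$cis_allele == "a", x$exp_a, x$exp_b)
  expect_true(all(cis == 0))
})

test_that("allelic counts are reproducible under a fixed seed", {
  p <- sim_params(n_genes = 10, seed = 5)
  g <- simulate_genes(p)
  expect_identical(simulate_allelic_counts(g, p),
                   simulate_allelic_counts(g, p))
})

test_that("chip windows: null change without gain and noise; perfect rank
          correlation at zero noise", {
  p0 <- sim_params(gain_coefficient = 0, noise_sd = 0, seed = 3)
  ch0 <- simulate_chip_windows(p0)
  me3 <- ch0[ch0$mark == "H3K27me3", ]
  expect_equal(me3$exp, me3$ctrl)

  p1 <- sim_params(gain_coefficient = 1.5, noise_sd = 0, seed = 3)
  ch1 <- simulate_chip_windows(p1)
  m1 <- ch1[ch1$mark == "H3K27me3" & ch1$on_arm, ]
  expect_equal(cor(m1$ctrl, m1$exp - m1$ctrl, method = "spearman"), 1)
  # off-arm windows gain nothing
  off <- ch1[ch1$mark == "H3K27me3" & !ch1$on_arm, ]
  expect_equal(off$exp, off$ctrl)
})

test_that("default chip regime reproduces a strong baseline-gain rank
          correlation", {
  ch <- simulate_chip_windows(sim_params(seed = 4))
  m <- ch[ch$mark == "H3K27me3" & ch$on_arm, ]
  expect_gte(cor(m$ctrl, m$exp - m$ctrl, method = "spearman"), 0.8)
})

test_that("H3K27ac is lost where silencing is high", {
  p <- sim_params(noise_sd = 0, seed = 6)
  g <- simulate_genes(p)
  ch <- simulate_chip_windows(p, genes = g)
  ac <- ch[ch$mark == "H3K27ac", ]
  near <- ac$start < 1.5e7  # within ~5 Mb of the 10 Mb integration site
  far <- ac$start > 5e7
  expect_lt(mean((ac$exp - ac$ctrl)[near] / ac$ctrl[near]), -0.05)
  # decay makes the loss negligible far away
  expect_lt(max(abs(ac$exp[far] - ac$ctrl[far]) / ac$ctrl[far]), 0.01)
})

test_that("baseline profile length must match the window count", {
  p <- sim_params(k27me3_baseline_profile = c(1, 2, 3))
  expect_error(simulate_chip_windows(p, window_size = 2e5), "length")
  p2 <- sim_params(k27me3_baseline_profile = c(1, -1))
  expect_error(simulate_chip_windows(p2, window_size = 5e7), "non-negative")
})

test_that("simulated contact matrices are symmetric with power-law decay", {
  p <- sim_params(chrom_length = 2e6, seed = 7)
  cm <- simulate_hic(p)
  expect_s3_class(cm, "contact_matrix")
  expect_equal(cm$n_bins, 50)
  expect_identical(cm$matrix, t(cm$matrix))
  expect_true(all(cm$matrix >= 0))

  # noise off: row profile proportional to 1/(1 + distance) at exponent 1
  cm0 <- simulate_hic(sim_params(chrom_length = 2e6, hic_decay_exponent = 1),
                      noise = "none")
  row1 <- cm0$matrix[1, ]
  expect_equal(row1 / row1[1], 1 / (1 + (0:49)))

  # 2-bin chromosome edge case
  tiny <- simulate_hic(sim_params(chrom_length = 8e4, integration_pos = 1e4))
  expect_equal(dim(tiny$matrix), c(2, 2))
})

test_that("the whole dataset is byte-identical under a fixed seed", {
  p <- sim_params(n_genes = 8, chrom_length = 4e6, integration_pos = 1e6,
                  seed = 9)
  d1 <- simulate_dataset(p, include_hic = TRUE)
  d2 <- simulate_dataset(p, include_hic = TRUE)
  expect_identical(d1, d2)
})

test_that("resistant-domain genes carry zero true silencing and their
          estimates center on zero", {
  p <- sim_params(n_genes = 120, depth_mean = 80, variants_per_gene_mean = 6,
                  resistant_domains = list(c(1.2e7, 2e7)), seed = 10)
  g <- simulate_genes(p)
  mid <- (g$start + g$end) / 2
  in_dom <- mid >= 1.2e7 & mid < 2e7
  expect_true(any(in_dom))
  expect_true(all(g$true_silencing[in_dom] == 0))
  res <- summarize_allelic(simulate_allelic_counts(g, p), genes_to_regions(g))
  est <- res$percent_allelic_silencing[in_dom & res$min_reads_pass]
  # centered on zero apart from the lower-read designation bias
  expect_lt(abs(mean(est)), 15)
})
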