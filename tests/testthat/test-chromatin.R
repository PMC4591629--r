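test_that("uniform coverage fills equal windows and totals are conserved", {
  cov <- tibble::tibble(chrom = "c", start = 0, end = 10000, score = 1)
  w <- quantify_windows(cov, 2000, normalize = "none")
  expect_equal(nrow(w), 5)
  expect_equal(w$count, rep(2000, 5))

  set.seed(4)
  cov2 <- tibble::tibble(chrom = "c",
                         start = seq(0, 9900, 100),
                         end = seq(100, 10000, 100),
                         score = rpois(100, 5))
  w2 <- quantify_windows(cov2, 3000, normalize = "none")
  expect_equal(sum(w2$count), sum(cov2$score * 100))
  # partial terminal window is kept
  expect_equal(w2$end[nrow(w2)], 10000)
})

test_that("window counts equal brute-force per-base summation", {
  set.seed(5)
  per_base <- rpois(5000, 2)
  cov <- tibble::tibble(chrom = "c", start = seq_along(per_base) - 1,
                        end = seq_along(per_base), score = per_base)
  w <- quantify_windows(cov, 700, normalize = "none")
  expect_equal(w$count, oracle_window_counts(per_base, 700))
  # cpm normalization rescales to a million total
  wc <- quantify_windows(cov, 700, normalize = "cpm")
  expect_equal(sum(wc$value), 1e6)
})

test_that("paired t on a 5-window toy matches the hand formula", {
  ctrl <- c(1, 2, 3, 4, 5)
  exp <- c(2.2, 2.9, 4.4, 4.9, 6.3)
  out <- arm_change_summary(ctrl, exp)
  d <- exp - ctrl
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t_stat, t_hand)
  expect_equal(out$mean_delta, mean(d))
  expect_equal(out$p_value, 2 * stats::pt(-abs(t_hand), 4))
})

test_that("identical tracks give zero delta; a constant shift is detected", {
  x <- c(1, 2, 3, 4, 5)
  same <- arm_change_summary(x, x)
  expect_equal(same$mean_delta, 0)
  expect_equal(same$p_value, 1)

  set.seed(6)
  ctrl <- rlnorm(200, 1, 0.5)
  shifted <- arm_change_summary(ctrl, ctrl + 2 + rnorm(200, 0, 0.05))
  expect_lt(shifted$p_value, 1e-10)
  expect_equal(shifted$mean_delta, 2, tolerance = 0.05)
})

test_that("arm summaries partition the chromosome's windows", {
  set.seed(7)
  n <- 100
  windows <- tibble::tibble(start = (seq_len(n) - 1) * 1000,
                            end = seq_len(n) * 1000)
  arms <- tibble::tibble(arm = c("p", "q"), start = c(0, 40000),
                         end = c(40000, 100000))
  out <- arm_change_summary(rlnorm(n), rlnorm(n), windows, arms)
  expect_equal(out$scope, c("chromosome", "p", "q"))
  expect_equal(sum(out$n_windows[-1]), out$n_windows[1])
  expect_lt(out$n_windows[2], out$n_windows[1])
})

test_that("too few windows are flagged instead of tested", {
  out <- arm_change_summary(1, 2)
  expect_equal(out$flag, "too_few_windows")
  expect_true(is.na(out$t_stat))
})

test_that("metaprofile of uniform signal is flat to machine precision", {
  track <- tibble::tibble(start = seq(0, 48000, 2000),
                          end = seq(2000, 50000, 2000), score = 2000 * 3)
  genes <- tibble::tibble(start = 20000, end = 30000, strand = "+")
  prof <- gene_metaprofile(track, genes, values = "score")
  expect_equal(prof$score, rep(3, nrow(prof)))
  expect_equal(attr(prof, "n_genes"), 1)
})

test_that("signal confined to the TSS lands in the first body bin", {
  track <- tibble::tibble(start = seq(0, 49000, 1000),
                          end = seq(1000, 50000, 1000), score = 0)
  track$score[track$start == 20000] <- 1000  # exactly the first body kb
  genes <- tibble::tibble(start = 20000, end = 40000, strand = "+")
  prof <- gene_metaprofile(track, genes, values = "score", n_body_bins = 20)
  body <- prof[prof$segment == "body", ]
  expect_equal(body$score[1], 1)
  expect_equal(sum(prof$score > 0), 1)
  expect_true(all(prof$score[prof$segment != "body"] == 0))
})

test_that("strand flip leaves strand-symmetric signal unchanged and
          reverses an asymmetric one", {
  set.seed(8)
  track <- tibble::tibble(start = seq(0, 49000, 1000),
                          end = seq(1000, 50000, 1000),
                          score = rlnorm(50))
  gp <- tibble::tibble(start = 20000, end = 30000, strand = "+")
  gm <- tibble::tibble(start = 20000, end = 30000, strand = "-")
  pp <- gene_metaprofile(track, gp, values = "score", n_body_bins = 10)
  pm <- gene_metaprofile(track, gm, values = "score", n_body_bins = 10)
  expect_equal(pm$score, rev(pp$score))

  # symmetric signal about the gene midpoint: profile invariant
  sym <- track
  sym$score <- 1 + abs(25 - (seq_len(50) - 0.5))
  ps <- gene_metaprofile(sym, gp, values = "score", n_body_bins = 10)
  pms <- gene_metaprofile(sym, gm, values = "score", n_body_bins = 10)
  expect_equal(ps$score, pms$score)
})

test_that("metaprofile is invariant under gene order permutation and
          equivariant under translation", {
  set.seed(9)
  track <- tibble::tibble(start = seq(0, 99000, 1000),
                          end = seq(1000, 100000, 1000),
                          score = rlnorm(100))
  genes <- tibble::tibble(start = c(20000, 50000, 70000),
                          end = c(30000, 62000, 81000),
                          strand = c("+", "-", "+"))
  p1 <- gene_metaprofile(track, genes, values = "score")
  p2 <- gene_metaprofile(track, genes[c(3, 1, 2), ], values = "score")
  expect_equal(p1$score, p2$score)

  shift <- 5000
  p3 <- gene_metaprofile(dplyr::mutate(track, start = start + shift,
                                       end = end + shift),
                         dplyr::mutate(genes, start = start + shift,
                                       end = end + shift),
                         values = "score")
  expect_equal(p1$score, p3$score)
})

test_that("short genes are skipped and recorded", {
  track <- tibble::tibble(start = 0, end = 1000, score = 5)
  genes <- tibble::tibble(start = c(100, 200), end = c(105, 800),
                          strand = c("+", "+"))
  prof <- gene_metaprofile(track, genes, values = "score", n_body_bins = 10)
  expect_equal(attr(prof, "n_genes"), 1)
  expect_equal(attr(prof, "skipped"), 1L)
})

test_that("baseline-gain correlation delegates to Spearman and detects
          both the proportional and the null regime", {
  expect_equal(baseline_gain_correlation(1:10, (1:10) * 2)$statistic, 1)
  set.seed(10)
  ctrl <- rlnorm(500, 1, 0.75)
  null <- baseline_gain_correlation(ctrl, rnorm(500))
  expect_lt(abs(null$statistic), 0.15)
  expect_gt(null$p_value, 0.05)
})
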