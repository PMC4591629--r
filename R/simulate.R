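#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate non-overlapping genes with heterozygous variant sites
#'
#' Places `n_genes` disjoint, sorted genes on the toy chromosome. Each gene
#' carries at least one heterozygous variant position, a signed distance from
#' its midpoint to the integration site, and its true cis-silenced fraction
#' under the generator's decay model (see [silencing_fraction()]).
#'
#' @param params A [sim_params()] object.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `distance_to_integration` (signed,
#'   midpoint minus integration position), `true_silencing`, and a
#'   list-column `variant_pos` of 1-based variant positions.
#' @examples
#' genes <- simulate_genes(sim_params(n_genes = 10, seed = 1))
#' genes
#' @export
simulate_genes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_genes
  if (n == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      distance_to_integration = numeric(), true_silencing = numeric(),
      variant_pos = list()
    ))
  }
  slot <- params$chrom_length / n
  if (slot < 4000) {
    abort(sprintf(
      "chromosome too short for %d genes: %.0f bp per gene slot (need >= 4000).",
      n, slot))
  }
  with_seed(params$seed, {
    len <- runif(n, 2000, min(5e4, 0.8 * slot))
    start <- (seq_len(n) - 1) * slot + runif(n, 0, slot - len)
    start <- floor(start)
    end <- floor(start + len)
    mid <- (start + end) / 2
    n_var <- pmax(1L, rpois(n, params$variants_per_gene_mean))
    variant_pos <- lapply(seq_len(n), function(i) {
      k <- min(n_var[i], end[i] - start[i])
      # 1-based positions, unique within the gene
      sort(sample.int(end[i] - start[i], k) + start[i])
    })
    tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = params$chrom,
      start = start,
      end = end,
      strand = sample(c("+", "-"), n, replace = TRUE),
      distance_to_integration = mid - params$integration_pos,
      true_silencing = silencing_fraction(mid - params$integration_pos,
                                          params, pos = mid),
      variant_pos = variant_pos
    )
  })
}

#' Simulate allelic read counts at heterozygous variant sites
#'
#' Draws per-site allelic depths from a negative-binomial model and splits
#' them between the two alleles. In the control condition both alleles are
#' drawn at expected ratio 0.5. In the experimental (XIST-induced) condition
#' the allele in cis with the transgene is scaled by `1 - s` while the trans
#' allele is unchanged, so the expected cis-allele frequency is
#' `(1 - s) / (2 - s)` and expected total depth is scaled by `(2 - s) / 2`,
#' where `s` is the gene's true silenced fraction.
#'
#' @param genes Gene tibble from [simulate_genes()].
#' @param params A [sim_params()] object.
#' @return A tibble of per-variant allelic counts: `chrom`, `pos` (1-based),
#'   `gene_id`, `allele_a`, `allele_b`, `ctrl_a`, `ctrl_b`, `exp_a`,
#'   `exp_b`, plus ground-truth columns `cis_allele` ("a" or "b") and
#'   `true_silencing`.
#' @examples
#' p <- sim_params(n_genes = 5, seed = 1)
#' counts <- simulate_allelic_counts(simulate_genes(p), p)
#' head(counts)
#' @export
simulate_allelic_counts <- function(genes, params) {
  stopifnot(inherits(params, "sim_params"))
  sites <- genes |>
    select("gene_id", "chrom", "true_silencing", "variant_pos") |>
    tidyr::unnest_longer("variant_pos", values_to = "pos") |>
    select("chrom", "pos", "gene_id", "true_silencing")
  n <- nrow(sites)
  if (n == 0) {
    return(tibble(
      chrom = character(), pos = numeric(), gene_id = character(),
      allele_a = character(), allele_b = character(),
      ctrl_a = integer(), ctrl_b = integer(),
      exp_a = integer(), exp_b = integer(),
      cis_allele = character(), true_silencing = numeric()
    ))
  }
  with_seed(params$seed + 1L, {
    nt <- c("A", "C", "G", "T")
    allele_a <- sample(nt, n, replace = TRUE)
    allele_b <- vapply(allele_a,
                       function(a) sample(setdiff(nt, a), 1), character(1))
    cis_is_a <- runif(n) < 0.5
    s <- sites$true_silencing
    ctrl_depth <- rnbinom(n, mu = params$depth_mean,
                          size = params$depth_dispersion)
    ctrl_cis <- rbinom(n, ctrl_depth, 0.5)
    exp_depth <- rnbinom(n, mu = params$depth_mean * (2 - s) / 2,
                         size = params$depth_dispersion)
    exp_cis <- rbinom(n, exp_depth, (1 - s) / (2 - s))
    sites |>
      mutate(
        allele_a = allele_a,
        allele_b = unname(allele_b),
        ctrl_a = ifelse(cis_is_a, ctrl_cis, ctrl_depth - ctrl_cis),
        ctrl_b = ctrl_depth - .data$ctrl_a,
        exp_a = ifelse(cis_is_a, exp_cis, exp_depth - exp_cis),
        exp_b = exp_depth - .data$exp_a,
        cis_allele = ifelse(cis_is_a, "a", "b")
      ) |>
      select("chrom", "pos", "gene_id", "allele_a", "allele_b",
             "ctrl_a", "ctrl_b", "exp_a", "exp_b",
             "cis_allele", "true_silencing")
  })
}

#' Simulate per-window ChIP-seq tracks for H3K27me3 and H3K27ac
#'
#' Generates control/experimental/input signal in non-overlapping fixed-size
#' windows. On the integration arm the experimental H3K27me3 equals
#' `baseline * (1 + gain_coefficient * w)` times mean-one log-normal noise,
#' where the proximity weight `w` is 1 under the default infinite
#' `gain_halflife` (otherwise `2^(-d / gain_halflife)`), and 0 off the arm
#' or inside resistant domains — a gain proportional to the pre-existing
#' level, as observed for XIST-induced H3K27me3 recruitment. H3K27ac is lost
#' in proportion to the local silenced fraction, more strongly at promoter
#' windows.
#'
#' @param params A [sim_params()] object.
#' @param window_size Window size in bp.
#' @param genes Optional gene tibble; promoter windows (those containing a
#'   gene 5' end) get elevated baseline H3K27ac and stronger loss.
#' @return A long tibble with one row per window and mark: `chrom`, `start`,
#'   `end`, `window`, `on_arm`, `mark` ("H3K27me3"/"H3K27ac"), `ctrl`,
#'   `exp`, `input`, and the noise-free ground-truth change `true_delta`.
#' @examples
#' track <- simulate_chip_windows(sim_params(seed = 1), window_size = 1e6)
#' head(track)
#' @export
simulate_chip_windows <- function(params, window_size = 2e5, genes = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n_win <- as.integer(ceiling(params$chrom_length / window_size))
  if (!is.null(params$k27me3_baseline_profile) &&
      length(params$k27me3_baseline_profile) != n_win) {
    abort(sprintf(
      "`k27me3_baseline_profile` has length %d but %d windows are required.",
      length(params$k27me3_baseline_profile), n_win))
  }
  if (!is.null(params$k27me3_baseline_profile) &&
      any(params$k27me3_baseline_profile < 0)) {
    abort("`k27me3_baseline_profile` must be non-negative.")
  }
  start <- (seq_len(n_win) - 1) * window_size
  end <- pmin(start + window_size, params$chrom_length)
  mid <- (start + end) / 2
  d <- abs(mid - params$integration_pos)
  # arm carrying the integration site: same side of the centromere
  on_arm <- if (params$integration_pos < params$centromere_pos) {
    mid < params$centromere_pos
  } else {
    mid >= params$centromere_pos
  }
  w <- ifelse(on_arm, 2^(-d / params$gain_halflife), 0)
  for (dom in params$resistant_domains) {
    w[mid >= dom[1] & mid < dom[2]] <- 0
  }
  s_w <- silencing_fraction(mid - params$integration_pos, params, pos = mid)

  with_seed(params$seed + 2L, {
    base_me3 <- params$k27me3_baseline_profile %||%
      rlnorm(n_win, meanlog = log(5), sdlog = 0.75)
    promoter <- rep(FALSE, n_win)
    if (!is.null(genes)) {
      tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
      promoter[pmin(floor(tss / window_size) + 1, n_win)] <- TRUE
    }
    base_ac <- rlnorm(n_win, meanlog = log(5), sdlog = 0.75) *
      ifelse(promoter, 4, 1)
    noise <- function() {
      if (params$noise_sd == 0) rep(1, n_win)
      else rlnorm(n_win, meanlog = -params$noise_sd^2 / 2,
                  sdlog = params$noise_sd)
    }
    me3_true <- base_me3 * (1 + params$gain_coefficient * w)
    ac_loss <- s_w * ifelse(promoter, 0.8, 0.4)
    ac_true <- base_ac * (1 - ac_loss)
    win <- tibble(chrom = params$chrom, start = start, end = end,
                  window = seq_len(n_win), on_arm = on_arm)
    bind_rows(
      win |> mutate(mark = "H3K27me3",
                    ctrl = base_me3,
                    exp = me3_true * noise(),
                    input = rlnorm(n_win, log(2), 0.2),
                    true_delta = me3_true - base_me3),
      win |> mutate(mark = "H3K27ac",
                    ctrl = base_ac,
                    exp = ac_true * noise(),
                    input = rlnorm(n_win, log(2), 0.2),
                    true_delta = ac_true - base_ac)
    )
  })
}

#' Simulate a binned chromosomal contact matrix
#'
#' Expected contacts between bins `i` and `j` follow a power-law distance
#' decay, `hic_scale * (1 + |i - j|)^-hic_decay_exponent`; observed counts
#' are Poisson draws around the expectation (or the exact expectation with
#' `noise = "none"`). The matrix is symmetric by construction.
#'
#' @param params A [sim_params()] object.
#' @param bin_size Bin size in bp (40 kb default, the native resolution the
#'   anchored-profile workflow rebins from).
#' @param noise `"poisson"` for count noise, `"none"` for the exact
#'   expectation.
#' @return A [contact_matrix()] object.
#' @examples
#' cm <- simulate_hic(sim_params(chrom_length = 2e6, seed = 1))
#' dim(cm$matrix)
#' @export
simulate_hic <- function(params, bin_size = 4e4,
                         noise = c("poisson", "none")) {
  stopifnot(inherits(params, "sim_params"))
  noise <- match.arg(noise)
  if (params$chrom_length < bin_size) {
    abort("`chrom_length` must cover at least one bin.")
  }
  n <- as.integer(ceiling(params$chrom_length / bin_size))
  dist <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- params$hic_scale * (1 + dist)^(-params$hic_decay_exponent)
  m <- if (noise == "none") {
    expected
  } else {
    with_seed(params$seed + 3L, {
      upper <- upper.tri(expected, diag = TRUE)
      draws <- matrix(0, n, n)
      draws[upper] <- rpois(sum(upper), expected[upper])
      draws + t(draws) - diag(diag(draws))
    })
  }
  contact_matrix(m, chrom = params$chrom, bin_size = bin_size)
}

#' Simulate gene-level total expression under cis-silencing
#'
#' Silencing one allele by fraction `s` reduces total expression by `s / 2`;
#' FPKM values get multiplicative log-normal noise.
#'
#' @param genes Gene tibble from [simulate_genes()].
#' @param params A [sim_params()] object.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of baseline FPKM.
#' @return Tibble: `gene_id`, `fpkm_ctrl`, `fpkm_exp`,
#'   `distance_to_integration`, `true_silencing`.
#' @export
simulate_expression <- function(genes, params,
                                fpkm_meanlog = log(20), fpkm_sdlog = 1) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed + 4L, {
    n <- nrow(genes)
    fpkm_ctrl <- rlnorm(n, fpkm_meanlog, fpkm_sdlog)
    noise <- if (params$noise_sd == 0) rep(1, n) else {
      rlnorm(n, -params$noise_sd^2 / 2, params$noise_sd)
    }
    tibble(
      gene_id = genes$gene_id,
      fpkm_ctrl = fpkm_ctrl,
      fpkm_exp = fpkm_ctrl * (1 - genes$true_silencing / 2) * noise,
      distance_to_integration = genes$distance_to_integration,
      true_silencing = genes$true_silencing
    )
  })
}

#' Simulate a complete synthetic dataset
#'
#' One call generating every input the downstream pipeline consumes: genes,
#' per-variant allelic counts, expression, ChIP window tracks, and (optional)
#' a contact matrix, all deterministic in `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param chip_window_size Window size for the simulated ChIP tracks, bp.
#' @param include_hic Generate the contact matrix too (can be large for long
#'   chromosomes at 40 kb bins).
#' @return A named list: `params`, `genes`, `counts`, `expression`, `chip`,
#'   and `hic` (NULL unless requested).
#' @examples
#' d <- simulate_dataset(sim_params(n_genes = 10, seed = 1))
#' names(d)
#' @export
simulate_dataset <- function(params, chip_window_size = 2e5,
                             include_hic = FALSE) {
  genes <- simulate_genes(params)
  list(
    params = params,
    genes = genes,
    counts = simulate_allelic_counts(genes, params),
    expression = simulate_expression(genes, params),
    chip = simulate_chip_windows(params, chip_window_size, genes = genes),
    hic = if (include_hic) simulate_hic(params) else NULL
  )
}
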