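#' Simulation parameters for a toy integration-site chromosome
#'
#' Bundles every knob of the synthetic-data generator: a single toy
#' chromosome carrying an inducible XIST transgene at `integration_pos`,
#' genes with heterozygous variant sites, sequencing depths, the spatial
#' decay of cis-silencing away from the integration site, H3K27me3/H3K27ac
#' window tracks, and a distance-decaying contact matrix.
#'
#' The true cis-silenced fraction of a gene at distance `d` (bp, absolute)
#' from the integration site is
#' `s(d) = silencing_max * 2^(-d / silencing_halflife)`, forced to zero
#' inside `resistant_domains`. The half-life has no empirical estimate to
#' anchor it; the default is an arbitrary, documented choice.
#'
#' @param chrom Chromosome name used in all generated tables.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of genes to place.
#' @param variants_per_gene_mean Mean number of heterozygous variant sites
#'   per gene (Poisson, truncated at >= 1).
#' @param integration_pos Transgene integration position, bp (0-based);
#'   defaults to a tenth of the chromosome length, well inside the short
#'   arm.
#' @param centromere_pos Boundary between the integration ("p") arm and the
#'   other arm; windows and genes at or beyond it are off-arm.
#' @param silencing_max Maximal true silenced fraction, in `[0, 1]`.
#' @param silencing_halflife Distance (bp) at which the silenced fraction
#'   halves.
#' @param resistant_domains List of length-2 numeric vectors `c(start, end)`
#'   (bp, 0-based half-open) where silencing is forced to zero, emulating
#'   domains that resist the spread of silencing.
#' @param depth_mean Mean allelic read depth per variant site.
#' @param depth_dispersion Negative-binomial size parameter of the per-site
#'   depth model (smaller = more overdispersed).
#' @param k27me3_baseline_profile Optional numeric vector of per-window
#'   baseline H3K27me3 levels; `NULL` generates a log-normal profile.
#' @param gain_coefficient Proportionality of H3K27me3 gain to the baseline
#'   level on the integration arm.
#' @param gain_halflife Distance (bp) at which the H3K27me3 proximity weight
#'   halves; `Inf` (default) applies the full gain across the whole
#'   integration arm.
#' @param noise_sd Standard deviation (log scale) of the multiplicative
#'   log-normal noise on simulated window tracks.
#' @param hic_decay_exponent Exponent of the power-law contact decay,
#'   expected contacts proportional to `(1 + |i - j|)^-hic_decay_exponent`.
#' @param hic_scale Expected self-contact count per bin.
#' @param seed Integer seed; every generator draw flows from it.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(n_genes = 20, seed = 1)
#' p$silencing_max
#' @export
sim_params <- function(chrom = "chrS",
                       chrom_length = 1e8,
                       n_genes = 100,
                       variants_per_gene_mean = 5,
                       integration_pos = chrom_length / 10,
                       centromere_pos = chrom_length / 2,
                       silencing_max = 0.8,
                       silencing_halflife = 5e6,
                       resistant_domains = list(),
                       depth_mean = 50,
                       depth_dispersion = 10,
                       k27me3_baseline_profile = NULL,
                       gain_coefficient = 1.5,
                       gain_halflife = Inf,
                       noise_sd = 0.22,
                       hic_decay_exponent = 1,
                       hic_scale = 100,
                       seed = 1L) {
  p <- list(
    chrom = as.character(chrom),
    chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes),
    variants_per_gene_mean = as.numeric(variants_per_gene_mean),
    integration_pos = as.numeric(integration_pos),
    centromere_pos = as.numeric(centromere_pos),
    silencing_max = as.numeric(silencing_max),
    silencing_halflife = as.numeric(silencing_halflife),
    resistant_domains = resistant_domains,
    depth_mean = as.numeric(depth_mean),
    depth_dispersion = as.numeric(depth_dispersion),
    k27me3_baseline_profile = k27me3_baseline_profile,
    gain_coefficient = as.numeric(gain_coefficient),
    gain_halflife = as.numeric(gain_halflife),
    noise_sd = as.numeric(noise_sd),
    hic_decay_exponent = as.numeric(hic_decay_exponent),
    hic_scale = as.numeric(hic_scale),
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  if (p$chrom_length <= 0) abort("`chrom_length` must be positive.")
  if (p$n_genes < 0) abort("`n_genes` must be non-negative.")
  if (p$silencing_max < 0 || p$silencing_max > 1) {
    abort("`silencing_max` must lie in [0, 1].")
  }
  if (p$silencing_halflife <= 0) abort("`silencing_halflife` must be > 0.")
  if (p$integration_pos < 0 || p$integration_pos >= p$chrom_length) {
    abort("`integration_pos` must lie within the chromosome.")
  }
  if (p$depth_mean <= 0) abort("`depth_mean` must be positive.")
  if (p$depth_dispersion <= 0) abort("`depth_dispersion` must be positive.")
  if (p$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  for (dom in p$resistant_domains) {
    if (length(dom) != 2 || dom[1] >= dom[2]) {
      abort("each resistant domain must be c(start, end) with start < end.")
    }
  }
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  chromosome     %s (%.1f Mb), %d genes\n",
              x$chrom, x$chrom_length / 1e6, x$n_genes))
  cat(sprintf("  integration    %s:%d (centromere at %.1f Mb)\n",
              x$chrom, as.integer(x$integration_pos),
              x$centromere_pos / 1e6))
  cat(sprintf("  silencing      max %.2f, half-life %.1f Mb, %d resistant domain(s)\n",
              x$silencing_max, x$silencing_halflife / 1e6,
              length(x$resistant_domains)))
  cat(sprintf("  depth model    NB(mean %.0f, size %.1f)\n",
              x$depth_mean, x$depth_dispersion))
  cat(sprintf("  seed           %d\n", x$seed))
  invisible(x)
}

#' True cis-silenced fraction at a distance from the integration site
#'
#' Exponential-decay ground truth used by the generator:
#' `s(d) = silencing_max * 2^(-|d| / silencing_halflife)`, zero inside any
#' resistant domain (membership judged at `pos` when supplied, otherwise the
#' decay alone is returned).
#'
#' @param distance Signed or absolute distance(s) to the integration site, bp.
#' @param params A [sim_params()] object.
#' @param pos Optional genomic position(s) used to test resistant-domain
#'   membership.
#' @return Numeric vector of true silenced fractions in `[0, 1]`.
#' @examples
#' p <- sim_params()
#' silencing_fraction(c(0, p$silencing_halflife), p)
#' @export
silencing_fraction <- function(distance, params, pos = NULL) {
  s <- params$silencing_max * 2^(-abs(distance) / params$silencing_halflife)
  if (!is.null(pos) && length(params$resistant_domains) > 0) {
    for (dom in params$resistant_domains) {
      s[pos >= dom[1] & pos < dom[2]] <- 0
    }
  }
  s
}
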