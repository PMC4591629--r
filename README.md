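# cisspread

Quantifying the spread of cis-silencing from an inducible XIST transgene.

When an *XIST* transgene is induced on an autosome, the XIST RNA coats the
chromosome in cis and silences nearby genes, with silencing fading — often
discontinuously — with distance from the integration site. Because the
silencing affects only the transgene-bearing homolog, it is detectable as
**allelic imbalance** at heterozygous variant sites: one allele's reads drop
while the other's stay put. `cisspread` implements the complete downstream
analysis for such experiments, for anyone quantifying allele-specific
silencing from RNA-seq / ChIP-seq read counts around a defined genomic
anchor:

* **Allelic workflow** — per-site allelic ratios; the biallelic control
  screen (control ratio in 0.3–0.7); phasing by the lower-read allele in the
  induced sample; region aggregation with one-pass removal of sites whose
  ratio deviates from the region ratio by more than 0.15; a 2-fold depth
  screen for ChIP regions; minimum allelic-read gates (4 reads per gene for
  RNA, 5 per region for ChIP, in both conditions); and **percent allelic
  silencing**
  `100 × (control ratio − experimental ratio) / control ratio`.
* **Silencing statistics** — percent total-expression silencing with an
  FPKM ≥ 5 gate and a 30–60 % classification band; a 2×2 chi-square test of
  the silencing proportion near the integration site versus the genome; and
  a permutation test for **distance decay** (genes in equal-count distance
  bins, chi-square statistic, silenced labels permuted across genes).
* **Chromatin windows** — fixed-window (2 kb / 1 Mb) signal quantification
  with CPM normalization, per-chromosome/arm paired t-tests of induced
  changes, strand-aware gene metaprofiles with 10 kb flanks, and the
  correlation of H3K27me3 gain with its pre-existing level.
* **Hi-C anchor profiles** — 40 kb contact matrices rebinned to 1 Mb by
  block summation and the contact profile of the bin containing the
  transgene.
* **Synthetic data with known ground truth** — a generator producing genes,
  heterozygous variant counts (negative-binomial depths, binomial allele
  splits with cis-allele frequency `(1 − s)/(2 − s)` for silenced fraction
  `s`), ChIP window tracks, and power-law contact matrices, so every stage
  is testable by parameter recovery.

Everything is data-frame-first: functions take tibbles, return tibbles,
chain with the pipe, and test results support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Simulate a 60 Mb chromosome with the transgene at 6 Mb (silencing maximum
0.8, half-life 5 Mb), run the allelic workflow, and test for distance decay:

```r
library(cisspread)
library(dplyr)

p <- sim_params(n_genes = 60, chrom_length = 6e7, integration_pos = 6e6,
                centromere_pos = 3e7, seed = 42)
d <- simulate_dataset(p)

al <- summarize_allelic(d$counts, genes_to_regions(d$genes))
al |> as_tibble() |> head(4) |>
  select(region_id, n_sites_retained, ctrl_allelic_ratio,
         exp_allelic_ratio, percent_allelic_silencing)
#> # A tibble: 4 × 5
#>   region_id n_sites_retained ctrl_allelic_ratio exp_allelic_ratio percent_allelic_silencing
#> 1 g0001                    4              0.469             0.407                      13.3
#> 2 g0002                    4              0.473             0.357                      24.6
#> 3 g0003                    5              0.5               0.299                      40.2
#> 4 g0004                    5              0.498             0.345                      30.9
```

These four genes sit 5.3–2.4 Mb from the integration site; their designated
silenced allele drops from a balanced ~0.5 control ratio to 0.30–0.41 after
induction, i.e. 13–40 % allelic silencing, rising as the transgene gets
closer. Does silencing decay with distance?

```r
calls <- call_silencing(d$expression, allelic = al)
distance_decay_test(calls, n_perm = 10000, seed = 43)
#> <cisspread_test: distance_decay_chisq>
#>   statistic = 38.18, p = 9.999e-05
#>   permutations = 10000
```

No permuted arrangement of the silenced labels reached the observed
concentration of silenced genes in the near-distance bins. The chromatin
side shows the hallmark H3K27me3 behavior — gain proportional to the
pre-existing level on the integration arm:

```r
me3 <- filter(d$chip, mark == "H3K27me3", on_arm)
baseline_gain_correlation(me3$ctrl, me3$exp - me3$ctrl)
#> <cisspread_test: correlate_spearman>
#>   statistic = 0.9045, p = 0
#>   n = 150
```

And the anchored Hi-C profile peaks at the bin containing the transgene:

```r
cm <- sim_params(chrom_length = 6e6, integration_pos = 2.3e6, seed = 42) |>
  simulate_hic() |>
  rebin_contacts(1e6)
anchor_profile(cm, 2.3e6)
#> # A tibble: 6 × 5
#>     bin   start     end contacts is_anchor
#> 1     1       0 1000000     1276 FALSE
#> 2     2 1000000 2000000     3084 FALSE
#> 3     3 2000000 3000000    12432 TRUE
#> ...
```

`run_pipeline(run_config(seed = 1))` chains all stages on one configuration
and writes TSV/BED/bedGraph/JSON outputs; see the vignette in `vignettes/`
for the model, parameter meanings, and design choices.

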