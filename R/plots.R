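#' Plot percent allelic silencing against distance from the integration site
#'
#' The standard view of cis-silencing spread: per-gene percent allelic
#' silencing as a function of (absolute) distance to the transgene.
#'
#' @param summary A [summarize_allelic()] result with a
#'   `distance_to_integration` column.
#' @param show_truth Overlay the generator's true expected percent
#'   silencing when a `true_silencing` column is present.
#' @return A ggplot.
#' @export
plot_silencing_distance <- function(summary, show_truth = TRUE) {
  df <- as_tibble(summary) |>
    filter(.data$min_reads_pass) |>
    mutate(dist_mb = abs(.data$distance_to_integration) / 1e6)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dist_mb,
                                        y = .data$percent_allelic_silencing)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "distance to integration site (Mb)",
                  y = "percent allelic silencing")
  if (show_truth && "true_silencing" %in% names(df)) {
    df$expected <- 100 * (0.5 - (1 - df$true_silencing) /
                            (2 - df$true_silencing)) / 0.5
    p <- p + ggplot2::geom_line(
      data = arrange(df, .data$dist_mb),
      ggplot2::aes(y = .data$expected), colour = "red")
  }
  p
}

#' @rdname gene_metaprofile
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-c("bin", "segment"), names_to = "signal",
                        values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$level,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = range(object$bin[object$segment == "body"]) + c(-0.5, 0.5),
      linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "bin (5' flank - body - 3' flank)",
                  y = "mean signal density")
}

#' Plot per-window ChIP signal change along the chromosome
#'
#' @param chip A [simulate_chip_windows()]-style tibble (columns `start`,
#'   `end`, `mark`, `ctrl`, `exp`).
#' @return A ggplot of exp - ctrl per window, faceted by mark.
#' @export
plot_window_delta <- function(chip) {
  df <- chip |>
    mutate(mid_mb = (.data$start + .data$end) / 2e6,
           delta = .data$exp - .data$ctrl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mb, y = .data$delta)) +
    ggplot2::geom_col(width = (df$end[1] - df$start[1]) / 1e6) +
    ggplot2::facet_wrap(~mark, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = "signal change (exp - ctrl)")
}
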