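#' Binned chromosomal contact matrix
#'
#' A square, symmetric, non-negative matrix of contact counts between
#' fixed-size genomic bins (0-based half-open; a position on a bin boundary
#' belongs to the higher bin).
#'
#' @param matrix Square numeric matrix of contact counts.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param tol Relative tolerance for the symmetry check.
#' @return A `contact_matrix` object (list with `chrom`, `bin_size`,
#'   `n_bins`, `matrix`).
#' @examples
#' contact_matrix(matrix(1, 2, 2), "chr8", 40000)
#' @export
contact_matrix <- function(matrix, chrom = "chr", bin_size = 4e4,
                           tol = 1e-8) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    abort("contact matrix must be square.")
  }
  if (any(matrix < 0)) abort("contact counts must be non-negative.")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > tol * max(1, max(abs(matrix)))) {
    abort("contact matrix is asymmetric beyond tolerance.")
  }
  structure(
    list(chrom = chrom, bin_size = bin_size, n_bins = nrow(matrix),
         matrix = (matrix + t(matrix)) / 2),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %g bp, total mass %.4g\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$matrix)))
  invisible(x)
}

#' Rebin a contact matrix to a coarser resolution
#'
#' Sums the counts of all fine bins falling inside each coarse bin (40 kb to
#' 1 Mb in the anchored-profile workflow: 25 x 25 blocks; the last coarse
#' bin may be partial). Total mass and symmetry are preserved.
#'
#' @param cm A [contact_matrix()].
#' @param new_bin_size Target bin size, a multiple of `cm$bin_size`.
#' @return A [contact_matrix()] at the coarser resolution.
#' @examples
#' cm <- contact_matrix(matrix(1, 50, 50), bin_size = 4e4)
#' rebin_contacts(cm, 1e6)$matrix  # 2 x 2 of 625
#' @export
rebin_contacts <- function(cm, new_bin_size = 1e6) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (new_bin_size %% cm$bin_size != 0) {
    abort("`new_bin_size` must be a multiple of the input bin size.")
  }
  group <- floor((seq_len(cm$n_bins) - 1) * cm$bin_size / new_bin_size)
  m <- rowsum(cm$matrix, group)
  m <- t(rowsum(t(m), group))
  contact_matrix(unname(m), chrom = cm$chrom, bin_size = new_bin_size)
}

#' Contact profile anchored at the bin containing the integration site
#'
#' Extracts the row of the (typically 1 Mb) contact matrix for the bin
#' containing the transgene integration position: the density of nuclear
#' contacts of every bin with the integration site. The anchor's own
#' (diagonal) count is reported but flagged, since self-contacts dominate.
#'
#' @param cm A [contact_matrix()], usually after [rebin_contacts()].
#' @param integration_pos Integration position in bp (0-based; a position on
#'   a bin boundary belongs to the higher bin).
#' @return An `anchor_profile` tibble: `bin` (1-based index), `start`,
#'   `end`, `contacts`, `is_anchor`. Attributes `anchor_bin` (0-based
#'   index), `chrom`, `bin_size`. Supports [autoplot()].
#' @examples
#' cm <- contact_matrix(matrix(1:4, 2, 2) + t(matrix(1:4, 2, 2)),
#'                      bin_size = 1e6)
#' anchor_profile(cm, 1e6)
#' @export
anchor_profile <- function(cm, integration_pos) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (integration_pos < 0 ||
      integration_pos >= cm$n_bins * cm$bin_size) {
    abort("`integration_pos` is outside the matrix extent.")
  }
  anchor <- floor(integration_pos / cm$bin_size)
  start <- (seq_len(cm$n_bins) - 1) * cm$bin_size
  out <- tibble(
    bin = seq_len(cm$n_bins),
    start = start,
    end = start + cm$bin_size,
    contacts = cm$matrix[anchor + 1, ],
    is_anchor = seq_len(cm$n_bins) == anchor + 1
  )
  attr(out, "anchor_bin") <- anchor
  attr(out, "chrom") <- cm$chrom
  attr(out, "bin_size") <- cm$bin_size
  class(out) <- c("anchor_profile", class(out))
  out
}

#' @rdname anchor_profile
#' @param object An `anchor_profile`.
#' @param ... Unused.
#' @method autoplot anchor_profile
#' @export
autoplot.anchor_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$contacts)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$is_anchor),
                      show.legend = FALSE, width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "red")) +
    ggplot2::labs(x = "position (Mb)", y = "contacts with anchor bin",
                  title = sprintf("Contacts anchored at %s bin %d",
                                  attr(object, "chrom"),
                                  attr(object, "anchor_bin")))
}
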