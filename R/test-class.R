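new_cisspread_test <- function(method, statistic, p_value, ...) {
  structure(
    c(list(method = method, statistic = statistic, p_value = p_value),
      list(...)),
    class = "cisspread_test"
  )
}

#' @export
print.cisspread_test <- function(x, ...) {
  cat(sprintf("<cisspread_test: %s>\n", x$method))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$n)) cat(sprintf("  n = %d\n", x$n))
  if (!is.null(x$n_perm)) cat(sprintf("  permutations = %d\n", x$n_perm))
  if (!is.null(x$flag) && nzchar(x$flag)) cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

#' Tidy a cisspread test result
#'
#' @param x A `cisspread_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`, and any
#'   of `df`, `n`, `n_perm`, `flag` the test recorded.
#' @method tidy cisspread_test
#' @export
tidy.cisspread_test <- function(x, ...) {
  out <- tibble(method = x$method, statistic = x$statistic,
                p_value = x$p_value)
  for (f in c("df", "n", "n_perm", "flag")) {
    if (!is.null(x[[f]])) out[[f]] <- x[[f]]
  }
  out
}

#' @rdname tidy.cisspread_test
#' @method glance cisspread_test
#' @export
glance.cisspread_test <- function(x, ...) tidy(x, ...)

#' Plot the permutation null distribution of a decay test
#'
#' @param object A `cisspread_test` from [distance_decay_test()].
#' @param ... Unused.
#' @return A ggplot: histogram of the permutation statistics with the
#'   observed value marked.
#' @method autoplot cisspread_test
#' @export
autoplot.cisspread_test <- function(object, ...) {
  if (is.null(object$null_distribution)) {
    abort("autoplot is available for permutation tests only.")
  }
  df <- tibble(stat = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(
      x = "permutation statistic", y = "count",
      title = sprintf("%s: observed %.3g, p = %.3g",
                      object$method, object$statistic, object$p_value)
    )
}
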