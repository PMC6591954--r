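# ggplot2 views of the result types: read identity distributions and the
# per-class consensus error profile.

#' Histogram of per-read identities
#'
#' @param per_read tibble from [score_reads()].
#' @param binwidth histogram bin width on the identity scale.
#' @return a ggplot.
#' @export
plot_read_identities <- function(per_read, binwidth = 0.005) {
  ggplot2::ggplot(per_read, ggplot2::aes(x = .data$identity)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "grey20", linewidth = 0.1) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "read identity (BLAST)", y = "reads",
                  title = "Per-read identity") +
    ggplot2::theme_minimal()
}

#' Bar chart of a consensus error profile
#'
#' @param profile an [error_profile()].
#' @param rate plot per-100-bp rates instead of raw counts.
#' @return a ggplot.
#' @export
plot_error_profile <- function(profile, rate = FALSE) {
  tab <- profile$table
  tab$klass <- factor(tab$klass, levels = rev(ERROR_CLASSES))
  y <- if (rate) "rate_per_100bp" else "count"
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$klass, y = .data[[y]])) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = if (rate) "errors per 100 bp" else "errors",
                  title = "Consensus errors by class") +
    ggplot2::theme_minimal()
}

#' @rdname plot_error_profile
#' @param object an `error_profile`.
#' @param ... passed to [plot_error_profile()].
#' @method autoplot error_profile
#' @export
autoplot.error_profile <- function(object, ...) {
  plot_error_profile(object, ...)
}

#' Plot an evaluation
#'
#' Read identity histogram when read-level results exist, otherwise the
#' error profile.
#'
#' @param object a `bc_eval` object.
#' @param which `"reads"` or `"profile"`.
#' @param ... passed on to the underlying plot function.
#' @return a ggplot.
#' @method autoplot bc_eval
#' @export
autoplot.bc_eval <- function(object, which = c("reads", "profile"), ...) {
  which <- match.arg(which)
  if (which == "reads" && !is.null(object$per_read)) {
    plot_read_identities(object$per_read, ...)
  } else if (!is.null(object$profile)) {
    plot_error_profile(object$profile, ...)
  } else {
    abort("nothing to plot in this evaluation")
  }
}
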