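# ggplot2 display methods -----------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a serial-position curve
#'
#' One line per list length, faceted by condition. Recency-justified curves
#' plot distance-from-end decreasing to the right, so the last list item
#' is always the rightmost point.
#'
#' @param object A `position_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot position_curve
#' @export
autoplot.position_curve <- function(object, ...) {
  alignment <- attr(object, "alignment")
  df <- tibble::as_tibble(object)
  if (alignment == "recency") {
    df$x <- -df$position
    xlab <- "distance from end of list (0 = last item)"
    breaks <- sort(unique(df$x))
    labels <- -breaks
  } else {
    df$x <- df$position
    xlab <- "input serial position"
    breaks <- sort(unique(df$x))
    labels <- breaks
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$value,
    group = factor(.data$list_length),
    colour = factor(.data$list_length))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = breaks, labels = labels) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = xlab,
                  y = sprintf("proportion (%s scoring)", attr(object, "rule")),
                  colour = "list length") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a transposition table or error gradient
#'
#' One line per input serial position across output positions, the
#' conventional display of transposition gradients: peaks on the diagonal
#' for raw matrices, locality-constrained humps around each input position
#' for error-only gradients.
#'
#' @param object A `transposition_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transposition_table
#' @export
autoplot.transposition_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ycol <- if ("proportion" %in% names(df)) "proportion" else "prop_by_input"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$output_position, y = .data[[ycol]],
    group = factor(.data$input_position),
    colour = factor(.data$input_position))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(
      breaks = sort(unique(df$output_position))) +
    ggplot2::labs(x = "output position",
                  y = if (ycol == "proportion") {
                    "proportion of order errors"
                  } else {
                    "proportion of recalls"
                  },
                  colour = "input position") +
    ggplot2::theme_minimal()
}

#' Plot a start/end cross-tabulation as a heatmap
#'
#' @param object A `startend_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot startend_table
#' @export
autoplot.startend_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$end_len, y = .data$start_len, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = df[df$count > 0, ],
      ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_reverse(breaks = 0:attr(object, "list_length")) +
    ggplot2::scale_x_continuous(breaks = 0:attr(object, "list_length")) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "end-sequence length", y = "start-sequence length",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Side-by-side observed vs estimated gradients
#'
#' @param observed,estimated Error-only `transposition_table`s, e.g. from
#'   [error_gradient()] and [estimated_gradient_analytic()].
#' @return A ggplot object faceted by source.
#' @export
plot_gradient_comparison <- function(observed, estimated) {
  take <- function(x, src) {
    tibble::as_tibble(x) |>
      dplyr::select("input_position", "output_position", "proportion") |>
      dplyr::mutate(source = src)
  }
  df <- dplyr::bind_rows(take(observed, "observed"),
                         take(estimated, "estimated"))
  df$source <- factor(df$source, levels = c("observed", "estimated"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$output_position, y = .data$proportion,
    group = factor(.data$input_position),
    colour = factor(.data$input_position))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$source)) +
    ggplot2::labs(x = "output position", y = "proportion of order errors",
                  colour = "input position") +
    ggplot2::theme_minimal()
}
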