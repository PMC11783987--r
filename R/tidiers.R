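# broom-style tidiers ---------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a start/end cross-tabulation
#'
#' @param x A `startend_table`.
#' @param drop_zero Drop empty cells? Default `TRUE`.
#' @param ... Unused.
#' @return A plain tibble with `start_len`, `end_len`, `count` and
#'   `proportion` of trials per cell.
#' @method tidy startend_table
#' @export
tidy.startend_table <- function(x, drop_zero = TRUE, ...) {
  out <- tibble::as_tibble(x)
  if (drop_zero) out <- out[out$count > 0L, ]
  out$proportion <- out$count / sum(out$count)
  out
}

#' One-row summary of a start/end cross-tabulation
#'
#' @param x A `startend_table`.
#' @param ... Unused.
#' @return A one-row tibble: `list_length`, `n_trials`, `prop_complete`,
#'   `mean_start`, `mean_end` (cell-weighted means of the sequence
#'   lengths).
#' @method glance startend_table
#' @export
glance.startend_table <- function(x, ...) {
  total <- sum(x$count)
  tibble::tibble(
    list_length = attr(x, "list_length"),
    n_trials = total,
    prop_complete = proportion_complete_correct(x),
    mean_start = sum(x$start_len * x$count) / total,
    mean_end = sum(x$end_len * x$count) / total
  )
}

#' Tidy a transposition table or gradient
#'
#' @param x A `transposition_table`.
#' @param ... Unused.
#' @return A plain tibble of cells with a `source` column.
#' @method tidy transposition_table
#' @export
tidy.transposition_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(source = attr(x, "source") %||% "observed")
}

#' One-row summary of a transposition table or gradient
#'
#' @param x A `transposition_table`.
#' @param ... Unused.
#' @return A one-row tibble: `list_length`, `n_trials`, `n_cells`,
#'   `normalisation`, `empty`, and for error-only gradients the
#'   `locality_correlation` between error share and transposition
#'   distance.
#' @method glance transposition_table
#' @export
glance.transposition_table <- function(x, ...) {
  tibble::tibble(
    list_length = attr(x, "list_length"),
    n_trials = attr(x, "n_trials"),
    n_cells = nrow(x),
    normalisation = attr(x, "normalisation"),
    empty = is_empty_gradient(x),
    locality_correlation = if (identical(attr(x, "normalisation"),
                                         "errors")) {
      locality_correlation(x)
    } else {
      NA_real_
    }
  )
}

#' One-row summary of a position curve
#'
#' @param x A `position_curve`.
#' @param ... Unused.
#' @return One row per condition and list length with the curve mean and
#'   its first/last values (primacy and recency ends).
#' @method glance position_curve
#' @export
glance.position_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$condition, .data$list_length) |>
    dplyr::summarise(
      rule = attr(x, "rule"),
      mean_value = mean(.data$value),
      first_position = .data$value[which.min(.data$position)],
      last_position = .data$value[which.max(.data$position)],
      .groups = "drop"
    )
}
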