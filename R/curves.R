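# Serial-position curves and transposition matrices --------------------------

#' Score each input position of each trial
#'
#' Three scoring rules, all on the temporally ordered sequence of responses
#' (output rank is the positional slot; omission marks and intrusions occupy
#' output indices, so they shift the slots of later items):
#' * `"SR"` (serial recall): item i is correct only when its first recall
#'   occurs at output index i.
#' * `"FR"` (free recall): item i is correct when it is recalled anywhere.
#' * `"START_END"`: item i is correct only when it is output as part of a
#'   start-sequence or an end-sequence (completely correct trials score all
#'   items correct).
#'
#' Only the first recall of an item contributes; later recalls are
#' repetitions.
#'
#' @inheritParams find_start_sequence
#' @param rule `"SR"`, `"FR"` or `"START_END"`.
#' @param annotations Optional precomputed [annotate_trials()] result
#'   (required only for `"START_END"`; computed when missing).
#' @return A tibble with columns `trial_id`, `condition`, `list_length`,
#'   `input_position`, `correct` (0/1).
#' @examples
#' score_trials(parse_letter_trial("ABCD", "ABDC"), "SR")
#' @export
score_trials <- function(trials, rule = c("SR", "FR", "START_END"),
                         annotations = NULL, policy = sequence_policy()) {
  rule <- match.arg(rule)
  pos_list <- trials_pos_list(trials)
  if (rule == "START_END" && is.null(annotations)) {
    annotations <- annotate_trials(trials, policy)
  }
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    n <- trials$list_length[i]
    pos <- pos_list[[i]]
    first_out <- rep(NA_integer_, n)
    item_idx <- which(!is.na(pos) & pos > 0L)
    for (j in item_idx) {
      if (is.na(first_out[pos[j]])) first_out[pos[j]] <- j
    }
    correct <- switch(
      rule,
      SR = !is.na(first_out) & first_out == seq_len(n),
      FR = !is.na(first_out),
      START_END = {
        labels <- annotations$labels[[i]]
        if (annotations$complete_correct[i]) {
          rep(TRUE, n)
        } else {
          in_seq <- rep(FALSE, n)
          hit <- item_idx[labels[item_idx] %in% c("start", "end")]
          in_seq[unique(pos[hit])] <- TRUE
          in_seq
        }
      }
    )
    rows[[i]] <- tibble::tibble(
      trial_id = trials$trial_id[i],
      condition = trials$condition[i],
      list_length = n,
      input_position = seq_len(n),
      correct = as.integer(correct)
    )
  }
  dplyr::bind_rows(rows)
}

new_position_curve <- function(df, rule, alignment) {
  df <- tibble::as_tibble(df)
  attr(df, "rule") <- rule
  attr(df, "alignment") <- alignment
  class(df) <- c("position_curve", class(df))
  df
}

#' Serial-position curve
#'
#' Mean per-position correctness across trials, computed separately for
#' each condition and list length (curves are never averaged across
#' lengths). With `alignment = "recency"` positions are re-expressed as the
#' distance from the end of the list (the last item at distance 0), so
#' curves from different lengths align on the right.
#'
#' @inheritParams score_trials
#' @param alignment `"primacy"` (input position 1..n) or `"recency"`
#'   (distance from end 0..n-1).
#' @param include_complete Should completely correct trials enter the
#'   aggregate? Set `FALSE` to study the residual structure of imperfect
#'   protocols only.
#' @return A tibble of class `"position_curve"`: `condition`,
#'   `list_length`, `rule`, `alignment`, `position`, `value`,
#'   `denominator`.
#' @examples
#' tr <- parse_letter_trial("ABCD", "ABDC")
#' position_curve(tr, "SR")
#' @export
position_curve <- function(trials, rule = c("SR", "FR", "START_END"),
                           annotations = NULL,
                           alignment = c("primacy", "recency"),
                           include_complete = TRUE,
                           policy = sequence_policy()) {
  rule <- match.arg(rule)
  alignment <- match.arg(alignment)
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  if (is.null(annotations)) annotations <- annotate_trials(trials, policy)
  if (!include_complete) {
    keep <- !annotations$complete_correct
    trials <- trials[keep, , drop = FALSE]
    annotations <- annotations[keep, , drop = FALSE]
    if (nrow(trials) == 0L) stop("no incomplete trials left", call. = FALSE)
  }
  scored <- score_trials(trials, rule, annotations = annotations,
                         policy = policy)
  curve <- scored |>
    dplyr::mutate(position = if (alignment == "recency") {
      .data$list_length - .data$input_position
    } else {
      .data$input_position
    }) |>
    dplyr::group_by(.data$condition, .data$list_length, .data$position) |>
    dplyr::summarise(value = mean(.data$correct),
                     denominator = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rule = rule, alignment = alignment, .before = "position")
  new_position_curve(curve, rule, alignment)
}

#' Residual "Other"-item curve
#'
#' The proportion of trials on which each input position was recalled
#' outside both sequences (label `"other"`). Recency-justified by default:
#' the last list item plots at distance 0, so the residual recency advantage
#' of near-end items lines up across list lengths.
#'
#' @inheritParams position_curve
#' @return A `position_curve` tibble with `rule = "OTHER_RESIDUAL"`.
#' @examples
#' residual_other_curve(parse_letter_trial("ABCDEFGH", "FGHCABG"))
#' @export
residual_other_curve <- function(trials, annotations = NULL,
                                 alignment = c("recency", "primacy"),
                                 policy = sequence_policy()) {
  alignment <- match.arg(alignment)
  if (is.null(annotations)) annotations <- annotate_trials(trials, policy)
  rows <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    n <- annotations$list_length[i]
    other <- rep(0L, n)
    op <- annotations$other_positions[[i]]
    other[op] <- 1L
    rows[[i]] <- tibble::tibble(
      condition = annotations$condition[i],
      list_length = n,
      input_position = seq_len(n),
      is_other = other
    )
  }
  curve <- dplyr::bind_rows(rows) |>
    dplyr::mutate(position = if (alignment == "recency") {
      .data$list_length - .data$input_position
    } else {
      .data$input_position
    }) |>
    dplyr::group_by(.data$condition, .data$list_length, .data$position) |>
    dplyr::summarise(value = mean(.data$is_other),
                     denominator = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rule = "OTHER_RESIDUAL", alignment = alignment,
                  .before = "position")
  new_position_curve(curve, "OTHER_RESIDUAL", alignment)
}

new_transposition_table <- function(df, n, n_trials, normalisation = "none",
                                    source = "observed", empty = FALSE) {
  df <- tibble::as_tibble(df)
  attr(df, "list_length") <- as.integer(n)
  attr(df, "n_trials") <- n_trials
  attr(df, "normalisation") <- normalisation
  attr(df, "source") <- source
  attr(df, "empty") <- empty
  class(df) <- c("transposition_table", class(df))
  df
}

#' Observed transposition matrix
#'
#' Counts of (input position, output position) pairs across trials of one
#' list length. Only the first recall of each list item contributes;
#' intrusions contribute no counts but (by default) occupy an output index,
#' shifting the slots of later recalls, as do omission marks.
#'
#' @inheritParams find_start_sequence
#' @param intrusions `"occupy"` (default: intrusions keep their output slot)
#'   or `"transparent"` (output positions are recomputed after dropping
#'   intrusions, for sensitivity analysis).
#' @return A tibble of class `"transposition_table"`: `input_position`,
#'   `output_position`, `count`, and `prop_by_input` (counts normalised
#'   within each input position).
#' @examples
#' transposition_matrix(parse_letter_trial("ABCD", "ABDC"))
#' @export
transposition_matrix <- function(trials,
                                 intrusions = c("occupy", "transparent")) {
  intrusions <- match.arg(intrusions)
  n_seen <- unique(trials$list_length)
  if (length(n_seen) != 1L) {
    stop("transposition matrices require a single list length; got ",
         paste(n_seen, collapse = ", "), call. = FALSE)
  }
  n <- n_seen
  pos_list <- trials_pos_list(trials)
  pairs_i <- integer(0)
  pairs_o <- integer(0)
  for (pos in pos_list) {
    out_idx <- seq_along(pos)
    if (intrusions == "transparent") {
      keep <- !is.na(pos)
      pos <- pos[keep]
      out_idx <- seq_along(pos)
    }
    item <- which(!is.na(pos) & pos > 0L)
    item <- item[!duplicated(pos[item])]  # first occurrences only
    pairs_i <- c(pairs_i, pos[item])
    pairs_o <- c(pairs_o, out_idx[item])
  }
  df <- tibble::tibble(input_position = pairs_i, output_position = pairs_o) |>
    dplyr::count(.data$input_position, .data$output_position, name = "count") |>
    dplyr::group_by(.data$input_position) |>
    dplyr::mutate(prop_by_input = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  new_transposition_table(df, n = n, n_trials = nrow(trials))
}

#' Error-only transposition gradient
#'
#' Removes the correct-in-position diagonal from a transposition table and
#' renormalises so the remaining (order-error) cells sum to 1.
#'
#' @param table A `transposition_table` (observed or estimated; any table
#'   with `input_position`, `output_position` and a `count` or `expected`
#'   column).
#' @return A `transposition_table` with column `proportion` summing to 1.
#'   When the table contains no order error the result has zero rows and
#'   attribute `empty = TRUE` (see [is_empty_gradient()]).
#' @examples
#' error_gradient(transposition_matrix(parse_letter_trial("ABCD", "ABDC")))
#' @export
error_gradient <- function(table) {
  stopifnot(inherits(table, "transposition_table"))
  weight_col <- if ("count" %in% names(table)) "count" else "expected"
  errs <- tibble::as_tibble(table) |>
    dplyr::filter(.data$input_position != .data$output_position)
  total <- sum(errs[[weight_col]])
  if (total <= 0) {
    out <- tibble::tibble(input_position = integer(0),
                          output_position = integer(0),
                          weight = numeric(0), proportion = numeric(0))
    return(new_transposition_table(out, n = attr(table, "list_length"),
                                   n_trials = attr(table, "n_trials"),
                                   normalisation = "errors",
                                   source = attr(table, "source"),
                                   empty = TRUE))
  }
  out <- errs |>
    dplyr::transmute(.data$input_position, .data$output_position,
                     weight = .data[[weight_col]],
                     proportion = .data[[weight_col]] / total)
  new_transposition_table(out, n = attr(table, "list_length"),
                          n_trials = attr(table, "n_trials"),
                          normalisation = "errors",
                          source = attr(table, "source"))
}

#' Is a gradient the empty-gradient signal?
#'
#' @param table A `transposition_table` returned by [error_gradient()],
#'   [estimated_gradient_mc()] or [estimated_gradient_analytic()].
#' @return `TRUE` when the input contained no order errors.
#' @export
is_empty_gradient <- function(table) {
  isTRUE(attr(table, "empty"))
}

#' Locality of a transposition-error gradient
#'
#' The correlation between each error cell's share of the total error mass
#' and its transposition distance `|input - output|`. Locality-constrained
#' gradients (errors concentrated near the diagonal) give a clearly
#' negative value. Reported as a description of gradient shape, not a test
#' statistic.
#'
#' @param gradient An error-only `transposition_table`.
#' @return A single correlation, or `NA` for an empty gradient.
#' @export
locality_correlation <- function(gradient) {
  stopifnot(inherits(gradient, "transposition_table"))
  if (is_empty_gradient(gradient) || nrow(gradient) < 3L) return(NA_real_)
  stats::cor(gradient$proportion,
             abs(gradient$input_position - gradient$output_position))
}
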