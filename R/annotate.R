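# Start/end-sequence detection and trial annotation --------------------------

trials_pos_list <- function(trials) {
  tok <- omission_token(trials)
  purrr::map2(trials$recalled, trials$presented,
              function(r, p) tokens_to_pos(r, p, tok))
}

#' Detect the start-sequence of each trial
#'
#' A start-sequence is the maximal run of recalls from consecutive input
#' positions `1, 2, ..., s`, in forward order, initiating with the first
#' presented item; it may sit anywhere in the output. Its length is 0
#' exactly when item 1 has no eligible recall.
#'
#' @inheritParams omission_token
#' @param policy A [sequence_policy()] (or `"first"` / `"any"`).
#' @return A tibble with columns `trial_id`, `length`, `output_from`,
#'   `output_to` (`NA` when the length is 0).
#' @examples
#' find_start_sequence(parse_letter_trial("ABCDEFGH", "FGHCABG"))
#' @export
find_start_sequence <- function(trials, policy = sequence_policy()) {
  ann <- annotate_trials(trials, policy)
  tibble::tibble(
    trial_id = ann$trial_id,
    length = ann$start_len,
    output_from = ann$start_from,
    output_to = ann$start_to
  )
}

#' Detect the end-sequence of each trial
#'
#' An end-sequence is the maximal run of recalls from consecutive input
#' positions `n-e+1, ..., n`, in forward order, terminating with the last
#' presented item. Its length is 0 exactly when item n has no eligible
#' recall. Completely correct protocols follow the convention
#' `s = n, e = 0`.
#'
#' @inheritParams find_start_sequence
#' @return A tibble with columns `trial_id`, `length`, `output_from`,
#'   `output_to`.
#' @examples
#' find_end_sequence(parse_letter_trial("ABCDEFGH", "FGHCABG"))
#' @export
find_end_sequence <- function(trials, policy = sequence_policy()) {
  ann <- annotate_trials(trials, policy)
  tibble::tibble(
    trial_id = ann$trial_id,
    length = ann$end_len,
    output_from = ann$end_from,
    output_to = ann$end_to
  )
}

#' Annotate trials with start/end-sequences and event labels
#'
#' Labels every recall event as `"start"`, `"end"`, `"other"`,
#' `"repetition"`, `"intrusion"` or `"omission"`, and summarises each trial
#' by its start-sequence length s, end-sequence length e, Other-item count
#' k, and completeness. A protocol is completely correct when it consists of
#' exactly the items `1..n` in order with no intrusions, omission marks or
#' repetitions; such trials take `s = n`, `e = 0` by convention.
#'
#' @inheritParams find_start_sequence
#' @return A tibble of class `"recall_annotations"` with one row per trial:
#'   `trial_id`, `condition`, `list_length`, `outputs_total`, `start_len`,
#'   `end_len`, `other_count`, `n_repetition`, `n_intrusion`, `n_omission`,
#'   `complete_correct`, output spans of both sequences, and list-columns
#'   `labels` (one label per recall event) and `other_positions` (input
#'   positions of the Other items). The policy is stored as an attribute.
#' @examples
#' annotate_trials(parse_letter_trial("ABCDEFGH", "FGHCABG"))
#' @export
annotate_trials <- function(trials, policy = sequence_policy()) {
  policy <- as_sequence_policy(policy)
  pos_list <- trials_pos_list(trials)
  scans <- purrr::map2(pos_list, trials$list_length,
                       function(p, n) scan_protocol(p, n, policy))
  span <- function(field, which_end) {
    vapply(scans, function(s) {
      sp <- s[[field]]
      if (is.null(sp)) NA_integer_ else as.integer(sp[which_end])
    }, integer(1))
  }
  out <- tibble::tibble(
    trial_id = trials$trial_id,
    condition = trials$condition,
    list_length = trials$list_length,
    outputs_total = lengths(pos_list),
    start_len = vapply(scans, function(s) as.integer(s$start_len), integer(1)),
    end_len = vapply(scans, function(s) as.integer(s$end_len), integer(1)),
    other_count = vapply(scans, function(s) s$n_other, integer(1)),
    n_repetition = vapply(scans, function(s) s$n_repetition, integer(1)),
    n_intrusion = vapply(scans, function(s) s$n_intrusion, integer(1)),
    n_omission = vapply(scans, function(s) s$n_omission, integer(1)),
    complete_correct = vapply(scans, function(s) s$complete, logical(1)),
    start_from = span("start_span", 1L),
    start_to = span("start_span", 2L),
    end_from = span("end_span", 1L),
    end_to = span("end_span", 2L),
    labels = lapply(scans, `[[`, "labels"),
    other_positions = lapply(scans, `[[`, "other_positions")
  )
  attr(out, "policy") <- policy
  class(out) <- c("recall_annotations", class(out))
  out
}

#' Cross-tabulate trials by start- and end-sequence length
#'
#' Counts trials in each (start length, end length) cell, the shape of a
#' published start/end frequency table. Completely correct trials land in
#' cell (n, 0).
#'
#' @param annotations Output of [annotate_trials()], all from trials of one
#'   list length (mixed lengths are an error; aggregate per length).
#' @param list_length List length n; inferred when all annotations agree.
#' @param label Optional group label stored on the result.
#' @return A tibble of class `"startend_table"` with columns `start_len`,
#'   `end_len` (the full grid `0..n` by `0..n`) and `count`. Attributes:
#'   `list_length`, `n_trials`, `n_complete`, `label`.
#' @examples
#' tr <- parse_letter_trial(rep("ABCDEF", 3), c("ABCDEF", "ABEF", "CDF"))
#' crosstab_start_end(annotate_trials(tr))
#' @export
crosstab_start_end <- function(annotations, list_length = NULL, label = NULL) {
  n_seen <- unique(annotations$list_length)
  if (is.null(list_length)) {
    if (length(n_seen) > 1L) {
      stop("annotations mix list lengths (", paste(n_seen, collapse = ", "),
           "); aggregate per length", call. = FALSE)
    }
    if (length(n_seen) == 0L) {
      stop("cannot infer list_length from empty annotations", call. = FALSE)
    }
    list_length <- n_seen
  } else if (length(n_seen) && any(n_seen != list_length)) {
    stop("annotations contain list lengths other than ", list_length,
         call. = FALSE)
  }
  n <- as.integer(list_length)
  grid <- tidyr::expand_grid(start_len = 0:n, end_len = 0:n)
  obs <- annotations |>
    dplyr::count(.data$start_len, .data$end_len, name = "count")
  out <- grid |>
    dplyr::left_join(obs, by = c("start_len", "end_len")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
  new_startend_table(out, list_length = n,
                     n_complete = sum(annotations$complete_correct),
                     label = label %||%
                       paste(unique(annotations$condition), collapse = "+"))
}

new_startend_table <- function(df, list_length, n_complete = NULL,
                               label = NULL) {
  df <- tibble::as_tibble(df)
  attr(df, "list_length") <- as.integer(list_length)
  attr(df, "n_trials") <- sum(df$count)
  attr(df, "n_complete") <- n_complete
  attr(df, "label") <- label
  class(df) <- c("startend_table", class(df))
  df
}

#' Proportion of completely correct trials
#'
#' The fraction of trials whose recall equalled the full presented order
#' with no extra, missing or repeated responses. For tables built by
#' [crosstab_start_end()] this uses the recorded complete-correct count;
#' for tables transcribed from print it uses cell (n, 0), where such trials
#' land by convention.
#'
#' @param table A `startend_table`.
#' @return A proportion in `[0, 1]`.
#' @export
proportion_complete_correct <- function(table) {
  stopifnot(inherits(table, "startend_table"))
  total <- sum(table$count)
  if (total == 0L) {
    stop("proportion is undefined for an empty table", call. = FALSE)
  }
  n <- attr(table, "list_length")
  complete <- attr(table, "n_complete")
  if (is.null(complete)) {
    complete <- table$count[table$start_len == n & table$end_len == 0L]
  }
  as.numeric(complete) / total
}

#' Summarise sequence lengths by group
#'
#' Mean start-sequence length, mean end-sequence length, mean Other count
#' and the completely-correct proportion, per group.
#'
#' @inheritParams crosstab_start_end
#' @param ... Grouping columns (tidy-select style bare names), defaulting to
#'   `condition` and `list_length`. Empty groups are dropped with a warning.
#' @return A tibble with one row per group: `n_trials`, `mean_start`,
#'   `mean_end`, `mean_other`, `prop_complete`.
#' @export
sequence_length_summary <- function(annotations, ...) {
  if (nrow(annotations) == 0L) {
    stop("no annotations to summarise", call. = FALSE)
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0L) {
    groups <- rlang::quos(.data$condition, .data$list_length)
  }
  annotations |>
    tibble::as_tibble() |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_start = mean(.data$start_len),
      mean_end = mean(.data$end_len),
      mean_other = mean(.data$other_count),
      prop_complete = mean(.data$complete_correct),
      .groups = "drop"
    )
}

#' Serialise a start/end table
#'
#' Writes the cross-tabulation either as CSV in the published layout (rows
#' labelled `"no start"`, `"1"`, `"12"`, ...; columns `"no end"`, `"6"`,
#' `"56"`, ... for n = 6) or as JSON.
#'
#' @param table A `startend_table`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_startend_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  n <- attr(table, "list_length")
  start_labels <- c("no start",
                    vapply(1:n, function(s) paste(1:s, collapse = ""), ""))
  end_labels <- c("no end",
                  vapply(1:n, function(e) paste((n - e + 1):n, collapse = ""), ""))
  if (format == "json") {
    payload <- list(
      list_length = n,
      n_trials = attr(table, "n_trials"),
      n_complete = attr(table, "n_complete"),
      label = attr(table, "label"),
      cells = tibble::as_tibble(table)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  wide <- tibble::as_tibble(table) |>
    dplyr::mutate(end_lab = factor(end_labels[.data$end_len + 1L],
                                   levels = end_labels)) |>
    dplyr::select(-"end_len") |>
    tidyr::pivot_wider(names_from = "end_lab", values_from = "count") |>
    dplyr::mutate(start_len = start_labels[.data$start_len + 1L]) |>
    dplyr::rename(`start sequence` = "start_len")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' @export
print.startend_table <- function(x, ...) {
  cat(sprintf("<startend_table> n = %d, %d trials (%s)\n",
              attr(x, "list_length"), attr(x, "n_trials"),
              attr(x, "label") %||% "unlabelled"))
  m <- startend_matrix(x)
  print(m)
  invisible(x)
}

#' Start/end table as a matrix
#'
#' @param table A `startend_table`.
#' @return An `(n+1) x (n+1)` integer matrix; rows are start lengths 0..n,
#'   columns end lengths 0..n.
#' @export
startend_matrix <- function(table) {
  n <- attr(table, "list_length")
  m <- matrix(0L, n + 1L, n + 1L,
              dimnames = list(start = 0:n, end = 0:n))
  m[cbind(table$start_len + 1L, table$end_len + 1L)] <- table$count
  m
}
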