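# Packaged transcription of the published 6-word ISR start/end
# cross-tabulation (Osth & Dennis, 2015 data as re-scored with start/end
# sequences; four between-subject conditions).

.table1_conditions <- c("Closed ISR", "Open ISR", "Blanks", "Open RoO")

# Trial totals as reported in the running text. They disagree with the
# printed block sums for three conditions (the printed cells are taken as
# authoritative: their sums reproduce the printed completely-correct
# proportions).
.table1_text_totals <- c(
  "Open ISR" = 6128L, "Blanks" = 6186L, "Closed ISR" = 6198L,
  "Open RoO" = 5797L
)

#' Published start/end cross-tabulation for 6-word ISR
#'
#' A packaged transcription of the printed frequency distribution of
#' start-sequence length by end-sequence length for four immediate serial
#' recall conditions with 6-word lists: a closed stimulus set
#' (`"Closed ISR"`), an open set (`"Open ISR"`), an open set with explicit
#' `"blank"` omission marks (`"Blanks"`), and reconstruction of order
#' (`"Open RoO"`).
#'
#' @param condition One of `"Closed ISR"`, `"Open ISR"`, `"Blanks"`,
#'   `"Open RoO"`, or `NULL` for the long tibble of all four blocks.
#' @return For a single condition, a `startend_table` whose attributes also
#'   record `text_total`, the trial count reported in the running text
#'   (which for three conditions disagrees with the block sum; the block
#'   sums reproduce the printed proportions and are used for all derived
#'   quantities). For `NULL`, a tibble with columns `condition`,
#'   `start_len`, `end_len`, `count` covering every printed cell.
#' @examples
#' tab <- osth_dennis_table1("Open RoO")
#' proportion_complete_correct(tab)
#' @export
osth_dennis_table1 <- function(condition = NULL) {
  path <- system.file("extdata", "osth_dennis_2015_table1.csv",
                      package = "recallseq", mustWork = TRUE)
  all_cells <- readr::read_csv(
    path,
    col_types = readr::cols(condition = "c", start_len = "i",
                            end_len = "i", count = "i"),
    progress = FALSE
  )
  if (is.null(condition)) return(all_cells)
  if (!condition %in% .table1_conditions) {
    stop("condition must be one of: ",
         paste(.table1_conditions, collapse = ", "), call. = FALSE)
  }
  block <- all_cells |> dplyr::filter(.data$condition == !!condition)
  grid <- tidyr::expand_grid(start_len = 0:6, end_len = 0:6) |>
    dplyr::left_join(block |> dplyr::select(-"condition"),
                     by = c("start_len", "end_len")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
  out <- new_startend_table(grid, list_length = 6L,
                            n_complete = grid$count[grid$start_len == 6L &
                                                      grid$end_len == 0L],
                            label = condition)
  attr(out, "text_total") <- unname(.table1_text_totals[condition])
  out
}
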