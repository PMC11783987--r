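# Trial data model -----------------------------------------------------------
#
# A trial set is a tibble with one row per trial:
#   trial_id     character, unique within the set
#   condition    character label (free text)
#   list_length  integer n
#   presented    list-column of n distinct item tokens (input order)
#   recalled     list-column of raw response tokens (output order; may be
#                empty). Tokens equal to the reserved omission token mark an
#                explicit skip ("blank"); tokens absent from `presented` are
#                intrusions. Everything is 1-based: input serial positions
#                run 1..n, output positions are the rank in `recalled`.
# The tibble carries an "omission_token" attribute (default "blank").

new_trialset <- function(df, omission_token = "blank") {
  df <- tibble::as_tibble(df)
  attr(df, "omission_token") <- omission_token
  class(df) <- c("recall_trials", class(df))
  df
}

#' The reserved omission token of a trial set
#'
#' @param trials A trial tibble as returned by [parse_letter_trial()],
#'   [read_trials()] or [generate_trials()].
#' @return A single string (default `"blank"`).
#' @export
omission_token <- function(trials) {
  attr(trials, "omission_token") %||% "blank"
}

#' Parse trials written in letter notation
#'
#' In letter notation an n-item list is written as n distinct characters
#' (e.g. `"ABCDEFGH"`) and a recall protocol as the ordered characters the
#' participant produced (e.g. `"FGHCABG"`). Characters absent from the
#' presented string are intrusions; the reserved `omission_char` marks an
#' explicit skip. Both arguments are vectorised.
#'
#' @param presented Character vector of presented lists, one string per
#'   trial; each string must have pairwise-distinct characters.
#' @param recalled Character vector of recall protocols (may be `""`).
#' @param trial_id Optional character vector of identifiers; defaults to
#'   `"t1", "t2", ...`.
#' @param condition Condition label(s), recycled across trials.
#' @param omission_char Single character reserved for omission marks
#'   (default `"-"`).
#' @return A trial tibble (one row per trial) with list-columns `presented`
#'   and `recalled`.
#' @examples
#' parse_letter_trial("ABCDEFGH", "FGHCABG")
#' @export
parse_letter_trial <- function(presented, recalled, trial_id = NULL,
                               condition = "unspecified",
                               omission_char = "-") {
  stopifnot(is.character(presented), is.character(recalled),
            length(presented) == length(recalled))
  n_trials <- length(presented)
  if (is.null(trial_id)) trial_id <- paste0("t", seq_len(n_trials))
  condition <- rep_len(condition, n_trials)
  pres <- stringr::str_split(presented, "")
  rec <- lapply(stringr::str_split(recalled, ""),
                function(x) x[x != ""])
  dup <- vapply(pres, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    stop("duplicate characters in presented list(s): ",
         paste(presented[dup], collapse = ", "), call. = FALSE)
  }
  if (any(vapply(pres, function(p) omission_char %in% p, logical(1)))) {
    stop("the omission character ", dQuote(omission_char),
         " may not appear in a presented list", call. = FALSE)
  }
  new_trialset(
    tibble::tibble(
      trial_id = as.character(trial_id),
      condition = condition,
      list_length = lengths(pres),
      presented = pres,
      recalled = rec
    ),
    omission_token = omission_char
  )
}

#' Render trials back to letter notation
#'
#' Inverse of [parse_letter_trial()]: concatenates the stored raw tokens,
#' reproducing the original strings exactly.
#'
#' @inheritParams omission_token
#' @return A tibble with columns `trial_id`, `presented`, `recalled`.
#' @export
render_letter_trial <- function(trials) {
  tibble::tibble(
    trial_id = trials$trial_id,
    presented = vapply(trials$presented, paste, "", collapse = ""),
    recalled = vapply(trials$recalled, paste, "", collapse = "")
  )
}

#' Expand trials into one row per recall event
#'
#' @inheritParams omission_token
#' @return A tibble with columns `trial_id`, `output_index` (1-based rank of
#'   the event), `raw_token`, `kind` (`"item"`, `"intrusion"` or
#'   `"omission"`), and `input_position` (1..n for items, `NA` otherwise).
#' @examples
#' recall_events(parse_letter_trial("ABCD", "ABXD"))
#' @export
recall_events <- function(trials) {
  tok <- omission_token(trials)
  rows <- purrr::pmap(
    list(trials$trial_id, trials$presented, trials$recalled),
    function(id, p, r) {
      pos <- tokens_to_pos(r, p, tok)
      kind <- dplyr::case_when(
        is.na(pos) ~ "intrusion",
        pos == 0L ~ "omission",
        TRUE ~ "item"
      )
      tibble::tibble(
        trial_id = id,
        output_index = seq_along(r),
        raw_token = r,
        kind = kind,
        input_position = ifelse(kind == "item", pos, NA_integer_)
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Validate trials against the data-model invariants
#'
#' Checks that presented tokens are distinct, `list_length` matches the
#' presented count, trial ids are unique, and recall protocols are
#' well-formed. Issues are returned, not raised; trials with more recall
#' events than list items are flagged but accepted (perseveration is real
#' data).
#'
#' @inheritParams omission_token
#' @return A tibble with columns `trial_id` and `issue`; zero rows when all
#'   invariants hold.
#' @export
validate_trials <- function(trials) {
  issues <- list()
  add <- function(id, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(trial_id = id, issue = msg)
  }
  dup_id <- trials$trial_id[duplicated(trials$trial_id)]
  for (id in unique(dup_id)) add(id, "duplicated trial_id")
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    p <- trials$presented[[i]]
    r <- trials$recalled[[i]]
    if (anyDuplicated(p)) {
      add(id, paste0("duplicate presented token: ",
                     paste(unique(p[duplicated(p)]), collapse = ", ")))
    }
    if (trials$list_length[i] != length(p)) {
      add(id, sprintf("list_length is %d but %d tokens were presented",
                      trials$list_length[i], length(p)))
    }
    if (omission_token(trials) %in% p) {
      add(id, "presented list contains the reserved omission token")
    }
    if (length(r) > length(p)) {
      add(id, sprintf("more recall events (%d) than list items (%d)",
                      length(r), length(p)))
    }
  }
  if (length(issues) == 0L) {
    return(tibble::tibble(trial_id = character(0), issue = character(0)))
  }
  dplyr::bind_rows(issues)
}

#' Read recall trials from disk
#'
#' Two plain-text formats are supported. `"tsv"`: UTF-8, tab-separated, one
#' trial per row, columns `trial_id`, `condition`, `list_length`,
#' `presented` (semicolon-joined item tokens) and `recalled`
#' (semicolon-joined response tokens, possibly empty; the reserved omission
#' token marks a skip). `"letters"`: two tab-separated columns per line,
#' presented letters and recalled letters.
#'
#' Malformed rows are reported with their line numbers and abort the read.
#'
#' @param path File path.
#' @param format `"tsv"` or `"letters"`.
#' @param omission_token Reserved skip token for the TSV format.
#' @param condition Condition label used for letters files (which carry
#'   none).
#' @inheritParams parse_letter_trial
#' @return A trial tibble.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, format = c("tsv", "letters"),
                        omission_token = "blank", omission_char = "-",
                        condition = "unspecified") {
  format <- match.arg(format)
  if (format == "letters") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no trials found in ", path, call. = FALSE)
    parts <- stringr::str_split(lines, "\t")
    pres <- vapply(parts, `[`, "", 1L)
    rec <- vapply(parts, function(x) if (length(x) >= 2L) x[2L] else "", "")
    return(parse_letter_trial(pres, rec, condition = condition,
                              omission_char = omission_char))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("trial_id", "condition", "list_length", "presented", "recalled")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no trials found in ", path, call. = FALSE)
  split_tokens <- function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  }
  pres <- lapply(df$presented, split_tokens)
  rec <- lapply(df$recalled, split_tokens)
  n <- suppressWarnings(as.integer(df$list_length))
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (is.na(n[i])) {
      problems <- c(problems, sprintf("line %d: non-integer list_length", line))
      next
    }
    if (anyDuplicated(pres[[i]])) {
      problems <- c(problems, sprintf(
        "line %d: duplicate presented token %s", line,
        dQuote(pres[[i]][duplicated(pres[[i]])][1])))
    }
    if (n[i] != length(pres[[i]])) {
      problems <- c(problems, sprintf(
        "line %d: list_length %d disagrees with %d presented tokens",
        line, n[i], length(pres[[i]])))
    }
  }
  if (length(problems)) {
    stop("malformed trial file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  new_trialset(
    tibble::tibble(
      trial_id = df$trial_id,
      condition = df$condition,
      list_length = n,
      presented = pres,
      recalled = rec
    ),
    omission_token = omission_token
  )
}

#' Write recall trials to disk
#'
#' Serialises a trial tibble in the TSV trial format (or letter notation).
#' `read_trials(write_trials(x))` reproduces `x` token for token.
#'
#' @inheritParams omission_token
#' @param path Output file path.
#' @param format `"tsv"` or `"letters"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, format = c("tsv", "letters")) {
  format <- match.arg(format)
  if (format == "letters") {
    rendered <- render_letter_trial(trials)
    writeLines(paste(rendered$presented, rendered$recalled, sep = "\t"), path)
    return(invisible(path))
  }
  out <- tibble::tibble(
    trial_id = trials$trial_id,
    condition = trials$condition,
    list_length = trials$list_length,
    presented = vapply(trials$presented, paste, "", collapse = ";"),
    recalled = vapply(trials$recalled, paste, "", collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
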