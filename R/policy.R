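#' Sequence-detection policy
#'
#' Controls how start- and end-sequences are detected in a recall protocol.
#' A start-sequence is a run of recalls from consecutive input positions
#' `1, 2, ..., s` beginning with the first list item; an end-sequence is a
#' run `n-e+1, ..., n` terminating with the last list item. Runs may sit
#' anywhere in the output.
#'
#' @param occurrence `"first"` (default): only the first recall of each list
#'   item is eligible to join a sequence, and later recalls are labelled
#'   repetitions, so no physical response can belong to two sequences.
#'   `"any"`: every recall of a list item is eligible, which permits
#'   overlapping start- and end-sequences realised through repeated items
#'   (needed to replay published cross-tabulations whose cells imply
#'   `s + e > n`).
#' @param break_intrusion,break_omission Should intrusion / omission-mark
#'   events interrupt run contiguity? Defaults `TRUE` (a run is a run of
#'   consecutive response events). Setting either to `FALSE` makes that
#'   event kind transparent, for sensitivity analysis.
#'
#' @details Ties between candidate runs are resolved deterministically:
#'   the longest run wins, and among equal lengths the run with the
#'   earliest output index wins.
#'
#' @return A list with class `"sequence_policy"`.
#' @examples
#' sequence_policy()
#' sequence_policy("any")
#' @export
sequence_policy <- function(occurrence = c("first", "any"),
                            break_intrusion = TRUE,
                            break_omission = TRUE) {
  occurrence <- match.arg(occurrence)
  structure(
    list(occurrence = occurrence,
         break_intrusion = isTRUE(break_intrusion),
         break_omission = isTRUE(break_omission)),
    class = "sequence_policy"
  )
}

#' @export
print.sequence_policy <- function(x, ...) {
  cat("<sequence_policy>\n")
  cat("  occurrence rule :", x$occurrence, "\n")
  cat("  runs broken by  :",
      paste(c(if (x$break_intrusion) "intrusion",
              if (x$break_omission) "omission"), collapse = ", "), "\n")
  invisible(x)
}

as_sequence_policy <- function(policy) {
  if (inherits(policy, "sequence_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1L) {
    return(sequence_policy(policy))
  }
  stop("`policy` must be a sequence_policy() or \"first\"/\"any\"",
       call. = FALSE)
}
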