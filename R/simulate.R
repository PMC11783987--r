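# Synthetic recall-protocol generator ----------------------------------------

.norm_dist <- function(x, support, what) {
  if (is.null(x)) return(NULL)
  if (length(x) != length(support) || any(x < 0) || sum(x) <= 0) {
    stop(what, " must be a non-negative vector over lengths ",
         support[1], "..", support[length(support)], call. = FALSE)
  }
  x / sum(x)
}

#' Configuration for the synthetic protocol generator
#'
#' The generator emulates the statistical structure of 6-word immediate
#' serial recall protocols: with probability `p_complete` a trial is the
#' completely correct sequence `1..n`; otherwise a start-sequence length s,
#' an end-sequence length e and an Other count k are sampled and the
#' protocol is assembled as `[1..s] + [k shuffled Other items (+ noise)] +
#' [n-e+1..n]`. No cognitive process is modelled; only output-protocol
#' statistics are reproduced.
#'
#' @param n_trials Number of trials.
#' @param list_length List length n (2..15).
#' @param p_complete Probability of a completely correct trial. Default
#'   0.383, the completely-correct rate of a closed-set 6-word ISR
#'   condition.
#' @param start_dist Probability vector over start lengths `0..n-1`
#'   (default uniform). Start lengths of n arise only via `p_complete`.
#' @param end_dist Probability vector over end lengths `0..n-1` (default
#'   geometric-decaying, end-sequences are typically short). Truncated and
#'   renormalised to the feasible range `0..n-1-s` after s is drawn.
#' @param other_dist Probability vector over Other counts `0..n` (default
#'   mass 0.5/0.3/0.2 on 0/1/2). Truncated to the feasible counts given
#'   (s, e) and, in strict mode, to counts for which a non-extending
#'   arrangement exists.
#' @param intrusion_rate,repetition_rate,omission_rate Per-gap probability
#'   of injecting an intrusion token, a repetition of an already-output
#'   item, or an explicit omission mark into the middle (non-sequence)
#'   region of the protocol.
#' @param strict Strict mode: Other arrangements that would change the
#'   annotated (s, e) -- e.g. item s+1 landing immediately after the start
#'   run -- are rejected and resampled, so the scorer recovers the sampled
#'   lengths exactly. With `strict = FALSE` such "lucky positioning" is
#'   allowed and annotated sequence lengths can only exceed the sampled
#'   ones.
#' @param condition Condition label attached to the trials.
#' @return A list with class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_trials = 100L,
                             list_length = 6L,
                             p_complete = 0.383,
                             start_dist = NULL,
                             end_dist = NULL,
                             other_dist = NULL,
                             intrusion_rate = 0,
                             repetition_rate = 0,
                             omission_rate = 0,
                             strict = TRUE,
                             condition = "synthetic") {
  n <- as.integer(list_length)
  if (n < 2L || n > 15L) stop("list_length must be in 2..15", call. = FALSE)
  if (p_complete < 0 || p_complete > 1) {
    stop("p_complete must be in [0, 1]", call. = FALSE)
  }
  if (is.null(start_dist)) start_dist <- rep(1, n)           # over 0..n-1
  if (is.null(end_dist)) end_dist <- 0.5 ^ (0:(n - 1))       # over 0..n-1
  if (is.null(other_dist)) {
    other_dist <- c(0.5, 0.3, 0.2, rep(0, n - 2))            # over 0..n
  }
  structure(
    list(
      n_trials = as.integer(n_trials), list_length = n,
      p_complete = p_complete,
      start_dist = .norm_dist(start_dist, 0:(n - 1), "start_dist"),
      end_dist = .norm_dist(end_dist, 0:(n - 1), "end_dist"),
      other_dist = .norm_dist(other_dist, 0:n, "other_dist"),
      intrusion_rate = intrusion_rate,
      repetition_rate = repetition_rate,
      omission_rate = omission_rate,
      strict = isTRUE(strict),
      condition = condition
    ),
    class = "synthetic_config"
  )
}

.sample_len <- function(dist, support, feasible) {
  p <- dist
  p[!(support %in% feasible)] <- 0
  if (sum(p) <= 0) return(NA_integer_)
  support[sample.int(length(support), 1L, prob = p)]
}

# Other items may never include the boundary items already used by the
# sequences; item 1 (when s = 0) and item n (when e = 0) are excluded
# because recalling either forces a sequence of length >= 1 under the
# content-based definition.
.other_pool <- function(s, e, n) {
  if (s + 1L > n - e) return(integer(0))
  pool <- seq.int(s + 1L, n - e)
  if (s == 0L) pool <- setdiff(pool, 1L)
  if (e == 0L) pool <- setdiff(pool, n)
  pool
}

# Feasible Other counts k for (s, e). In strict mode a k is feasible only
# if some arrangement leaves (s, e) unchanged: the first middle item must
# not be s+1 (run extension) and the last must not be n-e.
.feasible_k <- function(s, e, n, strict) {
  pool <- .other_pool(s, e, n)
  m <- length(pool)
  if (!strict) return(0:m)
  cf <- if (s > 0L) s + 1L else NA_integer_
  cl <- if (e > 0L) n - e else NA_integer_
  ks <- 0L
  pool1 <- setdiff(pool, c(cf, cl))
  if (length(pool1) > 0L) ks <- c(ks, 1L)
  if (m >= 2L) {
    coincide <- !is.na(cf) && !is.na(cl) && cf == cl
    for (k in 2:m) {
      if (coincide && k == 2L && (m - 1L) < 2L) next
      ks <- c(ks, k)
    }
  }
  ks
}

.intrusion_tokens <- function(i) sprintf("x%d", i)

# Assemble one non-complete protocol for sampled (s, e, k).
.assemble_protocol <- function(s, e, k, n, config, policy, max_tries = 200L) {
  pool <- .other_pool(s, e, n)
  cf <- if (s > 0L) s + 1L else NA_integer_
  cl <- if (e > 0L) n - e else NA_integer_
  for (try in seq_len(max_tries)) {
    others <- if (k > 0L) sample(pool, k) else integer(0)
    if (config$strict && k >= 1L) {
      if (k == 1L && others %in% c(cf, cl)) next
      if (!is.na(cf) && others[1] == cf) next
      if (!is.na(cl) && others[k] == cl) next
    }
    core_start <- if (s > 0L) seq_len(s) else integer(0)
    core_end <- if (e > 0L) seq.int(n - e + 1L, n) else integer(0)
    # inject noise into the middle region: walk the k+1 gaps around the
    # Other items and drop in intrusions / omission marks / repetitions
    middle <- list()
    emitted <- core_start
    intr_id <- 0L
    for (g in seq_len(k + 1L)) {
      if (config$intrusion_rate > 0 &&
          stats::runif(1) < config$intrusion_rate) {
        intr_id <- intr_id + 1L
        middle <- c(middle, list(list(kind = "intrusion", id = intr_id)))
      }
      if (config$omission_rate > 0 &&
          stats::runif(1) < config$omission_rate) {
        middle <- c(middle, list(list(kind = "omission")))
      }
      if (config$repetition_rate > 0 && length(emitted) > 0L &&
          stats::runif(1) < config$repetition_rate) {
        middle <- c(middle, list(list(kind = "repeat",
                                      item = sample(emitted, 1L))))
      }
      if (g <= k) {
        middle <- c(middle, list(list(kind = "item", item = others[g])))
        emitted <- c(emitted, others[g])
      }
    }
    protocol <- list(start = core_start, middle = middle, end = core_end,
                     others = others)
    if (!config$strict) return(protocol)
    # strict: verify with the actual scorer that (s, e) are preserved
    pos <- .protocol_pos(protocol, n)
    sc <- scan_protocol(pos, n, policy)
    if (sc$start_len == s && sc$end_len == e) return(protocol)
  }
  stop(sprintf(
    "strict mode could not realise (s = %d, e = %d, k = %d) for n = %d",
    s, e, k, n), call. = FALSE)
}

# integer protocol (0 = omission, NA = intrusion) for a structured protocol
.protocol_pos <- function(protocol, n) {
  mid <- vapply(protocol$middle, function(ev) {
    switch(ev$kind,
           item = as.integer(ev$item),
           "repeat" = as.integer(ev$item),
           omission = 0L,
           intrusion = NA_integer_)
  }, integer(1))
  c(protocol$start, mid, protocol$end)
}

.protocol_tokens <- function(protocol, items, omission_tok) {
  mid <- vapply(protocol$middle, function(ev) {
    switch(ev$kind,
           item = items[ev$item],
           "repeat" = items[ev$item],
           omission = omission_tok,
           intrusion = .intrusion_tokens(ev$id))
  }, character(1))
  c(items[protocol$start], mid, items[protocol$end])
}

#' Generate synthetic recall trials
#'
#' Samples trials under a [synthetic_config()]. Item tokens are
#' `LETTERS[1:n]`; intrusion tokens come from a disjoint alphabet
#' (`"x1"`, `"x2"`, ...) so parsing is unambiguous. The sampled ground
#' truth is attached as columns `intended_start`, `intended_end`,
#' `intended_other`: in strict mode the scorer recovers these exactly, and
#' with `strict = FALSE` annotated lengths can exceed them through lucky
#' positioning of Other items, never fall below.
#'
#' If a sampled (s, e, k) triple is jointly infeasible (`s + e + k > n`,
#' or no valid Other set in strict mode), k is resampled over its feasible
#' range first, then e, preserving the start-length distribution
#' preferentially.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; identical (config, seed) gives an identical
#'   trial set.
#' @param policy Policy used for strict-mode verification.
#' @return A trial tibble with the ground-truth columns described above.
#' @examples
#' generate_trials(synthetic_config(n_trials = 5), seed = 1)
#' @export
generate_trials <- function(config = synthetic_config(), seed = 1L,
                            policy = sequence_policy()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$list_length
  items <- LETTERS[seq_len(n)]
  omission_tok <- "blank"
  rows <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    if (stats::runif(1) < config$p_complete) {
      rows[[i]] <- list(recalled = items, s = n, e = 0L, k = 0L)
      next
    }
    s <- .sample_len(config$start_dist, 0:(n - 1), 0:(n - 1))
    e <- .sample_len(config$end_dist, 0:(n - 1), 0:(n - 1L - s))
    if (is.na(e)) e <- 0L
    feas_k <- .feasible_k(s, e, n, config$strict)
    k <- .sample_len(config$other_dist, 0:n, feas_k)
    if (is.na(k)) k <- 0L
    protocol <- .assemble_protocol(s, e, k, n, config, policy)
    rows[[i]] <- list(
      recalled = .protocol_tokens(protocol, items, omission_tok),
      s = s, e = e, k = length(protocol$others)
    )
  }
  new_trialset(
    tibble::tibble(
      trial_id = sprintf("s%05d", seq_len(config$n_trials)),
      condition = config$condition,
      list_length = n,
      presented = rep(list(items), config$n_trials),
      recalled = lapply(rows, `[[`, "recalled"),
      intended_start = vapply(rows, function(r) as.integer(r$s), integer(1)),
      intended_end = vapply(rows, function(r) as.integer(r$e), integer(1)),
      intended_other = vapply(rows, function(r) as.integer(r$k), integer(1))
    ),
    omission_token = omission_tok
  )
}

#' Realise a start/end cross-tabulation as concrete trials
#'
#' Builds exactly `sum(count)` trials whose annotations reproduce the input
#' table cell for cell under the same policy. Cell realisations:
#' * `(n, 0)`: the completely correct sequence `1..n`.
#' * `s + e < n`: `[1..s] + Others + [n-e+1..n]` (Others placed strictly so
#'   the annotation is preserved; defaults to none, since published tables
#'   do not report Other counts per cell).
#' * `s + e = n`, `0 < s < n`: the two runs would fuse into the complete
#'   sequence, so a single repetition of item 1 is inserted between them as
#'   a run separator.
#' * `s + e > n` (overlap cells): `[1..s] + [n-e+1..n]` with the boundary
#'   items output twice; feasible only under the `"any"` occurrence policy
#'   (an error names the offending cell under `"first"`).
#'
#' @param table A `startend_table` (e.g. one block of
#'   [osth_dennis_table1()], or built by [crosstab_start_end()]).
#' @param policy Occurrence policy the trials must annotate under.
#' @param other_dist Optional probability vector over Other counts `0..n`
#'   applied to cells with `s + e < n`; Others are inserted strictly.
#' @param seed Seed for Other sampling (unused when `other_dist` is NULL).
#' @param condition Condition label; defaults to the table's label.
#' @return A trial tibble of `sum(count)` trials.
#' @export
generate_from_crosstab <- function(table, policy = sequence_policy("any"),
                                   other_dist = NULL, seed = 1L,
                                   condition = NULL) {
  stopifnot(inherits(table, "startend_table"))
  policy <- as_sequence_policy(policy)
  n <- attr(table, "list_length")
  items <- LETTERS[seq_len(n)]
  condition <- condition %||% attr(table, "label") %||% "replay"
  set.seed(seed)
  cells <- tibble::as_tibble(table) |> dplyr::filter(.data$count > 0L)
  feas_config <- synthetic_config(list_length = n, strict = TRUE,
                                  condition = condition)
  recalls <- list()
  intended <- list()
  for (r in seq_len(nrow(cells))) {
    s <- cells$start_len[r]
    e <- cells$end_len[r]
    cnt <- cells$count[r]
    if (e >= n) {
      stop(sprintf(
        paste0("cell (start = %d, end = %d) is infeasible: an end-sequence ",
               "of length n is the complete sequence and lands in (n, 0)"),
        s, e), call. = FALSE)
    }
    if (s + e > n && policy$occurrence == "first") {
      stop(sprintf(
        paste0("cell (start = %d, end = %d) implies an overlapping ",
               "sequence (s + e > n = %d) and is infeasible under the ",
               "first-occurrence policy; use sequence_policy(\"any\")"),
        s, e, n), call. = FALSE)
    }
    for (j in seq_len(cnt)) {
      rec <- if (s == n && e == 0L) {
        items
      } else if (s + e > n) {
        c(items[seq_len(s)], items[seq.int(n - e + 1L, n)])
      } else if (s + e == n) {
        # a repeated item separates the two runs so they cannot fuse into
        # 1..n. Item 1 is safe except when s = 1 under the any-occurrence
        # policy (the repeat would anchor a full run itself); there a
        # repeat of item n is used instead.
        sep <- if (policy$occurrence == "any" && s == 1L) n else 1L
        if (policy$occurrence == "any" && s == 1L && n == 2L) {
          stop("cell (start = 1, end = 1) for n = 2 has no realisation ",
               "under the any-occurrence policy", call. = FALSE)
        }
        c(items[seq_len(s)], items[sep], items[seq.int(n - e + 1L, n)])
      } else {
        k <- 0L
        if (!is.null(other_dist)) {
          feas <- .feasible_k(s, e, n, strict = TRUE)
          k <- .sample_len(.norm_dist(other_dist, 0:n, "other_dist"),
                           0:n, feas)
          if (is.na(k)) k <- 0L
        }
        protocol <- .assemble_protocol(s, e, k, n, feas_config, policy)
        .protocol_tokens(protocol, items, "blank")
      }
      recalls[[length(recalls) + 1L]] <- rec
      intended[[length(intended) + 1L]] <- c(s, e)
    }
  }
  n_tr <- length(recalls)
  if (n_tr == 0L) {
    return(new_trialset(tibble::tibble(
      trial_id = character(0), condition = character(0),
      list_length = integer(0), presented = list(), recalled = list(),
      intended_start = integer(0), intended_end = integer(0)
    )))
  }
  new_trialset(
    tibble::tibble(
      trial_id = sprintf("r%05d", seq_len(n_tr)),
      condition = condition,
      list_length = n,
      presented = rep(list(items), n_tr),
      recalled = recalls,
      intended_start = vapply(intended, function(x) as.integer(x[1]),
                              integer(1)),
      intended_end = vapply(intended, function(x) as.integer(x[2]),
                            integer(1))
    ),
    omission_token = "blank"
  )
}
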