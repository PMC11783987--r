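# Internal scanning engine.
#
# A recall protocol is represented internally as an integer vector `pos`,
# one entry per recall event in output order:
#   1..n  -> recall of the list item presented at that input position
#   0     -> an explicit omission mark ("blank")
#   NA    -> an intrusion (a response token not in the presented list)
#
# All positions are 1-based: input serial positions run 1..n, output
# positions are the 1-based rank of the event in the protocol.

# Eligibility of each event to take part in a sequence. Under the default
# "first" occurrence rule only the first recall of each list item is
# eligible; later recalls of the same item are repetitions. Under "any",
# every item event is eligible (needed to realise cross-tabulation cells
# with overlapping start- and end-sequences).
.event_flags <- function(pos, policy) {
  is_item <- !is.na(pos) & pos > 0L
  first_occ <- logical(length(pos))
  if (any(is_item)) {
    first_occ[is_item] <- !duplicated(pos[is_item])
  }
  eligible <- if (policy$occurrence == "first") first_occ else is_item
  # transparent events are skipped when extending a run; blocking events
  # terminate it. Item events that do not match the next expected position
  # always terminate a run.
  transparent <- (is.na(pos) & !policy$break_intrusion) |
    (!is.na(pos) & pos == 0L & !policy$break_omission)
  list(is_item = is_item, first_occ = first_occ, eligible = eligible,
       transparent = transparent)
}

# Maximal forward run 1,2,...,s anchored at an eligible recall of item 1,
# located anywhere in the output. Longest run wins; ties break to the
# earliest output index.
.scan_start <- function(pos, n, flags) {
  L <- length(pos)
  best <- integer(0)
  anchors <- which(flags$eligible & pos == 1L)
  for (a in anchors) {
    members <- a
    expect <- 2L
    j <- a + 1L
    while (j <= L) {
      if (flags$transparent[j]) {
        j <- j + 1L
        next
      }
      if (flags$eligible[j] && !is.na(pos[j]) && pos[j] == expect) {
        members <- c(members, j)
        expect <- expect + 1L
        j <- j + 1L
      } else {
        break
      }
    }
    if (length(members) > length(best)) best <- members
  }
  best
}

# Maximal forward run n-e+1,...,n terminating with an eligible recall of
# item n. Events already claimed by the start-sequence are excluded (start
# priority); they block extension like any non-matching item event.
.scan_end <- function(pos, n, flags, start_members) {
  L <- length(pos)
  in_start <- logical(L)
  in_start[start_members] <- TRUE
  best <- integer(0)
  anchors <- which(flags$eligible & !in_start & pos == n)
  for (a in anchors) {
    members <- a
    expect <- n - 1L
    j <- a - 1L
    while (j >= 1L && expect >= 1L) {
      if (flags$transparent[j]) {
        j <- j - 1L
        next
      }
      if (flags$eligible[j] && !in_start[j] && !is.na(pos[j]) &&
          pos[j] == expect) {
        members <- c(j, members)
        expect <- expect - 1L
        j <- j - 1L
      } else {
        break
      }
    }
    if (length(members) > length(best)) {
      best <- members
    } else if (length(members) == length(best) && length(best) &&
               members[1] < best[1]) {
      best <- members
    }
  }
  best
}

# Full per-protocol annotation. Returns sequence lengths, spans, per-event
# labels, and the Other-item inventory used by the null model.
scan_protocol <- function(pos, n, policy = sequence_policy()) {
  L <- length(pos)
  labels <- character(L)
  complete <- (L == n) && !anyNA(pos) && all(pos == seq_len(n))
  if (complete) {
    # complete-correct convention: the whole protocol is one start-sequence
    # of length n and the end-sequence length is 0.
    labels[] <- "start"
    return(list(
      start_len = n, end_len = 0L,
      start_span = if (n > 0L) c(1L, n) else NULL, end_span = NULL,
      labels = labels, complete = TRUE,
      other_positions = integer(0),
      n_other = 0L, n_repetition = 0L, n_intrusion = 0L, n_omission = 0L
    ))
  }
  flags <- .event_flags(pos, policy)
  start_members <- .scan_start(pos, n, flags)
  end_members <- .scan_end(pos, n, flags, start_members)
  labels[start_members] <- "start"
  labels[end_members] <- "end"
  unlabelled <- which(labels == "")
  for (j in unlabelled) {
    if (is.na(pos[j])) {
      labels[j] <- "intrusion"
    } else if (pos[j] == 0L) {
      labels[j] <- "omission"
    }
  }
  # Remaining item events: the earliest unclaimed recall of an item whose
  # value is not already inside a sequence is an Other item; every further
  # recall of an already-output item is a repetition.
  seq_values <- pos[c(start_members, end_members)]
  item_left <- which(labels == "" & flags$is_item)
  seen <- integer(0)
  for (j in item_left) {
    v <- pos[j]
    if (v %in% seq_values || v %in% seen) {
      labels[j] <- "repetition"
    } else {
      labels[j] <- "other"
      seen <- c(seen, v)
    }
  }
  other_idx <- which(labels == "other")
  list(
    start_len = length(start_members),
    end_len = length(end_members),
    start_span = if (length(start_members)) range(start_members) else NULL,
    end_span = if (length(end_members)) range(end_members) else NULL,
    labels = labels,
    complete = FALSE,
    other_positions = pos[other_idx],
    n_other = length(other_idx),
    n_repetition = sum(labels == "repetition"),
    n_intrusion = sum(labels == "intrusion"),
    n_omission = sum(labels == "omission")
  )
}

# Map raw response tokens onto the integer protocol representation.
tokens_to_pos <- function(recalled, presented, omission_token) {
  if (length(recalled) == 0L) return(integer(0))
  p <- match(recalled, presented)
  p[!is.na(p)] <- as.integer(p[!is.na(p)])
  p[recalled == omission_token] <- 0L
  as.integer(p)
}
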