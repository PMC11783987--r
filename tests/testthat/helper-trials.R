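# shared fixtures built in code

lt <- function(presented, recalled, ...) {
  parse_letter_trial(presented, recalled, ...)
}

# the four worked IFR protocols for the 8-item list ABCDEFGH
worked_trials <- function() {
  lt(rep("ABCDEFGH", 4), c("FGHCABG", "HGABCE", "ABCFEGH", "GFAC"),
     trial_id = c("w1", "w2", "w3", "w4"))
}

# numeric shorthand: build one trial over list 1..n from a vector of input
# positions (0 = omission mark, NA = intrusion)
pos_trial <- function(pos, n, trial_id = "p1") {
  items <- LETTERS[seq_len(n)]
  tokens <- vapply(seq_along(pos), function(i) {
    if (is.na(pos[i])) "x1" else if (pos[i] == 0) "blank" else items[pos[i]]
  }, "")
  if (length(pos) == 0L) tokens <- character(0)
  tr <- tibble::tibble(
    trial_id = trial_id, condition = "test", list_length = n,
    presented = list(items), recalled = list(tokens)
  )
  attr(tr, "omission_token") <- "blank"
  class(tr) <- c("recall_trials", class(tr))
  tr
}

small_startend_table <- function(cells, n = 6L, label = "custom") {
  grid <- tidyr::expand_grid(start_len = 0:n, end_len = 0:n)
  grid$count <- 0L
  for (cell in cells) {
    hit <- grid$start_len == cell[1] & grid$end_len == cell[2]
    grid$count[hit] <- as.integer(cell[3])
  }
  out <- grid
  attr(out, "list_length") <- as.integer(n)
  attr(out, "n_trials") <- sum(out$count)
  attr(out, "label") <- label
  class(out) <- c("startend_table", class(out))
  out
}
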