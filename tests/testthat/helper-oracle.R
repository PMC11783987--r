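# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's scanning implementation: sequences are found by
# enumerating every contiguous output window, and null-model expectations
# by enumerating every permutation of the Other items.

# Integer protocol notation shared with the package: 1..n = list item at
# that input position, 0 = omission mark, NA = intrusion.

oracle_scan <- function(pos, n, occurrence = "first",
                        break_intrusion = TRUE, break_omission = TRUE) {
  L <- length(pos)
  if (L == n && !anyNA(pos) && all(pos == seq_len(n))) {
    return(list(start_len = n, end_len = 0L))
  }
  is_item <- !is.na(pos) & pos > 0L
  fo <- rep(FALSE, L)
  fo[which(is_item)[!duplicated(pos[is_item])]] <- TRUE
  elig <- if (occurrence == "first") fo else is_item
  transparent <- (is.na(pos) & !break_intrusion) |
    (!is.na(pos) & pos == 0L & !break_omission)

  window_items <- function(a, b, start_set = NULL) {
    idx <- a:b
    items <- idx[is_item[idx]]
    if (length(items) == 0L) return(NULL)
    if (items[1] != a || items[length(items)] != b) return(NULL)
    nonitems <- setdiff(idx, items)
    if (length(nonitems) && !all(transparent[nonitems])) return(NULL)
    if (!all(elig[items])) return(NULL)
    if (!is.null(start_set) && any(start_set[items])) return(NULL)
    items
  }

  best_s <- integer(0)
  for (a in seq_len(L)) {
    if (!is_item[a]) next
    for (b in a:L) {
    if (!is_item[b]) next
    items <- window_items(a, b)
    if (is.null(items)) next
    if (!identical(as.integer(pos[items]), seq_along(items))) next
    if (length(items) > length(best_s)) best_s <- items
  }
  }
  start_set <- rep(FALSE, L)
  start_set[best_s] <- TRUE
  best_e <- integer(0)
  for (a in seq_len(L)) {
    if (!is_item[a]) next
    for (b in a:L) {
    if (!is_item[b]) next
    items <- window_items(a, b, start_set)
    if (is.null(items)) next
    le <- length(items)
    if (!identical(as.integer(pos[items]), seq.int(n - le + 1L, n))) next
    if (le > length(best_e)) {
      best_e <- items
    } else if (le == length(best_e) && le > 0L && items[1] < best_e[1]) {
      best_e <- items
    }
  }
  }
  list(start_len = length(best_s), end_len = length(best_e))
}

# all permutations of a small vector
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# exact null-model expectation by enumerating every arrangement of the
# Other items over the middle slots (k <= 5); returns the error-only
# normalised gradient as a named vector "input:output" -> proportion.
oracle_null_gradient <- function(annotations) {
  n <- unique(annotations$list_length)
  stopifnot(length(n) == 1L)
  mass <- matrix(0, n, max(n, max(annotations$outputs_total, 1L)))
  for (i in seq_len(nrow(annotations))) {
    s <- annotations$start_len[i]
    e <- annotations$end_len[i]
    others <- annotations$other_positions[[i]]
    k <- length(others)
    if (s > 0L) for (j in seq_len(s)) mass[j, j] <- mass[j, j] + 1
    if (e > 0L) for (j in seq_len(e)) {
      mass[n - e + j, s + k + j] <- mass[n - e + j, s + k + j] + 1
    }
    if (k > 0L) {
      perms <- all_perms(others)
      w <- 1 / length(perms)
      for (p in perms) for (j in seq_len(k)) {
        mass[p[j], s + j] <- mass[p[j], s + j] + w
      }
    }
  }
  for (d in seq_len(min(dim(mass)))) mass[d, d] <- 0
  total <- sum(mass)
  idx <- which(mass > 0, arr.ind = TRUE)
  stats::setNames(mass[idx] / total, paste0(idx[, 1], ":", idx[, 2]))
}

# gradient tibble -> named vector comparable with oracle_null_gradient()
gradient_as_vector <- function(g) {
  stats::setNames(g$proportion, paste0(g$input_position, ":",
                                       g$output_position))
}

# enumerate every protocol of length L over the alphabet {items 1..n,
# omission mark, intrusion} as an integer matrix (one protocol per row,
# codes 1..n items, n+1 omission, n+2 intrusion)
protocol_grid <- function(n, L) {
  if (L == 0L) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(seq_len(n + 2L)), L),
                        KEEP.OUT.ATTRS = FALSE))
}

decode_protocol <- function(codes, n) {
  pos <- as.integer(codes)
  pos[codes == n + 1L] <- 0L
  pos[codes == n + 2L] <- NA_integer_
  pos
}
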