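# "start + guess + end" null model -------------------------------------------
#
# Given only each trial's annotation (start length s, end length e, and the
# identities of its Other list items), the null model outputs the
# start-sequence first (slots 1..s), the end-sequence last (slots
# s+k+1..s+k+e), and allocates the k Other items uniformly at random to the
# intervening slots s+1..s+k. No positional information is assumed for the
# Other items. Because the number of output slots equals the number of
# counted recall events, end-sequences on short protocols land prematurely
# at early output positions -- the mechanism behind the reduced recency of
# in-position scoring.

# deterministic 31-bit hash of a string, used to give each trial its own
# reproducible RNG stream derived from (seed, trial_id); results are then
# invariant to trial ordering.
.trial_seed <- function(seed, trial_id) {
  h <- 0
  for (k in utf8ToInt(as.character(trial_id))) {
    h <- (h * 31 + k) %% 2147483629
  }
  as.integer((h + seed %% 2147483629) %% 2147483629)
}

# Middle-slot bookkeeping shared by both estimators. Under the default
# "exclude" intrusion policy the slot count is s + k + e (Other list items
# only); under "occupy" each intrusion also takes one of the middle slots.
.null_layout <- function(ann_row, intrusions) {
  s <- ann_row$start_len
  e <- ann_row$end_len
  others <- ann_row$other_positions[[1]]
  k <- length(others)
  m <- k + if (intrusions == "occupy") ann_row$n_intrusion else 0L
  n <- ann_row$list_length
  list(
    s = s, e = e, k = k, m = m, n = n, others = others,
    start_pairs = if (s > 0L) cbind(seq_len(s), seq_len(s)) else NULL,
    end_pairs = if (e > 0L) {
      cbind(n - e + seq_len(e), s + m + seq_len(e))
    } else NULL
  )
}

#' One random null assignment per trial
#'
#' Draws a single realisation of the null model for every annotated trial:
#' start items at the first s output slots, end items at the last e, Other
#' items uniformly permuted over the middle slots.
#'
#' @param annotations Output of [annotate_trials()].
#' @param seed Integer seed (per-trial streams are derived from it and the
#'   trial id, so results do not depend on row order).
#' @param intrusions `"exclude"` (default; intrusions take no slot) or
#'   `"occupy"` (each intrusion occupies one middle slot, shifting end
#'   items later).
#' @return A tibble with one row per assigned list item: `trial_id`,
#'   `input_position`, `output_position`, `role` (start/other/end).
#' @examples
#' ann <- annotate_trials(parse_letter_trial("ABCDEF", "ABEF"))
#' null_assignment(ann, seed = 1)
#' @export
null_assignment <- function(annotations, seed = 1L,
                            intrusions = c("exclude", "occupy")) {
  intrusions <- match.arg(intrusions)
  rows <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    lay <- .null_layout(annotations[i, ], intrusions)
    slots <- integer(0)
    if (lay$k > 0L) {
      set.seed(.trial_seed(seed, annotations$trial_id[i]))
      middle <- lay$s + sample.int(lay$m)
      slots <- middle[seq_len(lay$k)]
    }
    rows[[i]] <- tibble::tibble(
      trial_id = annotations$trial_id[i],
      input_position = c(if (!is.null(lay$start_pairs)) lay$start_pairs[, 1],
                         lay$others,
                         if (!is.null(lay$end_pairs)) lay$end_pairs[, 1]),
      output_position = c(if (!is.null(lay$start_pairs)) lay$start_pairs[, 2],
                          slots,
                          if (!is.null(lay$end_pairs)) lay$end_pairs[, 2]),
      role = c(rep("start", lay$s), rep("other", lay$k), rep("end", lay$e))
    )
  }
  dplyr::bind_rows(rows)
}

# Accumulate expected or simulated (input, output) mass for one estimator
# run; returns a dense matrix n x max_output.
.null_mass <- function(annotations, intrusions, estimator, replications,
                       seed) {
  n <- unique(annotations$list_length)
  if (length(n) != 1L) {
    stop("annotations must share one list length", call. = FALSE)
  }
  max_out <- max(n, annotations$start_len + annotations$other_count +
                   annotations$end_len +
                   if (intrusions == "occupy") annotations$n_intrusion else 0L)
  mass <- matrix(0, nrow = n, ncol = max_out)
  for (i in seq_len(nrow(annotations))) {
    lay <- .null_layout(annotations[i, ], intrusions)
    w <- if (estimator == "monte_carlo") replications else 1
    if (!is.null(lay$start_pairs)) {
      mass[lay$start_pairs] <- mass[lay$start_pairs] + w
    }
    if (!is.null(lay$end_pairs)) {
      mass[lay$end_pairs] <- mass[lay$end_pairs] + w
    }
    if (lay$k > 0L) {
      if (estimator == "analytic") {
        # each Other item occupies each middle slot with probability 1/m
        for (j in seq_len(lay$k)) {
          cols <- lay$s + seq_len(lay$m)
          mass[lay$others[j], cols] <- mass[lay$others[j], cols] + 1 / lay$m
        }
      } else {
        set.seed(.trial_seed(seed, annotations$trial_id[i]))
        R <- replications
        # rank each of the m middle columns within each replication row;
        # the first k columns are the Other items, the rest (under the
        # occupy policy) are intrusions, which contribute no mass.
        U <- matrix(stats::runif(R * lay$m), nrow = R, ncol = lay$m)
        rank_j <- matrix(1L, nrow = R, ncol = lay$k)
        for (j in seq_len(lay$k)) {
          for (l in seq_len(lay$m)) {
            if (l != j) rank_j[, j] <- rank_j[, j] + (U[, l] < U[, j])
          }
        }
        for (j in seq_len(lay$k)) {
          tab <- tabulate(rank_j[, j], nbins = lay$m)
          cols <- lay$s + seq_len(lay$m)
          mass[lay$others[j], cols] <- mass[lay$others[j], cols] + tab
        }
      }
    }
  }
  mass
}

.mass_to_gradient <- function(mass, n, n_trials, source) {
  idx <- which(mass > 0, arr.ind = TRUE)
  df <- tibble::tibble(
    input_position = as.integer(idx[, 1]),
    output_position = as.integer(idx[, 2]),
    expected = mass[idx]
  )
  tab <- new_transposition_table(df, n = n, n_trials = n_trials,
                                 source = source)
  error_gradient(tab)
}

#' Estimated transposition-error gradient (Monte Carlo)
#'
#' Simulates the null model `replications` times per trial, pools the
#' resulting error counts over all replications and trials, and normalises
#' by the total number of order errors. The only positional information
#' entering the estimate is that carried by the start- and end-sequences.
#'
#' @inheritParams null_assignment
#' @param replications Replications per trial (default 1000).
#' @return An error-only `transposition_table` (`proportion` sums to 1), or
#'   the empty-gradient signal when no order error is possible (all trials
#'   complete). Deterministic given `seed`; exactly seed-invariant when
#'   every trial has `k = 0`.
#' @seealso [estimated_gradient_analytic()], the infinite-replication limit.
#' @export
estimated_gradient_mc <- function(annotations, replications = 1000L,
                                  seed = 1L,
                                  intrusions = c("exclude", "occupy")) {
  intrusions <- match.arg(intrusions)
  stopifnot(replications >= 1L)
  mass <- .null_mass(annotations, intrusions, "monte_carlo",
                     as.integer(replications), seed)
  .mass_to_gradient(mass, unique(annotations$list_length),
                    nrow(annotations), "estimated_mc")
}

#' Estimated transposition-error gradient (exact expectation)
#'
#' Closed-form expectation of the null model: start and end contributions
#' are deterministic, and each Other item contributes probability `1/k`
#' (or `1/m` under the occupy-slot intrusion policy) to each intervening
#' output slot. Equals the infinite-replication limit of
#' [estimated_gradient_mc()] and is the reference estimator.
#'
#' @inheritParams estimated_gradient_mc
#' @return An error-only `transposition_table`, or the empty-gradient
#'   signal.
#' @export
estimated_gradient_analytic <- function(annotations,
                                        intrusions = c("exclude", "occupy")) {
  intrusions <- match.arg(intrusions)
  mass <- .null_mass(annotations, intrusions, "analytic", 1L, 0L)
  .mass_to_gradient(mass, unique(annotations$list_length),
                    nrow(annotations), "estimated_analytic")
}

#' Total-variation distance between two gradients
#'
#' Half the sum of absolute cell differences after aligning the two
#' error-only gradients on the union of their cells.
#'
#' @param a,b Error-only `transposition_table`s.
#' @return A number in `[0, 1]`.
#' @export
gradient_tv_distance <- function(a, b) {
  key <- function(x) paste(x$input_position, x$output_position)
  all_keys <- union(key(a), key(b))
  pa <- stats::setNames(rep(0, length(all_keys)), all_keys)
  pb <- pa
  pa[key(a)] <- a$proportion
  pb[key(b)] <- b$proportion
  sum(abs(pa - pb)) / 2
}
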