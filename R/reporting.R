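# Reporting commands ----------------------------------------------------------
#
# Each command reads a trial file, runs one stage of the pipeline, and
# writes machine-readable outputs plus a provenance record (config,
# package version, seed) to an output directory. Re-running a command with
# the same inputs, options and seed reproduces byte-identical files.
# inst/scripts/recallseq wraps these as shell subcommands.

.write_provenance <- function(out_dir, command, params) {
  record <- list(
    command = command,
    package = "recallseq",
    package_version = as.character(utils::packageVersion("recallseq")),
    params = params
  )
  jsonlite::write_json(record, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.read_input_trials <- function(input, format, omission_token) {
  if (!file.exists(input)) stop("input file not found: ", input,
                                call. = FALSE)
  read_trials(input, format = format, omission_token = omission_token)
}

.annotations_flat <- function(ann) {
  ann |>
    tibble::as_tibble() |>
    dplyr::mutate(
      labels = vapply(.data$labels, paste, "", collapse = ";"),
      other_positions = vapply(.data$other_positions, paste, "",
                               collapse = ";")
    )
}

#' Score a trial file: annotations, cross-tabulations, summaries
#'
#' Annotates every trial, then writes `annotations.tsv` (one row per
#' trial), one `crosstab_<condition>_n<len>.csv` per condition and list
#' length in the published layout, `sequence_summary.csv`, and
#' `provenance.json`.
#'
#' @param input Path to a trial file.
#' @param out_dir Output directory (created if needed).
#' @param format Input format, `"tsv"` or `"letters"`.
#' @param policy `"first"` or `"any"`, or a [sequence_policy()].
#' @param omission_token Reserved skip token for TSV input.
#' @return Invisibly, the annotation tibble.
#' @export
cmd_score <- function(input, out_dir, format = c("tsv", "letters"),
                      policy = sequence_policy(),
                      omission_token = "blank") {
  format <- match.arg(format)
  policy <- as_sequence_policy(policy)
  trials <- .read_input_trials(input, format, omission_token)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- annotate_trials(trials, policy)
  readr::write_tsv(.annotations_flat(ann),
                   file.path(out_dir, "annotations.tsv"), progress = FALSE)
  groups <- ann |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$condition, .data$list_length)
  for (g in seq_len(nrow(groups))) {
    sub <- ann[ann$condition == groups$condition[g] &
                 ann$list_length == groups$list_length[g], ]
    tab <- crosstab_start_end(sub, list_length = groups$list_length[g],
                              label = groups$condition[g])
    fname <- sprintf("crosstab_%s_n%d.csv",
                     gsub("[^A-Za-z0-9]+", "_", groups$condition[g]),
                     groups$list_length[g])
    write_startend_table(tab, file.path(out_dir, fname))
  }
  readr::write_csv(sequence_length_summary(ann),
                   file.path(out_dir, "sequence_summary.csv"),
                   progress = FALSE)
  .write_provenance(out_dir, "score",
                    list(input = basename(input), format = format,
                         policy = unclass(policy),
                         omission_token = omission_token))
  invisible(ann)
}

#' Compute serial-position curves from a trial file
#'
#' Writes one tidy `curves.csv` (columns `condition`, `list_length`,
#' `rule`, `alignment`, `position`, `value`, `denominator`) covering the
#' requested scoring rules plus the residual Other curve, and
#' `provenance.json`. Trials are grouped by condition and list length; one
#' curve per length, never averaged across lengths.
#'
#' @inheritParams cmd_score
#' @param rules Scoring rules among `"SR"`, `"FR"`, `"START_END"`.
#' @param alignment `"primacy"` or `"recency"` for the scored curves (the
#'   residual Other curve is always recency-justified).
#' @param include_complete Include completely correct trials?
#' @return Invisibly, the combined curve tibble.
#' @export
cmd_curves <- function(input, out_dir, format = c("tsv", "letters"),
                       rules = c("SR", "FR", "START_END"),
                       alignment = c("primacy", "recency"),
                       include_complete = TRUE,
                       policy = sequence_policy(),
                       omission_token = "blank") {
  format <- match.arg(format)
  alignment <- match.arg(alignment)
  rules <- match.arg(rules, several.ok = TRUE)
  policy <- as_sequence_policy(policy)
  trials <- .read_input_trials(input, format, omission_token)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- annotate_trials(trials, policy)
  pieces <- lapply(rules, function(rule) {
    position_curve(trials, rule, annotations = ann, alignment = alignment,
                   include_complete = include_complete, policy = policy) |>
      tibble::as_tibble()
  })
  pieces <- c(pieces, list(tibble::as_tibble(
    residual_other_curve(trials, annotations = ann, policy = policy))))
  curves <- dplyr::bind_rows(pieces)
  readr::write_csv(curves, file.path(out_dir, "curves.csv"),
                   progress = FALSE)
  .write_provenance(out_dir, "curves",
                    list(input = basename(input), format = format,
                         rules = rules, alignment = alignment,
                         include_complete = include_complete,
                         policy = unclass(policy)))
  invisible(curves)
}

#' Observed and estimated transposition-error gradients
#'
#' Computes the observed error-only transposition gradient and the
#' start + guess + end estimate (analytic by default), and writes a single
#' tidy `gradients.csv` with a `source` column distinguishing
#' observed from estimated, plus `provenance.json`.
#'
#' @inheritParams cmd_score
#' @param estimator `"analytic"` or `"mc"`.
#' @param replications Monte Carlo replications per trial.
#' @param seed Seed for the Monte Carlo estimator.
#' @param intrusions Null-model intrusion policy, `"exclude"` or
#'   `"occupy"`.
#' @return Invisibly, the combined gradient tibble.
#' @export
cmd_null <- function(input, out_dir, format = c("tsv", "letters"),
                     estimator = c("analytic", "mc"),
                     replications = 1000L, seed = 1L,
                     intrusions = c("exclude", "occupy"),
                     policy = sequence_policy(),
                     omission_token = "blank") {
  format <- match.arg(format)
  estimator <- match.arg(estimator)
  intrusions <- match.arg(intrusions)
  policy <- as_sequence_policy(policy)
  trials <- .read_input_trials(input, format, omission_token)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- annotate_trials(trials, policy)
  observed <- error_gradient(transposition_matrix(trials))
  estimated <- if (estimator == "analytic") {
    estimated_gradient_analytic(ann, intrusions = intrusions)
  } else {
    estimated_gradient_mc(ann, replications = replications, seed = seed,
                          intrusions = intrusions)
  }
  tag <- function(x, src) {
    tibble::as_tibble(x) |>
      dplyr::select(dplyr::any_of(c("input_position", "output_position",
                                    "proportion"))) |>
      dplyr::mutate(source = src, .before = 1)
  }
  combined <- dplyr::bind_rows(tag(observed, "observed"),
                               tag(estimated, "estimated"))
  readr::write_csv(combined, file.path(out_dir, "gradients.csv"),
                   progress = FALSE)
  .write_provenance(out_dir, "null",
                    list(input = basename(input), format = format,
                         estimator = estimator,
                         replications = replications, seed = seed,
                         intrusions = intrusions,
                         policy = unclass(policy)))
  invisible(combined)
}

#' Generate synthetic trials and write them as a trial file
#'
#' @param config A [synthetic_config()], or a path to a YAML/JSON file
#'   whose keys are `synthetic_config()` arguments.
#' @param out_dir Output directory; trials land in `trials.tsv`.
#' @param seed Generation seed.
#' @return Invisibly, the generated trial tibble.
#' @export
cmd_simulate <- function(config = synthetic_config(), out_dir, seed = 1L) {
  if (is.character(config)) config <- .read_config_file(config)
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- generate_trials(config, seed = seed)
  write_trials(trials, file.path(out_dir, "trials.tsv"))
  .write_provenance(out_dir, "simulate",
                    list(config = unclass(config), seed = seed))
  invisible(trials)
}

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  args <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(synthetic_config, args)
}

#' Replay the packaged published cross-tabulation
#'
#' Realises one (or every) block of [osth_dennis_table1()] as concrete
#' trials, re-annotates them under the `"any"` occurrence policy, and
#' writes the replayed trials, the round-trip cross-tabulation, and a
#' `complete_correct.csv` of completely-correct proportions.
#'
#' @param out_dir Output directory.
#' @param condition A single condition, or `NULL` for all four.
#' @param seed Seed (replay is deterministic; the seed feeds optional
#'   Other-item sampling).
#' @return Invisibly, a tibble of per-condition completely-correct
#'   proportions.
#' @export
cmd_replay_table1 <- function(out_dir, condition = NULL, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- condition %||% .table1_conditions
  rows <- vector("list", length(conds))
  policy <- sequence_policy("any")
  for (i in seq_along(conds)) {
    tab <- osth_dennis_table1(conds[i])
    trials <- generate_from_crosstab(tab, policy = policy, seed = seed)
    ann <- annotate_trials(trials, policy)
    round_trip <- crosstab_start_end(ann, list_length = 6L, label = conds[i])
    slug <- gsub("[^A-Za-z0-9]+", "_", conds[i])
    write_trials(trials, file.path(out_dir, sprintf("trials_%s.tsv", slug)))
    write_startend_table(round_trip,
                         file.path(out_dir, sprintf("crosstab_%s.csv", slug)))
    rows[[i]] <- tibble::tibble(
      condition = conds[i],
      n_trials = attr(round_trip, "n_trials"),
      prop_complete = proportion_complete_correct(round_trip)
    )
  }
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, file.path(out_dir, "complete_correct.csv"),
                   progress = FALSE)
  .write_provenance(out_dir, "replay-table1",
                    list(condition = conds, seed = seed))
  invisible(out)
}
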