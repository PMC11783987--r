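test_that("worked 8-item protocols score the published sequence lengths", {
  tr <- worked_trials()
  ann <- annotate_trials(tr)
  # FGHCABG: end-sequence of three (F,G,H), start-sequence of two (A,B)
  # HGABCE: start 3 (A,B,C), end 1 (H alone; the G after it is backward)
  # ABCFEGH: start 3, end 2 (G,H)
  # GFAC: start 1 (A alone), end 0 (H never recalled)
  expect_equal(ann$start_len, c(2L, 3L, 3L, 1L))
  expect_equal(ann$end_len, c(3L, 1L, 2L, 0L))

  # FGHCABG event labels: C is Other, the second G a repetition
  expect_equal(ann$labels[[1]],
               c("end", "end", "end", "other", "start", "start",
                 "repetition"))
  expect_equal(ann$other_count[1], 1L)
  expect_false(any(ann$complete_correct))

  ss <- find_start_sequence(tr)
  expect_equal(ss$length, c(2L, 3L, 3L, 1L))
  expect_equal(ss$output_from[1], 5L)  # A,B at outputs 5-6
  expect_equal(ss$output_to[1], 6L)
  es <- find_end_sequence(tr)
  expect_equal(es$output_from[1], 1L)  # F,G,H at outputs 1-3
  expect_equal(es$output_to[1], 3L)
})

test_that("sequence length is 0 exactly when the anchor item is absent", {
  expect_equal(find_end_sequence(lt("ABCDEF", ""))$length, 0L)
  expect_equal(find_start_sequence(lt("ABCDEF", ""))$length, 0L)
  # fully backward recall leaves only the singleton runs at the anchors
  bw <- annotate_trials(lt("ABCDEF", "FEDCBA"))
  expect_equal(bw$start_len, 1L)
  expect_equal(bw$end_len, 1L)
  # a singleton recall of the last item anywhere is an end-sequence
  expect_equal(annotate_trials(lt("ABCDEF", "CFD"))$end_len, 1L)
})

test_that("complete-correct trials take the (n, 0) convention", {
  ann <- annotate_trials(lt("ABCDEF", "ABCDEF"))
  expect_true(ann$complete_correct)
  expect_equal(ann$start_len, 6L)
  expect_equal(ann$end_len, 0L)
  expect_equal(ann$other_count, 0L)
  # an extra trailing event breaks completeness but not the start run
  ann2 <- annotate_trials(lt("ABCDEF", "ABCDEFA"))
  expect_false(ann2$complete_correct)
  expect_equal(ann2$start_len, 6L)
})

test_that("explicit omission marks break run contiguity", {
  # A blank C D E F: the skip splits A from C..F
  ann <- annotate_trials(lt("ABCDEF", "A-CDEF"))
  expect_equal(ann$start_len, 1L)
  expect_equal(ann$end_len, 4L)
  expect_equal(ann$other_count, 0L)
  expect_equal(ann$n_omission, 1L)
  # omission-transparent runs: the mark no longer interrupts
  lax <- sequence_policy(break_omission = FALSE)
  ann2 <- annotate_trials(lt("ABCDEF", "A-CDEF"), lax)
  expect_equal(ann2$start_len, 1L)  # B is genuinely missing either way
  strict3 <- annotate_trials(lt("ABCDEF", "AB-CDEF"))
  expect_equal(strict3$start_len, 2L)
  expect_equal(strict3$end_len, 4L)
  ann3 <- annotate_trials(lt("ABCDEF", "AB-CDEF"), lax)
  expect_equal(ann3$start_len, 6L)  # run continues through the skip
})

test_that("intrusions break runs by default but can be made transparent", {
  ann <- annotate_trials(lt("ABCDEF", "ABXCEF"))
  expect_equal(ann$start_len, 2L)
  expect_equal(ann$end_len, 2L)
  lax <- sequence_policy(break_intrusion = FALSE)
  ann2 <- annotate_trials(lt("ABCDEF", "ABXCEF"), lax)
  expect_equal(ann2$start_len, 3L)  # run continues through the intrusion
})

test_that("first-occurrence eligibility labels later recalls as repetitions", {
  ann <- annotate_trials(lt("ABCDEF", "ABAB"))
  expect_equal(ann$start_len, 2L)
  expect_equal(ann$n_repetition, 2L)
  expect_equal(ann$other_count, 0L)
  # under any_occurrence the repeated boundary item can serve two runs
  tr <- lt("ABCDEF", "ABCDDEF")
  expect_equal(annotate_trials(tr)$start_len, 4L)
  any_ann <- annotate_trials(tr, sequence_policy("any"))
  expect_equal(any_ann$start_len, 4L)
  expect_equal(any_ann$end_len, 3L)
})

test_that("annotation bookkeeping identity holds on noisy synthetic data", {
  cfg <- synthetic_config(n_trials = 300, p_complete = 0.2,
                          intrusion_rate = 0.15, repetition_rate = 0.15,
                          omission_rate = 0.15, strict = FALSE,
                          other_dist = c(.3, .3, .2, .2, rep(0, 3)))
  ann <- annotate_trials(generate_trials(cfg, seed = 8))
  expect_equal(ann$other_count,
               ann$outputs_total - ann$start_len - ann$end_len -
                 ann$n_repetition - ann$n_intrusion - ann$n_omission)
  # s + e never exceeds the number of distinct items recalled
  tr <- generate_trials(cfg, seed = 9)
  ann2 <- annotate_trials(tr)
  distinct <- vapply(seq_len(nrow(tr)), function(i) {
    hits <- match(tr$recalled[[i]], tr$presented[[i]])
    length(unique(hits[!is.na(hits)]))
  }, integer(1))
  expect_true(all(ann2$start_len + ann2$end_len <= distinct))
})

test_that("identical trial and policy always give identical annotations", {
  cfg <- synthetic_config(n_trials = 50, intrusion_rate = 0.2,
                          repetition_rate = 0.2, strict = FALSE)
  tr <- generate_trials(cfg, seed = 4)
  a1 <- annotate_trials(tr)
  a2 <- annotate_trials(tr)
  expect_identical(a1, a2)
})

test_that("scanning scorer matches the window-enumeration oracle (small n)", {
  mismatches <- 0L
  for (n in 2:4) {
    for (L in 0:4) {
      grid <- protocol_grid(n, L)
      for (r in seq_len(nrow(grid))) {
        pos <- decode_protocol(grid[r, ], n)
        got <- recallseq:::scan_protocol(pos, n)
        want <- oracle_scan(pos, n)
        if (got$start_len != want$start_len ||
            got$end_len != want$end_len) {
          mismatches <- mismatches + 1L
        }
      }
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("scanner matches the oracle under the any-occurrence policy", {
  pol <- sequence_policy("any")
  set.seed(21)
  for (i in 1:400) {
    n <- sample(3:6, 1)
    L <- sample(0:6, 1)
    pos <- decode_protocol(sample(seq_len(n + 2L), L, replace = TRUE), n)
    got <- recallseq:::scan_protocol(pos, n, pol)
    want <- oracle_scan(pos, n, occurrence = "any")
    expect_identical(c(got$start_len, got$end_len),
                     c(want$start_len, want$end_len))
  }
})

test_that("crosstab counts match hand enumeration", {
  # protocols over 1..6: 123456 (complete), 1256, 346
  tr <- lt(rep("ABCDEF", 3), c("ABCDEF", "ABEF", "CDF"))
  ann <- annotate_trials(tr)
  tab <- crosstab_start_end(ann)
  m <- startend_matrix(tab)
  expect_equal(m["6", "0"], 1L)  # complete-correct convention
  expect_equal(m["2", "2"], 1L)
  expect_equal(m["0", "1"], 1L)  # 346: no start run, end run "6" singleton
  expect_equal(sum(m), 3L)
  expect_equal(proportion_complete_correct(tab), 1 / 3)

  # summary means under the same convention
  summ <- sequence_length_summary(ann)
  expect_equal(summ$mean_start, (6 + 2 + 0) / 3)
  expect_equal(summ$mean_end, (0 + 2 + 1) / 3)

  # empty input
  empty_tab <- crosstab_start_end(ann[0, ], list_length = 6)
  expect_equal(sum(empty_tab$count), 0L)
  expect_error(proportion_complete_correct(empty_tab), "undefined")
  expect_error(crosstab_start_end(ann[0, ]), "empty")
})

test_that("crosstab refuses mixed list lengths", {
  tr <- lt(c("ABCD", "ABCDEF"), c("ABCD", "ABCDEF"))
  expect_error(crosstab_start_end(annotate_trials(tr)), "mix")
})

test_that("single complete trial gives proportion 1", {
  tab <- crosstab_start_end(annotate_trials(lt("ABCDEF", "ABCDEF")))
  expect_equal(proportion_complete_correct(tab), 1)
})

test_that("startend table serialises to the published CSV layout", {
  tab <- crosstab_start_end(
    annotate_trials(lt(rep("ABCDEF", 2), c("ABCDEF", "ABEF"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_startend_table(tab, path)
  csv <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(csv)[1:3], c("start sequence", "no end", "6"))
  expect_equal(csv[["start sequence"]][1:3], c("no start", "1", "12"))
  expect_equal(csv[["56"]][csv[["start sequence"]] == "12"], 1)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_startend_table(tab, jpath, format = "json")
  payload <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(payload$n_trials, 2L)
})
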