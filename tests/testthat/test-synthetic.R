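test_that("degenerate distributions force a single protocol shape", {
  cfg <- synthetic_config(
    n_trials = 25, p_complete = 0,
    start_dist = c(0, 0, 1, 0, 0, 0),
    end_dist = c(0, 0, 1, 0, 0, 0),
    other_dist = c(1, rep(0, 6))
  )
  tr <- generate_trials(cfg, seed = 1)
  rendered <- render_letter_trial(tr)
  expect_true(all(rendered$recalled == "ABEF"))
  tab <- crosstab_start_end(annotate_trials(tr))
  m <- startend_matrix(tab)
  expect_equal(m["2", "2"], 25L)
  expect_equal(sum(m), 25L)
})

test_that("strict mode is recovered exactly by the scorer", {
  cfg <- synthetic_config(
    n_trials = 600, p_complete = 0.3,
    start_dist = c(.2, .3, .3, .2, 0, 0),
    end_dist = c(.4, .35, .25, 0, 0, 0),
    other_dist = c(.4, .3, .3, rep(0, 4))
  )
  tr <- generate_trials(cfg, seed = 17)
  ann <- annotate_trials(tr)
  expect_equal(ann$start_len, tr$intended_start)
  expect_equal(ann$end_len, tr$intended_end)
  expect_equal(mean(ann$start_len), mean(tr$intended_start))
  # complete trials are the sampled completes exactly
  expect_equal(sum(ann$complete_correct), sum(tr$intended_start == 6L))
})

test_that("strict mode survives noise injection", {
  cfg <- synthetic_config(
    n_trials = 300, p_complete = 0.2,
    intrusion_rate = 0.2, repetition_rate = 0.2, omission_rate = 0.2,
    other_dist = c(.3, .3, .4, rep(0, 4))
  )
  tr <- generate_trials(cfg, seed = 23)
  ann <- annotate_trials(tr)
  expect_equal(ann$start_len, tr$intended_start)
  expect_equal(ann$end_len, tr$intended_end)
  ev <- recall_events(tr)
  expect_true(all(c("intrusion", "omission") %in% ev$kind))
  expect_gt(sum(ann$n_repetition), 0L)
})

test_that("non-strict generation can only inflate sequence lengths", {
  cfg <- synthetic_config(
    n_trials = 1500, p_complete = 0, strict = FALSE,
    start_dist = c(.25, .5, .25, 0, 0, 0),
    other_dist = c(.1, .3, .3, .3, rep(0, 3))
  )
  tr <- generate_trials(cfg, seed = 29)
  ann <- annotate_trials(tr)
  expect_true(all(ann$start_len >= tr$intended_start))
  # the end length can only shrink by vanishing into an accidentally
  # complete protocol (which takes the (n, 0) convention)
  ok_e <- ann$complete_correct | (ann$end_len >= tr$intended_end)
  expect_true(all(ok_e))
  # lucky positioning really occurs at these rates
  expect_gt(mean(ann$start_len), mean(tr$intended_start))
})

test_that("identical config and seed reproduce the trial set", {
  cfg <- synthetic_config(n_trials = 80, intrusion_rate = 0.1,
                          repetition_rate = 0.1)
  expect_identical(generate_trials(cfg, seed = 5),
                   generate_trials(cfg, seed = 5))
  t2 <- generate_trials(cfg, seed = 6)
  expect_false(identical(generate_trials(cfg, seed = 5)$recalled,
                         t2$recalled))
})

test_that("crosstab replay round-trips a custom table, separators included", {
  tab <- small_startend_table(list(
    c(6, 0, 3),   # complete trials
    c(2, 2, 4),   # plain two-run cell
    c(4, 2, 2),   # s + e = n: needs the repetition separator
    c(0, 3, 2),   # end-only
    c(3, 0, 1),   # start-only
    c(0, 0, 2)    # empty protocols
  ))
  for (pol in list(sequence_policy("first"), sequence_policy("any"))) {
    tr <- generate_from_crosstab(tab, policy = pol)
    expect_equal(nrow(tr), 14L)
    rt <- crosstab_start_end(annotate_trials(tr, pol), list_length = 6)
    expect_equal(startend_matrix(rt), startend_matrix(tab))
  }
})

test_that("the s = 1 boundary cell uses the item-n separator under any", {
  # (1, n-1): an item-1 separator would itself anchor a full run when
  # every recall of item 1 is sequence-eligible
  tab <- small_startend_table(list(c(1, 5, 3)))
  for (pol in list(sequence_policy("first"), sequence_policy("any"))) {
    tr <- generate_from_crosstab(tab, policy = pol)
    ann <- annotate_trials(tr, pol)
    expect_equal(ann$start_len, rep(1L, 3))
    expect_equal(ann$end_len, rep(5L, 3))
  }
})

test_that("overlap cells require the any-occurrence policy", {
  tab <- small_startend_table(list(c(4, 3, 1)))
  expect_error(generate_from_crosstab(tab, policy = sequence_policy("first")),
               "start = 4, end = 3")
  tr <- generate_from_crosstab(tab, policy = sequence_policy("any"))
  expect_equal(render_letter_trial(tr)$recalled, "ABCDDEF")
  ann <- annotate_trials(tr, sequence_policy("any"))
  expect_equal(ann$start_len, 4L)
  expect_equal(ann$end_len, 3L)
})

test_that("all-zero tables replay to an empty trial set", {
  tab <- small_startend_table(list())
  expect_equal(nrow(generate_from_crosstab(tab)), 0L)
})

test_that("replay can inject strictly placed Other items", {
  tab <- small_startend_table(list(c(1, 1, 40)))
  tr <- generate_from_crosstab(tab, other_dist = c(.2, .4, .4, rep(0, 4)),
                               seed = 3)
  ann <- annotate_trials(tr, sequence_policy("any"))
  expect_true(all(ann$start_len == 1L & ann$end_len == 1L))
  expect_gt(sum(ann$other_count), 0L)
  rt <- crosstab_start_end(ann, list_length = 6)
  expect_equal(startend_matrix(rt)["1", "1"], 40L)
})

test_that("sampled joint (s, e) distribution matches the configuration", {
  # supports chosen so no truncation applies: s <= 3, e <= 2, s + e <= 5
  p_start <- c(.2, .3, .3, .2, 0, 0)
  p_end <- c(.4, .35, .25, 0, 0, 0)
  cfg <- synthetic_config(n_trials = 4000, p_complete = 0.3,
                          start_dist = p_start, end_dist = p_end,
                          other_dist = c(1, rep(0, 6)))
  tr <- generate_trials(cfg, seed = 37)
  ann <- annotate_trials(tr)
  obs <- table(factor(ann$start_len, levels = 0:6),
               factor(ann$end_len, levels = 0:6))
  probs <- outer(p_start[1:4] * 0.7, p_end[1:3])
  expected <- matrix(0, 7, 7)
  expected[1:4, 1:3] <- probs
  expected[7, 1] <- 0.3
  keep <- expected > 0
  gof <- stats::chisq.test(as.vector(obs[keep]),
                           p = as.vector(expected[keep]))
  expect_gt(gof$p.value, 0.01)
})

test_that("strict mode refuses unsatisfiable cells", {
  # e = n would fold into the complete sequence; flagged as infeasible
  tab <- small_startend_table(list(c(0, 6, 1)))
  expect_error(generate_from_crosstab(tab, policy = sequence_policy("any")),
               "infeasible|end")
})
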