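test_that("k = 0 annotations give a deterministic premature-end gradient", {
  # recall "1 2 5 6" of a 6-item list: start 2, end 2, no Others; the end
  # items must land prematurely at outputs 3 and 4
  ann <- annotate_trials(lt("ABCDEF", "ABEF"))
  for (g in list(estimated_gradient_analytic(ann),
                 estimated_gradient_mc(ann, replications = 5, seed = 1))) {
    expect_equal(nrow(g), 2L)
    expect_equal(g$proportion, c(0.5, 0.5))
    expect_equal(g$input_position, c(5L, 6L))
    expect_equal(g$output_position, c(3L, 4L))
  }
  # no random slots anywhere: the MC estimator is seed-invariant
  g1 <- estimated_gradient_mc(ann, replications = 7, seed = 10)
  g2 <- estimated_gradient_mc(ann, replications = 7, seed = 77)
  expect_equal(gradient_tv_distance(g1, g2), 0)
})

test_that("analytic Other-item mass is uniform over intervening slots", {
  # recall "1 3 6 5": s = 1, e = 1 (the 5 after 6 is backward), Others
  # {3, 5}; each Other sits at outputs 2 and 3 with probability 1/2, and
  # output 4 holds the prematurely placed end item
  ann <- annotate_trials(lt("ABCDEF", "ACFE"))
  expect_equal(ann$start_len, 1L)
  expect_equal(ann$end_len, 1L)
  expect_equal(ann$other_positions[[1]], c(3L, 5L))
  g <- estimated_gradient_analytic(ann)
  v <- gradient_as_vector(g)
  # total error mass: (3,2) 0.5 + (5,2) 0.5 + (5,3) 0.5 + (6,4) 1 = 2.5
  expect_equal(unname(v["3:2"]), 0.5 / 2.5)
  expect_equal(unname(v["5:2"]), 0.5 / 2.5)
  expect_equal(unname(v["5:3"]), 0.5 / 2.5)
  expect_equal(unname(v["6:4"]), 1 / 2.5)
  expect_false("3:3" %in% names(v))  # diagonal removed
})

test_that("analytic gradient equals k!-enumeration for k up to 5", {
  protos <- list(
    c(1, 2, 4, 3, 6),          # start run plus two shuffled Others
    c(1, 5, 3, 2, 6),          # three Others between the anchors
    c(4, 2, 5, 3, 6),          # no start run
    c(2, 5, 3, 4, 1),          # no end run
    c(3, 5, 2, 4, 1, 6)        # k = 4 between two singleton anchors
  )
  for (p in protos) {
    tr <- pos_trial(p, 6)
    ann <- annotate_trials(tr)
    got <- gradient_as_vector(estimated_gradient_analytic(ann))
    want <- oracle_null_gradient(ann)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
  # and pooled across a mixed set of trials
  tr <- lt(rep("ABCDEF", 3), c("ABEF", "ACEF", "FBDC"))
  ann <- annotate_trials(tr)
  expect_equal(
    sort(gradient_as_vector(estimated_gradient_analytic(ann))),
    sort(oracle_null_gradient(ann)))
})

test_that("Monte Carlo converges to the analytic expectation", {
  cfg <- synthetic_config(n_trials = 40, p_complete = 0.2,
                          other_dist = c(.25, .25, .25, .25, rep(0, 3)))
  ann <- annotate_trials(generate_trials(cfg, seed = 6))
  exact <- estimated_gradient_analytic(ann)
  coarse <- estimated_gradient_mc(ann, replications = 200, seed = 2)
  fine <- estimated_gradient_mc(ann, replications = 5000, seed = 2)
  expect_lt(gradient_tv_distance(fine, exact),
            gradient_tv_distance(coarse, exact) + 0.01)
  expect_lt(gradient_tv_distance(fine, exact), 0.02)
  expect_equal(sum(exact$proportion), 1)
  expect_equal(sum(fine$proportion), 1)
})

test_that("null assignments conserve output slots", {
  cfg <- synthetic_config(n_trials = 60, p_complete = 0.2,
                          other_dist = c(.3, .3, .2, .2, rep(0, 3)))
  ann <- annotate_trials(generate_trials(cfg, seed = 12))
  asg <- null_assignment(ann, seed = 5)
  by_trial <- split(asg, asg$trial_id)
  for (id in names(by_trial)) {
    row <- ann[ann$trial_id == id, ]
    slots <- sort(by_trial[[id]]$output_position)
    expect_equal(slots, seq_len(row$start_len + row$other_count +
                                  row$end_len))
  }
  # start items occupy the first s slots in presented order
  one <- by_trial[[ann$trial_id[which(ann$start_len > 0 &
                                        !ann$complete_correct)[1]]]]
  st <- one[one$role == "start", ]
  expect_equal(st$output_position, seq_len(nrow(st)))
  expect_equal(st$input_position, seq_len(nrow(st)))
})

test_that("estimates are invariant to trial order and reproducible", {
  cfg <- synthetic_config(n_trials = 30, p_complete = 0.1,
                          other_dist = c(.2, .3, .3, .2, rep(0, 3)))
  ann <- annotate_trials(generate_trials(cfg, seed = 19))
  g1 <- estimated_gradient_mc(ann, replications = 100, seed = 4)
  shuffled <- ann[rev(seq_len(nrow(ann))), ]
  g2 <- estimated_gradient_mc(shuffled, replications = 100, seed = 4)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(g1), input_position, output_position),
    dplyr::arrange(tibble::as_tibble(g2), input_position, output_position),
    ignore_attr = TRUE)
  g3 <- estimated_gradient_mc(ann, replications = 100, seed = 4)
  expect_identical(tibble::as_tibble(g1), tibble::as_tibble(g3))
})

test_that("all-complete annotation sets yield the empty-gradient signal", {
  ann <- annotate_trials(lt(rep("ABCDEF", 2), c("ABCDEF", "ABCDEF")))
  expect_true(is_empty_gradient(estimated_gradient_analytic(ann)))
  expect_true(is_empty_gradient(estimated_gradient_mc(ann, 10, seed = 1)))
})

test_that("occupy-slot intrusion policy widens the middle region", {
  # "1 2 X 5 6": under exclude the layout is as without the intrusion;
  # under occupy the intrusion takes one middle slot, pushing 5,6 to 4,5
  ann <- annotate_trials(lt("ABCDEF", "ABXEF"))
  ex <- gradient_as_vector(estimated_gradient_analytic(ann))
  oc <- gradient_as_vector(estimated_gradient_analytic(ann,
                                                       intrusions = "occupy"))
  expect_equal(sort(names(ex)), c("5:3", "6:4"))
  expect_equal(sort(names(oc)), c("5:4", "6:5"))
})

test_that("estimated gradients from replayed data show the locality trend", {
  tab <- osth_dennis_table1("Closed ISR")
  trials <- generate_from_crosstab(tab, policy = sequence_policy("any"))
  ann <- annotate_trials(trials, sequence_policy("any"))
  g <- estimated_gradient_analytic(ann)
  expect_equal(sum(g$proportion), 1)
  # soft property, reported not asserted tightly: error mass decreases
  # with transposition distance
  expect_lt(locality_correlation(g), 0)
})
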