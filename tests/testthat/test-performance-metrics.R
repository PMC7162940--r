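test_that("block coefficients match direct counting", {
  # worked examples
  expect_equal(block_sensitivity(make_trials(c(TRUE, TRUE, TRUE),
                                             c(TRUE, TRUE, TRUE))), 1.0)
  expect_equal(block_sensitivity(make_trials(c(TRUE, TRUE, FALSE),
                                             c(TRUE, FALSE, FALSE))), 0.5)
  expect_equal(block_sensitivity(make_trials(rep(TRUE, 3),
                                             c(TRUE, TRUE, FALSE))), 2 / 3)
  expect_equal(block_specificity(make_trials(rep(FALSE, 8),
                                             rep(FALSE, 8))), 1.0)
  expect_equal(block_specificity(make_trials(rep(FALSE, 7),
                                             rep(TRUE, 7))), 0.0)
  expect_equal(block_specificity(make_trials(rep(FALSE, 8),
                                             rep(c(TRUE, FALSE), c(2, 6)))),
               0.75)
  # randomized cases vs loop oracles
  set.seed(101)
  for (i in 1:300) {
    b <- random_block(sample(5:40, 1))
    expect_equal(block_sensitivity(b), oracle_sensitivity(b))
    expect_equal(block_specificity(b), oracle_specificity(b))
  }
  expect_error(block_sensitivity(make_trials(FALSE, FALSE)), "target")
  expect_error(block_specificity(make_trials(TRUE, TRUE)), "non-target")
})

test_that("cumulative coefficients use the strict prefix and flag undefined", {
  tr <- make_trials(c(FALSE, TRUE, FALSE, TRUE, TRUE),
                    c(FALSE, TRUE, TRUE, FALSE, TRUE))
  # no target before trial 2
  expect_true(is.na(cumulative_sensitivity(tr, 2)))
  # one target (hit) before trial 3
  expect_equal(cumulative_sensitivity(tr, 3), 1.0)
  # strict prefix: trial 4's own outcome not included
  expect_equal(cumulative_sensitivity(tr, 4), 1.0)
  expect_equal(cumulative_sensitivity(tr, 5), 0.5)
  expect_equal(cumulative_specificity(tr, 2), 1.0)
  expect_equal(cumulative_specificity(tr, 4), 0.5)
  expect_error(cumulative_sensitivity(tr, 1), "i >= 2")

  tr2 <- make_trials(rep(c(TRUE, FALSE), c(4, 4)),
                     c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 4)))
  expect_equal(cumulative_sensitivity(tr2, 5), 0.75)
  expect_true(is.na(cumulative_specificity(tr2, 4)))
  tr3 <- make_trials(rep(FALSE, 7), rep(c(FALSE, TRUE), c(3, 4)))
  expect_equal(cumulative_specificity(tr3, 7), 0.5)
})

test_that("cumulative curve changes only through the last trial's outcome", {
  set.seed(7)
  s <- make_schedule(1, 11L)
  tr <- s
  tr$response <- ifelse(runif(240) < 0.5, "target_button", "nontarget_button")
  cv <- cumulative_curve(tr, "sensitivity")
  for (i in c(3, 50, 200)) {
    v_prev <- cv$value[cv$trial == i]
    v_next <- cv$value[cv$trial == i + 1]
    if (!tr$is_target[i]) {
      expect_equal(v_next, v_prev) # non-target trial leaves sensitivity alone
    }
    expect_equal(v_next, cumulative_sensitivity(tr, i + 1))
  }
})

test_that("block series have the expected lengths and aggregate exactly", {
  co <- generate_cohort(master_seed = 3L)
  tr <- co$trials[co$trials$participant_id == "P001", ]
  expect_length(block_series(tr, "sensitivity", 10L), 24L)
  expect_length(block_series(tr, "sensitivity", 40L), 6L)
  one <- block_series(tr, "sensitivity", 240L)
  expect_length(one, 1L)
  expect_equal(as.numeric(one), oracle_sensitivity(tr))
  expect_error(block_series(tr, "sensitivity", 7L), "divide")

  # session-wide sensitivity equals the target-count-weighted mean of blocks
  bs <- block_series(tr, "sensitivity", 10L)
  blk <- (tr$trial_index - 1L) %/% 10L + 1L
  wt <- tapply(tr$is_target, blk, sum)
  expect_equal(sum(bs * wt) / sum(wt), oracle_sensitivity(tr))

  # the first cumulative value after one block equals that block's coefficient
  expect_equal(cumulative_sensitivity(tr, 11L), bs[1])
})

test_that("group mean curves average participants and skip undefined values", {
  co <- generate_cohort(master_seed = 4L)
  tr1 <- co$trials[co$trials$participant_id == "P001", ]
  grp <- mean_cumulative_curves(tr1, "sensitivity")
  own <- cumulative_curve(tr1, "sensitivity")
  expect_equal(grp$value, own$value)

  # two hand-built participants with constant curves 0.4 and 0.8
  mk <- function(id, hits) {
    tr <- make_trials(rep(TRUE, 10), hits)
    cbind(data.frame(participant_id = id, config = 1, button = "left",
                     label = "L", stringsAsFactors = FALSE), tr)
  }
  two <- rbind(mk("a", rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 2)),
               mk("b", rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2)))
  mc <- mean_cumulative_curves(two, "sensitivity")
  expect_equal(mc$value[mc$trial == 6], (0.4 + 0.8) / 2)

  # all-perfect cohort: identically 1 wherever defined
  perfect <- learner_profile(hit_prob = c(1, 1, 1), cr_prob = c(1, 1, 1))
  pp <- simulate_participant(perfect, 2, "right", seed = 1L)
  ptr <- cbind(data.frame(participant_id = "p", config = 2, button = "right",
                          label = "L", stringsAsFactors = FALSE), pp$trials)
  pc <- mean_cumulative_curves(ptr, "specificity")
  expect_true(all(pc$value[!is.na(pc$value)] == 1))
  expect_error(mean_cumulative_curves(two[0, ], "sensitivity"), "empty")
})

test_that("all coefficients stay within [0, 1] on random cohorts", {
  co <- generate_cohort(master_seed = 5L)
  for (cc in c("sensitivity", "specificity")) {
    tab <- block_series_table(co$trials, cc, 10L)
    expect_true(all(tab$value >= 0 & tab$value <= 1))
    mc <- mean_cumulative_curves(co$trials, cc)
    v <- mc$value[!is.na(mc$value)]
    expect_true(all(v >= 0 & v <= 1))
  }
})
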