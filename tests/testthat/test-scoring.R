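visit_row <- function(bee_id = 1, phase = "learning", bout = 1, vi = 1,
                      flower = 1, pattern = "bar", rewarding = TRUE,
                      probed = TRUE, counted = TRUE, group = "bar_rewarded") {
  data.frame(bee_id = bee_id, nest_id = 1, group = group, phase = phase,
             bout_index = bout, visit_index = vi, flower_id = flower,
             pattern = pattern, rewarding = rewarding, probed = probed,
             counted = counted, stringsAsFactors = FALSE)
}

test_that("landing scoring implements the probe/reward contingency", {
  # learning phase: correct = probe on rewarding, or withhold on nonrewarding
  recs <- rbind(
    visit_row(vi = 1, rewarding = TRUE, probed = TRUE),    # correct
    visit_row(vi = 2, rewarding = TRUE, probed = FALSE),   # incorrect
    visit_row(vi = 3, rewarding = FALSE, probed = FALSE, pattern = "circle"),  # correct
    visit_row(vi = 4, rewarding = FALSE, probed = TRUE, pattern = "circle")    # incorrect
  )
  scored <- score_landings(recs)
  expect_equal(scored$correct, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(score_landings(visit_row(counted = FALSE)), "counted records only")
})

test_that("test-phase landings are scored by the learned reward scheme", {
  # bar was rewarding during learning; in the all-nonrewarding test phase,
  # probing a bar flower is still the correct action
  learn <- rbind(
    visit_row(vi = 1, flower = 1, pattern = "bar", rewarding = TRUE),
    visit_row(vi = 2, flower = 2, pattern = "circle", rewarding = FALSE,
              probed = FALSE))
  test <- rbind(
    visit_row(phase = "test", vi = 1, flower = 3, pattern = "bar",
              rewarding = FALSE, probed = TRUE),             # correct
    visit_row(phase = "test", vi = 2, flower = 4, pattern = "circle",
              rewarding = FALSE, probed = TRUE),             # incorrect
    visit_row(phase = "test", vi = 3, flower = 4, pattern = "circle",
              rewarding = FALSE, probed = FALSE))            # correct
  scored <- score_landings(rbind(learn, test))
  expect_equal(scored$correct[scored$phase == "test"], c(TRUE, FALSE, TRUE))

  # control group: no patterns displayed; roles follow flower position
  learnC <- rbind(
    visit_row(group = "control", vi = 1, flower = 1, pattern = "none",
              rewarding = TRUE),
    visit_row(group = "control", vi = 2, flower = 9, pattern = "none",
              rewarding = FALSE, probed = FALSE))
  testC <- rbind(
    visit_row(group = "control", phase = "test", vi = 1, flower = 1,
              pattern = "none", rewarding = FALSE, probed = TRUE),   # correct
    visit_row(group = "control", phase = "test", vi = 2, flower = 9,
              pattern = "none", rewarding = FALSE, probed = TRUE))   # incorrect
  scoredC <- score_landings(rbind(learnC, testC))
  expect_equal(scoredC$correct[scoredC$phase == "test"], c(TRUE, FALSE))
})

test_that("revisit filtering enforces the arena rules and is idempotent", {
  small <- arena_config("small")
  # bee empties flower 3 in bout 2 and returns to it within the bout
  recs <- rbind(
    visit_row(bout = 1, flower = 3, probed = TRUE),
    visit_row(bout = 2, flower = 3, probed = TRUE),
    visit_row(bout = 2, flower = 5, probed = FALSE, rewarding = FALSE),
    visit_row(bout = 2, flower = 3, probed = FALSE),  # return to emptied: out
    visit_row(bout = 3, flower = 3, probed = TRUE))   # new bout: refilled
  recs$visit_index <- NA_integer_
  out <- filter_revisits(recs, small)
  expect_equal(out$counted, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$visit_index, c(1L, 2L, 3L, NA_integer_, 4L))
  expect_identical(filter_revisits(out, small), out)

  # large arena: a revisit counts only once the bee has been elsewhere
  large <- arena_config("large")
  recsL <- rbind(
    visit_row(bout = 1, flower = 2, probed = TRUE),
    visit_row(bout = 1, flower = 2, probed = FALSE),  # immediate return: out
    visit_row(bout = 1, flower = 4, probed = TRUE),
    visit_row(bout = 1, flower = 2, probed = TRUE))   # refilled + moved: in
  outL <- filter_revisits(recsL, large)
  expect_equal(outL$counted, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(filter_revisits(outL, large), outL)

  # regenerating the simulator's own flags is a no-op
  rec <- simulate_trial(bee_params(learning_rate = 0.06), small,
                        group = "bar_rewarded", seed = 8)
  expect_identical(filter_revisits(rec, small), rec)
  recL <- simulate_trial(bee_params(learning_rate = 0.06), large,
                         group = "cross_rewarded", seed = 8)
  expect_identical(filter_revisits(recL, large), recL)

  bad <- recs[c(5, 1, 2, 3, 4), ]
  expect_error(filter_revisits(bad, small), "not in landing order")
})

test_that("windowed success aggregates blocks of ten landings", {
  mk <- function(correct) {
    n <- length(correct)
    r <- visit_row()[rep(1, n), ]
    r$visit_index <- seq_len(n)
    r$correct <- correct
    rownames(r) <- NULL
    r
  }
  all_right <- windowed_success(mk(rep(TRUE, 60)))
  expect_equal(all_right$x, seq(10, 60, by = 10))
  expect_equal(all_right$success, rep(1, 6))
  expect_equal(all_right$theta, rep(pi / 2, 6))

  alternating <- windowed_success(mk(rep(c(TRUE, FALSE), 30)))
  expect_equal(alternating$success, rep(0.5, 6))

  first_block <- mk(c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 10)))
  ws <- windowed_success(first_block)
  expect_equal(ws$success[1], 0.7)  # direct count: 7 of 10
  # partial trailing landings are dropped
  expect_equal(nrow(windowed_success(mk(rep(TRUE, 25)))), 2L)
  expect_error(windowed_success(mk(rep(TRUE, 7))), "fewer counted landings")

  # round trip: inverse transform returns the block success exactly, and
  # blocks account for every correct action used
  v <- simulate_cohort(cohort_config(bees_per_group = 3, seed = 14),
                       arena_config("small"), phases = "learning")
  scored <- score_landings(v[v$counted, ])
  series <- windowed_success(scored)
  expect_equal(sin(series$theta)^2, series$success)
  expect_equal(sum(series$success * 10), sum(scored$correct))
})

test_that("arcsine transform endpoints, inverse and domain", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.5), asin(sqrt(0.5)))  # pi/4
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
  expect_error(arcsine_transform(-0.1), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.05)
  expect_equal(inverse_arcsine(arcsine_transform(p)), p)
  # plain arcsine variant for sensitivity analysis
  expect_equal(arcsine_transform(0.5, method = "asin"), asin(0.5))
  expect_equal(inverse_arcsine(asin(0.5), method = "asin"), 0.5)
})

test_that("test-phase table has one row per bee on the arcsine scale", {
  v <- simulate_cohort(cohort_config(bees_per_group = 3, seed = 33),
                       arena_config("small"))
  scored <- score_landings(v[v$counted, ])
  tab <- testphase_table(scored)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$success >= 0 & tab$success <= 1))
  expect_equal(tab$theta, asin(sqrt(tab$success)))
})
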