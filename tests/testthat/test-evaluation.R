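make_table <- function(n, means = c(0, 0, 0), sd = 1) {
  conds <- rep(c("control_constant", "control_time", "stress_adaptive"),
               each = n)
  data.frame(
    participant_id = seq_len(3 * n), condition = conds,
    time_to_criterion = rnorm(3 * n, rep(means, each = n), sd),
    performance_at_criterion = rnorm(3 * n, rep(means, each = n), sd),
    stringsAsFactors = FALSE)
}

test_that("yoked speed is the time-weighted mean over task segments", {
  tr <- difficulty_trace(c(0, 300), c(20, 20))
  expect_equal(yoke_constant_speed(list(tr), durations = 600), 20)
  tr1 <- difficulty_trace(0, 10); tr2 <- difficulty_trace(0, 30)
  expect_equal(yoke_constant_speed(list(tr1, tr2), durations = c(60, 60)), 20)
  # the session profile: 6 p/s for 12 s then 30 p/s for 588 s
  tr <- difficulty_trace(c(0, 12), c(6, 30))
  expect_equal(yoke_constant_speed(list(tr), durations = 600),
               (6 * 12 + 30 * 588) / 600)
  expect_error(yoke_constant_speed(list()), class = "sat_input_error")
})

test_that("yoking is invariant to session order and splitting", {
  rec <- simulate_participant(policy = policy_config("stress_adaptive"),
                              schedule = session_schedule(2), seed = 31)
  rec2 <- simulate_participant(policy = policy_config("time_ramp"),
                               schedule = session_schedule(2), seed = 32)
  expect_equal(yoke_constant_speed(list(rec, rec2)),
               yoke_constant_speed(list(rec2, rec)))
  # splitting: a trace cut at an interior tick leaves the mean unchanged
  tr <- difficulty_trace(c(0, 10, 20), c(4, 8, 12))
  whole <- yoke_constant_speed(list(tr), durations = 30)
  halves <- yoke_constant_speed(
    list(difficulty_trace(c(0, 10), c(4, 8)), difficulty_trace(0, 12)),
    durations = c(20, 10))
  expect_equal(whole, halves)
})

test_that("pearson correlation matches hand computation and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_correlation(x, rep(1, 4)), class = "sat_degenerate")
  expect_error(pearson_correlation(1:2, 1:2), class = "sat_input_error")
})

test_that("identical groups give a null contrast; exact shifts are recovered", {
  tab <- make_table(5)
  tab$time_to_criterion <- 7
  res <- compare_conditions(tab, "time_to_criterion")
  expect_equal(res$t_adaptive, 0)
  expect_lte(res$adj_r2, 0)

  tab$time_to_criterion <- ifelse(tab$condition == "stress_adaptive",
                                  7 - 2.5, 7)
  res <- suppressWarnings(compare_conditions(tab, "time_to_criterion"))
  expect_equal(res$estimate_contrast, -2.5)

  expect_error(compare_conditions(make_table(1), "time_to_criterion"),
               class = "sat_insufficient_data")
})

test_that("the fixed-effect fit equals textbook ANOVA plus planned contrast", {
  set.seed(77)
  for (r in 1:5) {
    tab <- make_table(8, means = c(0, 0.4, -0.3), sd = 1)
    # drop a couple of rows so group sizes are unbalanced
    tab <- tab[-sample(nrow(tab), 3), ]
    res <- compare_conditions(tab, "performance_at_criterion")
    ora <- oracle_contrast(tab, "performance_at_criterion")
    expect_equal(res$f_stat, ora$f, tolerance = 1e-8)
    expect_equal(res$t_adaptive, ora$t, tolerance = 1e-8)
    expect_equal(res$estimate_contrast, ora$estimate, tolerance = 1e-8)
    expect_true(res$p_contrast >= 0 && res$p_contrast <= 1)
    expect_equal(res$f_df[2], nrow(tab) - 3)
  }
})

test_that("a planted one-SD deficit is detected with the right sign", {
  set.seed(88)
  signs <- logical(50)
  for (r in 1:50) {
    tab <- make_table(15, means = c(0, 0, -1), sd = 1)
    signs[r] <- compare_conditions(tab, "time_to_criterion")$t_adaptive < 0
  }
  expect_gt(mean(signs), 0.9)
})

test_that("run_experiment is reproducible and reports both outcomes", {
  sched <- session_schedule(1, task_seconds = 300)
  ex1 <- run_experiment(n_per_condition = 2, schedule = sched, seed = 9)
  ex2 <- run_experiment(n_per_condition = 2, schedule = sched, seed = 9)
  expect_identical(ex1$outcomes, ex2$outcomes)
  expect_equal(nrow(ex1$outcomes), 6L)
  expect_equal(sort(unique(ex1$outcomes$condition)),
               c("control_constant", "control_time", "stress_adaptive"))
  # yoking pins the constant arm's realised speed to the adaptive mean
  const_rows <- ex1$outcomes$condition == "control_constant"
  expect_lt(abs(mean(ex1$outcomes$mean_speed[const_rows]) -
                  mean(ex1$yoked_speeds)), 3)
  expect_true(all(c("time_to_criterion", "performance_at_criterion") %in%
                    names(ex1$comparisons)))
})
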