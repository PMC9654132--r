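test_that("degenerate dynamics give flat latent stress and baseline force", {
  p <- trainee_params(sigma = 0, kappa = 0)
  rec <- simulate_session(p, policy_config("constant"), duration = 120,
                          seed = 3)
  expect_true(all(rec$latent_stress$latent == 0))
  expect_lt(abs(mean(rec$force$force) - p$g0), 0.05)
  s <- rec$stress$s[!is.na(rec$stress$s)]
  expect_lt(abs(mean(s)), 0.2)  # estimator fluctuates around zero
})

test_that("the same seed reproduces a session and a cohort exactly", {
  a <- simulate_session(seed = 17)
  b <- simulate_session(seed = 17)
  expect_identical(a, b)
  ca <- simulate_cohort(2, seed = 5, schedule = session_schedule(1))
  cb <- simulate_cohort(2, seed = 5, schedule = session_schedule(1))
  expect_identical(ca, cb)
})

test_that("hit counts match the Poisson mean at saturated learning", {
  # stress pinned at the optimum, learning saturated: rate = h_max
  p <- trainee_params(sigma = 0, kappa = 0, tau_learn = 1e-9)
  rec <- simulate_session(p, policy_config("constant"), duration = 600,
                          seed = 8)
  n_hits <- sum(rec$events$kind == "hit")
  expect_lt(abs(n_hits - 720), 3 * sqrt(720))
})

test_that("cohorts have the right size and condition counts", {
  co <- simulate_cohort(1, seed = 2, schedule = session_schedule(1))
  expect_length(co, 3L)
  co <- simulate_cohort(5, seed = 2,
                        schedule = session_schedule(1, task_seconds = 60))
  expect_length(co, 15L)
  conds <- table(vapply(co, `[[`, "", "condition"))
  expect_equal(unname(conds[c("control_constant", "control_time",
                              "stress_adaptive")]), rep(5L, 3),
               ignore_attr = TRUE)
})

test_that("mean grip force tracks mean latent stress across sessions", {
  mf <- ml <- numeric(200)
  for (i in 1:200) {
    rec <- simulate_session(policy = policy_config("constant"),
                            duration = 600, seed = 1000 + i)
    mf[i] <- mean(rec$force$force)
    ml[i] <- mean(rec$latent_stress$latent)
  }
  expect_gt(cor(mf, ml), 0.9)
})

test_that("hit rate is inverted-U in latent stress, peaking at the optimum", {
  # learning saturated so the stress-rate relation is isolated
  p <- trainee_params(sigma = 0.6, tau_learn = 1e-9)
  lat <- list(); hits <- list()
  for (i in 1:30) {
    rec <- simulate_session(p, policy_config("constant"), duration = 600,
                            seed = 2000 + i)
    lat[[i]] <- rec$latent_stress$latent
    ht <- rec$events$t[rec$events$kind == "hit"]
    hits[[i]] <- lat[[i]][pmin(pmax(round(ht * 20) + 1, 1),
                               length(lat[[i]]))]
  }
  lat <- unlist(lat); hits <- unlist(hits)
  breaks <- seq(-2.25, 2.25, by = 0.5)
  occ <- table(cut(lat, breaks)) / 20       # seconds spent per stress bin
  hit_n <- table(cut(hits, breaks))
  rate <- as.numeric(hit_n) / as.numeric(occ)
  centers <- head(breaks, -1) + 0.25
  expect_equal(centers[which.max(rate)], 0)  # peak in the bin holding s_opt
  expect_lt(rate[1], 0.5 * max(rate))        # tails well below the peak
  expect_lt(rate[length(rate)], 0.5 * max(rate))
})

test_that("the closed loop holds latent stress nearer the optimum than a ramp", {
  dev_ad <- dev_ramp <- numeric(100)
  sched <- session_schedule(1)
  for (i in 1:100) {
    dev_ad[i] <- simulate_participant(policy = policy_config("stress_adaptive"),
                                      schedule = sched,
                                      seed = 3000 + i)$mean_abs_latent_dev
    dev_ramp[i] <- simulate_participant(policy = policy_config("time_ramp"),
                                        schedule = sched,
                                        seed = 3000 + i)$mean_abs_latent_dev
  }
  expect_lt(mean(dev_ad), mean(dev_ramp))
})

test_that("rests produce force but no events, and task time collapses rests", {
  rec <- simulate_participant(schedule = session_schedule(2, 120, 60),
                              seed = 21)
  rest <- rec$segments[!rec$segments$task, ]
  for (k in seq_len(nrow(rest)))
    expect_false(any(rec$events$t >= rest$start[k] &
                       rec$events$t < rest$end[k]))
  ev <- task_time_events(rec)
  expect_true(all(ev$t >= 0 & ev$t <= 240))
  expect_equal(nrow(ev), nrow(rec$events))
})
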