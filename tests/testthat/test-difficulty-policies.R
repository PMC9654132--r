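test_that("constant policy holds 6 p/s through the phase, then 30 p/s", {
  cfg <- policy_config("constant")
  expect_equal(speed_constant(5, cfg), 6)
  expect_equal(speed_constant(12, cfg), 30)
  expect_equal(speed_constant(599, cfg), 30)
  expect_error(speed_constant(-1, cfg), class = "sat_input_error")
})

test_that("time ramp gains 2 p/s per completed 5-s interval", {
  cfg <- policy_config("time_ramp")
  expect_equal(speed_time_ramp(11.9, cfg), 6)
  expect_equal(speed_time_ramp(12, cfg), 6)    # zero completed intervals
  expect_equal(speed_time_ramp(23, cfg), 10)   # two completed intervals
  expect_equal(speed_time_ramp(1e5, cfg), cfg$max_speed)
})

test_that("adaptive steps go down over +0.5, up under -0.5, clamp at bounds", {
  cfg <- policy_config("stress_adaptive")
  expect_equal(adaptive_step(0.7, 30, cfg), 28)
  expect_equal(adaptive_step(-0.6, 30, cfg), 32)
  expect_equal(adaptive_step(0.3, 30, cfg), 30)
  expect_equal(adaptive_step(0.9, 2, cfg), 2)        # floor
  expect_equal(adaptive_step(-3, cfg$max_speed, cfg), cfg$max_speed)
  # thresholds are strict: exactly 0.5 does not trigger
  expect_equal(adaptive_step(0.5, 30, cfg), 30)
  expect_equal(adaptive_step(-0.5, 30, cfg), 30)
  expect_error(adaptive_step(NA_real_, 30, cfg), class = "sat_input_error")
})

test_that("run_policy reproduces the session speed profiles", {
  tr <- run_policy(policy_config("constant"), duration = 600)
  expect_s3_class(tr, "difficulty_trace")
  expect_true(all(tr$speed[tr$t < 12] == 6))
  expect_true(all(tr$speed[tr$t >= 12] == 30))

  # sustained high stress drives the speed to the floor at 2 p/s per tick
  cfg <- policy_config("stress_adaptive")
  ss <- data.frame(t = seq(12, 40, by = 0.05), s = 1)
  tr <- run_policy(cfg, ss, duration = 40)
  sp <- tr$speed[tr$t >= 13]
  expect_equal(sp[1], 4)  # one step below initial by the first post-S tick
  expect_true(all(diff(tr$speed[tr$t >= 12]) <= 0))
  expect_equal(min(tr$speed), cfg$min_speed)

  # zero stress stays in the dead zone forever
  ss0 <- data.frame(t = seq(12, 600, by = 0.05), s = 0)
  tr0 <- run_policy(cfg, ss0, duration = 600)
  expect_true(all(tr0$speed == cfg$initial_speed))

  expect_error(run_policy(cfg, NULL, 600), class = "sat_config_error")
})

test_that("adaptive response is monotone, bounded and dead-zone idempotent", {
  cfg <- policy_config("stress_adaptive")
  set.seed(55)
  for (r in 1:50) {
    tt <- seq(12, 72, by = 1) - 0.5
    s2 <- rnorm(length(tt), sd = 1.5)
    s1 <- s2 + runif(length(tt), 0, 1)   # s1 >= s2 everywhere
    tr1 <- run_policy(cfg, data.frame(t = tt, s = s1), 72)
    tr2 <- run_policy(cfg, data.frame(t = tt, s = s2), 72)
    expect_true(all(tr1$speed <= tr2$speed))
    expect_true(all(tr1$speed >= cfg$min_speed & tr1$speed <= cfg$max_speed))
    dz <- run_policy(cfg, data.frame(t = tt, s = runif(length(tt), -0.49, 0.49)), 72)
    expect_true(all(dz$speed == cfg$initial_speed))
  }
})

test_that("the closed-loop speed trace replays through run_policy", {
  rec <- simulate_session(policy = policy_config("stress_adaptive"),
                          duration = 300, seed = 99)
  replay <- run_policy(policy_config("stress_adaptive"),
                       rec$stress[!is.na(rec$stress$s), ], duration = 300)
  expect_equal(replay$speed, rec$speed$speed)
  expect_equal(replay$t, rec$speed$t)
})

test_that("policy configs reject inconsistent settings and read from YAML", {
  expect_error(policy_config(stress_low = 1, stress_high = 0.5),
               class = "sat_config_error")
  expect_error(policy_config(min_speed = 10, initial_speed = 6),
               class = "sat_config_error")
  skip_if_not_installed("yaml")
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("policy: time_ramp", "ramp_step: 4"), p)
  cfg <- read_policy_config(p)
  expect_equal(cfg$policy, "time_ramp")
  expect_equal(cfg$ramp_step, 4)
})
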