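# Observer strategies: d-prime calculus and stochastic simulation.

test_that("strategy d-prime follows propagation of uncertainty", {
  expect_equal(strategy_dprime("speed_change", 1, 1)$d_prime, 0.5)
  expect_equal(round(strategy_dprime("end_speed", 1, 1)$d_prime, 3), 0.354)
  expect_equal(round(strategy_dprime("speed_cue", 1, 1)$d_prime, 3), 0.707)
  # within-interval change beats the single-speed comparison by sqrt(2),
  # at every separation and noise level
  for (delta in c(0.5, 1, 5, 30)) {
    for (sd in c(0.2, 1, 3.5)) {
      expect_equal(strategy_dprime("speed_change", delta, sd)$d_prime /
                   strategy_dprime("end_speed", delta, sd)$d_prime,
                   sqrt(2))
    }
  }
  # scale invariance: common rescaling of signal and noise leaves d' alone
  d1 <- strategy_dprime("speed_cue", 2, 1.3)$d_prime
  d2 <- strategy_dprime("speed_cue", 2 * 7, 1.3 * 7)$d_prime
  expect_equal(d1, d2)
  expect_error(strategy_dprime("speed_change", 1, 0), "noise_sd")
})

test_that("cue extraction summarizes the moving portion of an interval", {
  std <- extract_cues(cond_speed_change$standard, geom)
  expect_equal(std$start_speed, 40)
  expect_equal(std$end_speed, 40)
  expect_equal(std$speed_change, 0)

  lev7 <- extract_cues(cond_speed_change$test_levels[[7]], geom)
  expect_equal(lev7$start_speed, 10)
  expect_equal(lev7$end_speed, 70)
  expect_equal(lev7$speed_change, 60)
  # duration matched exactly; distance matched up to the half-frame left
  # over when the step change lands between frames (43/42 frame split)
  expect_equal(lev7$duration, std$duration)
  expect_lt(abs(lev7$distance - std$distance), lev7$end_speed / 85)

  catch <- extract_cues(cond_duration$catch, geom)
  expect_equal(round(catch$duration, 3), 1.071)  # 91 frames at 85 Hz
  expect_equal(round(catch$distance, 1), 42.8)
})

test_that("noiseless observers make forced choices by their cue", {
  std <- extract_cues(cond_distance$standard, geom)
  fast <- extract_cues(cond_distance$test_levels[[7]], geom)  # 70 cm/s
  catch <- extract_cues(cond_distance$catch, geom)
  quiet <- function(s) observer_model(s, noise_sd = 0)
  set.seed(1)
  expect_true(all(simulate_choices(quiet("speed_cue"), fast, std, 50) == 1L))
  expect_true(all(simulate_choices(quiet("speed_cue"), std, fast, 50) == 2L))
  # catch travels further at equal speed: distance cue picks it, duration
  # cue picks the shorter standard
  expect_true(all(simulate_choices(quiet("distance_cue"), catch, std, 50) == 1L))
  expect_true(all(simulate_choices(quiet("duration_cue"), catch, std, 50) == 2L))
  # identical intervals: ties broken fairly
  ties <- simulate_choices(quiet("speed_cue"), std, std, 2000)
  expect_gt(mean(ties == 1L), 0.45)
  expect_lt(mean(ties == 1L), 0.55)
})

test_that("simulated percent correct tracks Phi(d-prime)", {
  n <- 40000
  set.seed(42)
  std <- extract_cues(cond_speed_change$standard, geom)
  for (case in list(list(strategy = "speed_change", level = 4),
                    list(strategy = "end_speed", level = 6),
                    list(strategy = "start_speed", level = 3))) {
    test <- extract_cues(cond_speed_change$test_levels[[case$level]], geom)
    obs <- observer_model(case$strategy, noise_sd = 12)
    dp <- strategy_dprime(case$strategy, test$speed_change, 12)$d_prime
    pc <- mean(simulate_choices(obs, test, std, n) == 1L)
    p0 <- pnorm(dp)
    expect_lt(abs(pc - p0), 3.5 * sqrt(p0 * (1 - p0) / n))
  }
  # percent correct is invariant under common rescaling of signal and noise
  test <- extract_cues(cond_speed_change$test_levels[[5]], geom)
  dp <- strategy_dprime("end_speed", test$speed_change, 10)$d_prime
  p0 <- pnorm(dp)
  for (scale in c(1, 4)) {
    scaled <- test
    scaled$start_speed <- 40 + (test$start_speed - 40) * scale
    scaled$end_speed <- 40 + (test$end_speed - 40) * scale
    scaled$speed_change <- scaled$end_speed - scaled$start_speed
    pc <- mean(simulate_choices(observer_model("end_speed", 10 * scale),
                                scaled, std, n) == 1L)
    expect_lt(abs(pc - p0), 3.5 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("full lapsing at zero noise yields 75% correct on average", {
  std <- extract_cues(cond_distance$standard, geom)
  fast <- extract_cues(cond_distance$test_levels[[7]], geom)
  obs <- observer_model("speed_cue", noise_sd = 0, lapse_rate = 0.5)
  set.seed(7)
  n <- 20000
  pc <- mean(simulate_choices(obs, fast, std, n) == 1L)
  expect_equal(pc, 0.75, tolerance = 3.5 * sqrt(0.75 * 0.25 / n))
})

test_that("experiment runs have the design's trial structure", {
  obs <- observer_model("speed_cue", 3.5, 0.02)
  rec <- simulate_experiment(cond_duration, obs, seed = 5)
  expect_equal(nrow(rec), 240)                        # 210 main + 30 catch
  expect_equal(sum(rec$is_catch), 30)
  main <- rec[!rec$is_catch, ]
  expect_equal(as.integer(table(main$level_index)), rep(30L, 7))
  expect_equal(as.integer(table(main$block)), rep(70L, 3))
  expect_equal(as.integer(table(rec$block)), rep(80L, 3))
  expect_true(all(rec$chose_interval %in% 1:2))
  expect_true(all(rec$outcome %in% 0:1))

  sc <- simulate_experiment(cond_speed_change,
                            observer_model("end_speed", 3.5), seed = 5)
  expect_equal(nrow(sc), 210)
  expect_equal(sum(sc$is_catch), 0)

  # byte-identical reproduction from the same seed
  rec2 <- simulate_experiment(cond_duration, obs, seed = 5)
  expect_identical(rec, rec2)
  rec3 <- simulate_experiment(cond_duration, obs, seed = 6)
  expect_false(identical(rec, rec3))
})

test_that("a speed-cue observer is at chance on catch trials", {
  obs <- observer_model("speed_cue", 3.5)
  set.seed(9)
  std <- extract_cues(cond_duration$standard, geom)
  catch <- extract_cues(cond_duration$catch, geom)
  n <- 30000
  picked <- mean(simulate_choices(obs, catch, std, n) == 1L)
  band <- qnorm(0.995) * sqrt(0.25 / n)    # binomial 99% band around 0.5
  expect_gt(picked, 0.5 - band)
  expect_lt(picked, 0.5 + band)
})
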