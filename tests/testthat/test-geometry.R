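# World-to-retina geometry: closed forms, frame quantization, conditions.

test_that("angular separation matches the exact closed form and its limits", {
  # high-precision evaluations of 2*atan((S/2)/d) * (180/pi) * 60
  expect_equal(angular_separation(97, geom), 70.87887, tolerance = 1e-6)
  expect_equal(angular_separation(117, geom), 58.76347, tolerance = 1e-6)
  # strictly decreasing in distance, vanishing in the far limit
  d <- seq(2, 500, length.out = 200)
  expect_true(all(diff(angular_separation(d, geom)) < 0))
  expect_lt(angular_separation(1e6, geom), 0.01)
  expect_error(angular_separation(0.5, geom), "distance")
  expect_error(angular_separation(-3, geom), "distance")
})

test_that("expansion rate reproduces the printed retinal speeds at 3 s.f.", {
  expect_equal(signif(expansion_rate(117, 40, geom), 3), 20.1)
  expect_equal(signif(expansion_rate(117, 10, geom), 3), 5.02)
  expect_equal(signif(expansion_rate(112, 70, geom), 3), 38.4)
  expect_equal(signif(expansion_rate(97, 40, geom), 3), 29.2)
  expect_identical(expansion_rate(50, 0, geom), 0)
  # linear in world speed
  expect_equal(expansion_rate(80, 70, geom), 7 * expansion_rate(80, 10, geom))
})

test_that("expansion rate is the derivative of angular separation", {
  # central finite difference along a simulated approach, 1e-4 s steps
  h <- 1e-4
  for (v in c(10, 40, 70)) {
    for (d in c(117, 97, 60, 30)) {
      fd <- (angular_separation(d - v * h, geom) -
             angular_separation(d + v * h, geom)) / (2 * h)
      expect_equal(expansion_rate(d, v, geom), fd, tolerance = 1e-6)
    }
  }
})

test_that("small-angle approximation agrees to <0.05% at viewing distances", {
  for (d in c(50, 97, 117, 200)) {
    approx <- 2 * 40 / d^2 * (180 / pi) * 60
    exact <- expansion_rate(d, 40, geom)
    expect_lt(abs(approx - exact) / exact, 5e-4)
  }
})

test_that("durations quantize to frames with half-counts away from zero", {
  q <- quantize_to_frames(0.41, 85)
  expect_identical(q$n_frames, 35L)
  expect_equal(round(q$realized_duration, 3), 0.412)
  expect_identical(quantize_to_frames(1.0, 85)$n_frames, 85L)
  q5 <- quantize_to_frames(0.5, 85)          # 42.5 frames: tie away from zero
  expect_identical(q5$n_frames, 43L)
  expect_equal(round(q5$realized_duration, 3), 0.506)
  expect_error(quantize_to_frames(-0.1, 85), "non-negative")
})

test_that("traces accelerate under constant approach and respect holds", {
  tr <- simulate_trace(cond_speed_change$standard, geom)
  moving <- tr$world_speed_cm_s > 0
  expect_true(all(diff(tr$distance_cm[moving]) < 0))
  expect_true(all(diff(tr$expansion_arcmin_per_s[moving]) > 0))
  expect_true(all(tr$expansion_arcmin_per_s[!moving] == 0))
  expect_equal(signif(tr$expansion_arcmin_per_s[moving][1], 3), 20.1)

  # every schedule of every condition accelerates within constant segments
  for (cond in all_conditions) {
    for (sched in c(list(cond$standard), cond$test_levels,
                    if (!is.null(cond$catch)) list(cond$catch))) {
      tr <- simulate_trace(sched, geom)
      v <- tr$world_speed_cm_s
      for (sp in unique(v[v > 0])) {
        expect_true(all(diff(tr$expansion_arcmin_per_s[v == sp]) > 0))
      }
    }
  }

  still <- interval_schedule(100, list(motion_segment(0, 40)), "standard")
  trs <- simulate_trace(still, geom)
  expect_true(all(trs$expansion_arcmin_per_s == 0))
  expect_equal(length(unique(trs$separation_arcmin)), 1L)

  # step change is a factor-7 jump in expansion rate at equal distance
  expect_equal(expansion_rate(111.94, 70, geom),
               7 * expansion_rate(111.94, 10, geom))

  crash <- interval_schedule(10, list(motion_segment(70, 50)), "test")
  expect_error(simulate_trace(crash, geom), "past the eye")
})

test_that("condition builders realize the design's schedules", {
  # speed-change levels: slow/fast pairs ending at (10, 70)
  lev7 <- cond_speed_change$test_levels[[7]]
  speeds <- vapply(lev7$segments, function(s) s$world_speed, numeric(1))
  expect_equal(speeds, c(0, 10, 70))
  expect_identical(cond_speed_change$n_catch, 0L)
  expect_null(cond_speed_change$catch)
  # test intervals match the standard's duration exactly and its distance
  # up to the half-frame remainder of the 43/42 split at the step change
  for (lev in cond_speed_change$test_levels) {
    expect_equal(schedule_motion_duration(lev, geom), 1.0)
    expect_lt(abs(schedule_distance(lev, geom) -
                    schedule_distance(cond_speed_change$standard, geom)),
              70 / 85)
  }

  # duration condition: common simulated distance within one frame's travel
  for (lev in cond_duration$test_levels) {
    v <- lev$segments[[2]]$world_speed
    expect_lt(abs(schedule_distance(lev, geom) - 28.7), v / 85)
  }

  # distance condition: identical frame counts across levels
  frames <- vapply(cond_distance$test_levels,
                   function(l) l$segments[[2]]$n_frames, integer(1))
  expect_true(all(frames == frames[1]))
  expect_equal(vapply(cond_distance$test_levels,
                      function(l) l$segments[[2]]$world_speed, numeric(1)),
               seq(40, 70, by = 5))

  # catch interval: 40 cm/s for 1.070 s quantized -> 42.8 cm
  expect_equal(round(schedule_distance(cond_distance$catch, geom), 1), 42.8)
  expect_identical(cond_duration$n_catch, 30L)

  expect_error(build_condition("unknown"), "arg")
})

test_that("conditions round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  condition_to_json(cond_duration, path)
  back <- condition_from_json(path)
  expect_equal(back$name, "duration")
  expect_equal(back$n_catch, 30L)
  expect_equal(schedule_distance(back$catch, geom),
               schedule_distance(cond_duration$catch, geom))
  expect_equal(vapply(back$test_levels, schedule_distance, numeric(1),
                      geometry = geom),
               vapply(cond_duration$test_levels, schedule_distance,
                      numeric(1), geometry = geom))
})
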