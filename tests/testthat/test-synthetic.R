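# Cohort generation, serialization, and recovery of generating parameters.

test_that("the default cohort reproduces the study's trial structure", {
  cfg <- cohort_config(master_seed = 21)
  gen <- generate_cohort(cfg)
  trials <- gen$trials
  ids <- unique(trials$participant_id)
  expect_length(ids, 18)
  expect_length(grep("^SC", ids), 11)
  expect_length(grep("^SD", ids), 7)
  per <- table(trials$participant_id, trials$condition)
  expect_true(all(per[grep("^SC", rownames(per)), "speed_change"] == 210))
  expect_true(all(per[grep("^SD", rownames(per)), "duration"] == 240))
  expect_true(all(per[grep("^SD", rownames(per)), "distance"] == 240))
  catch <- trials[trials$is_catch, ]
  expect_true(all(table(catch$participant_id, catch$condition) == 30))
  expect_false(any(trials$is_catch[trials$condition == "speed_change"]))
})

test_that("generation is deterministic in the seeds", {
  p <- participant_profile("X", c("duration", "distance"),
                           strategy = "speed_cue",
                           catch_strategy = "distance_cue",
                           noise_sd = 3.5, seed = 77)
  r1 <- generate_participant(p, all_conditions)
  r2 <- generate_participant(p, all_conditions)
  expect_identical(r1, r2)

  g1 <- generate_cohort(cohort_config(2, 2, master_seed = 5))
  g2 <- generate_cohort(cohort_config(2, 2, master_seed = 5))
  expect_identical(g1$trials, g2$trials)
  g3 <- generate_cohort(cohort_config(2, 2, master_seed = 6))
  expect_false(identical(g1$trials, g3$trials))
})

test_that("catch behaviour reflects the generating catch strategy", {
  # near-noiseless distance-cue user picks the catch interval every time
  p <- participant_profile("D", c("duration", "distance"),
                           strategy = "speed_cue",
                           catch_strategy = "distance_cue",
                           noise_sd = 1e-6, lapse_rate = 0, seed = 8)
  rec <- generate_participant(p, all_conditions)
  tab <- catch_table(rec)
  expect_true(all(tab$percent == 100))
  expect_true(all(tab$category == "distance"))

  # duration-cue user always prefers the shorter standard interval
  p2 <- participant_profile("T", c("duration", "distance"),
                            strategy = "speed_cue",
                            catch_strategy = "duration_cue",
                            noise_sd = 1e-6, lapse_rate = 0, seed = 8)
  tab2 <- catch_table(generate_participant(p2, all_conditions))
  expect_true(all(tab2$percent == 0))
  expect_true(all(tab2$category == "duration"))

  # full trial-to-trial switching to the speed cue puts catch picks at chance
  p3 <- participant_profile("S", "duration", strategy = "speed_cue",
                            catch_strategy = "distance_cue", noise_sd = 3.5,
                            lapse_rate = 0, seed = 8, catch_switch_prob = 1)
  tab3 <- catch_table(generate_participant(p3, all_conditions))
  expect_identical(tab3$category, "speed")
})

test_that("speed-cue catch users classify as speed at the nominal rate", {
  set.seed(909)
  std <- extract_cues(cond_duration$standard, geom)
  catch <- extract_cues(cond_duration$catch, geom)
  obs <- observer_model("speed_cue", 3.5)
  n_participants <- 3000
  choices <- simulate_choices(obs, catch, std, n_participants * 30)
  k <- colSums(matrix(choices == 1L, nrow = 30))
  cats <- vapply(k, function(ki) classify_cue_use(ki, 30)$category,
                 character(1))
  expect_gte(mean(cats == "speed"), 0.93)
  expect_gt(mean(k) / 30, 0.48)
  expect_lt(mean(k) / 30, 0.52)
})

test_that("trial files round-trip and invalid rows are reported", {
  cfg <- cohort_config(1, 1, master_seed = 3)
  dir <- withr::local_tempdir()
  gen <- generate_cohort(cfg, dir = dir)
  files <- list.files(dir, pattern = "^trials_", full.names = TRUE)
  expect_length(files, 2)
  back <- read_trials(files[1])
  orig <- gen$trials[gen$trials$participant_id ==
                       back$participant_id[1], ]
  rownames(orig) <- NULL
  expect_equal(back, orig)

  # unknown columns survive the round trip
  extra <- back
  extra$rt_ms <- seq_len(nrow(extra))
  p2 <- file.path(dir, "trials_extra.csv")
  write_trials(extra, p2)
  expect_equal(read_trials(p2)$rt_ms, extra$rt_ms)

  # malformed rows are reported with their numbers
  bad <- back
  bad$chose_interval[5] <- 3L
  pbad <- file.path(dir, "trials_bad.csv")
  write_trials(bad, pbad)
  expect_error(read_trials(pbad), "row\\(s\\): 5")
  expect_error(read_trials(file.path(dir, "nope.csv")), "no such file")
})

test_that("the manifest checksums match a regenerated cohort", {
  cfg <- cohort_config(2, 1, master_seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_cohort(cfg, dir = d1)
  g2 <- generate_cohort(cfg, dir = d2)
  md5_1 <- vapply(g1$manifest$files, function(f) f$md5, character(1))
  md5_2 <- vapply(g2$manifest$files, function(f) f$md5, character(1))
  expect_identical(md5_1, md5_2)
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(m$master_seed, 13)
  expect_equal(m$n_participants, 3)
})

test_that("an empty cohort yields a valid empty manifest", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(cohort_config(0, 0, master_seed = 1), dir = dir)
  expect_equal(nrow(gen$trials), 0)
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(m$n_participants, 0)
})

test_that("profile validation rejects inconsistent settings", {
  expect_error(participant_profile("x", "duration", "speed_cue",
                                   catch_strategy = "end_speed",
                                   noise_sd = 3))
  expect_error(participant_profile("x", "duration", "speed_cue",
                                   catch_strategy = "speed_cue",
                                   noise_sd = -1))
  expect_error(generate_participant(
    participant_profile("x", "distance", "speed_cue", "speed_cue", 3),
    conditions = list(duration = cond_duration)), "condition_set")
})

test_that("perfectly correlated catch strategies yield correlated catch rates", {
  cfg <- cohort_config(0, 7, master_seed = 31,
                       catch_strategy_correlation = 1.0)
  gen <- generate_cohort(cfg)
  tab <- catch_table(gen$trials)
  dur <- tab[tab$condition == "duration", ]
  dis <- tab[tab$condition == "distance", ]
  shared <- intersect(dur$participant_id, dis$participant_id)
  r <- pearson(dur$percent[match(shared, dur$participant_id)],
               dis$percent[match(shared, dis$participant_id)])$r
  expect_gt(r, 0.9)
})
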