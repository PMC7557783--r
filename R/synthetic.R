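# Synthetic cohort generation: trial-level data with the design's structure.

CATCH_STRATEGIES <- c("speed_cue", "distance_cue", "duration_cue")

#' Participant profile for the synthetic generator
#'
#' Describes one simulated participant: which conditions they ran (the
#' speed-change group runs only `speed_change`; the speed-discrimination
#' group runs `duration` and `distance`), the decision strategy per
#' condition, the cue consulted on catch trials (which may differ from the
#' main-trial strategy, emulating cue switching between trial types),
#' internal noise, lapse rate and a private seed.
#'
#' On catch trials the cue reading noise is rescaled to the cue's units so
#' the relative noise matches the speed noise: the distance-cue noise is
#' `noise_sd * standard_distance / standard_speed` (cm) and the
#' duration-cue noise `noise_sd * standard_duration / standard_speed` (s).
#'
#' @param id Participant label.
#' @param condition_set Character vector of condition names.
#' @param strategy Main-trial strategy: a single name, or a named vector
#'   with one entry per condition.
#' @param catch_strategy One of `"speed_cue"`, `"distance_cue"`,
#'   `"duration_cue"`; may be a named vector per condition.
#' @param noise_sd Cue-reading noise in cm/s (> 0).
#' @param lapse_rate Lapse probability in \[0, 0.5\].
#' @param seed Integer seed for this participant's trials.
#' @param catch_switch_prob Probability per catch trial of consulting the
#'   main-trial cue instead of `catch_strategy` (trial-to-trial switching;
#'   0 = always the catch cue).
#' @return An object of class `"participant_profile"`.
#' @export
participant_profile <- function(id, condition_set, strategy, catch_strategy,
                                noise_sd, lapse_rate = 0.02, seed = 1L,
                                catch_switch_prob = 0) {
  stopifnot(length(id) == 1L,
            all(condition_set %in% c("speed_change", "duration", "distance")),
            is.numeric(noise_sd), noise_sd > 0,
            lapse_rate >= 0, lapse_rate <= 0.5,
            catch_switch_prob >= 0, catch_switch_prob <= 1)
  strategy <- expand_per_condition(strategy, condition_set, OBSERVER_STRATEGIES)
  catch_strategy <- expand_per_condition(catch_strategy, condition_set,
                                         CATCH_STRATEGIES)
  structure(
    list(id = as.character(id), condition_set = condition_set,
         strategy = strategy, catch_strategy = catch_strategy,
         noise_sd = noise_sd, lapse_rate = lapse_rate,
         seed = as.integer(seed), catch_switch_prob = catch_switch_prob),
    class = "participant_profile"
  )
}

expand_per_condition <- function(x, condition_set, allowed) {
  if (is.null(names(x))) {
    stopifnot(length(x) == 1L)
    x <- stats::setNames(rep(x, length(condition_set)), condition_set)
  }
  stopifnot(all(condition_set %in% names(x)), all(x %in% allowed))
  x[condition_set]
}

#' Cohort configuration
#'
#' Defaults reproduce the study structure: 11 speed-change participants and
#' 7 speed-discrimination participants (who each run both the duration and
#' distance conditions). When `profiles` is `NULL`, default profiles are
#' drawn deterministically from `master_seed`:
#' \itemize{
#'   \item speed-change participants use the `end_speed` strategy — the
#'     sub-optimal between-interval comparison the group data were
#'     consistent with — with log-normal individual noise around 3.5 cm/s;
#'   \item speed-discrimination participants use `speed_cue` on main
#'     trials, with catch-trial cues mixed 3 distance / 3 speed /
#'     1 duration;
#'   \item with probability `catch_strategy_correlation` a participant
#'     keeps the same catch cue in both conditions, otherwise the distance-
#'     condition catch cue is re-drawn from the mixture — 1.0 emulates the
#'     observed cross-condition consistency of cue use.
#' }
#'
#' @param n_speed_change Number of speed-change participants.
#' @param n_speed_discrimination Number of speed-discrimination
#'   participants.
#' @param profiles Optional list of [participant_profile()]s overriding the
#'   defaults.
#' @param master_seed Integer master seed; all per-participant seeds derive
#'   from it.
#' @param noise_sd_meanlog,noise_sd_sdlog Log-normal parameters of the
#'   individual noise distribution (cm/s).
#' @param lapse_rate Shared lapse rate.
#' @param catch_strategy_correlation Probability of keeping the same catch
#'   cue across the two speed-discrimination conditions.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_speed_change = 11, n_speed_discrimination = 7,
                          profiles = NULL, master_seed = 1L,
                          noise_sd_meanlog = log(3.5), noise_sd_sdlog = 0.3,
                          lapse_rate = 0.02,
                          catch_strategy_correlation = 1.0) {
  stopifnot(n_speed_change >= 0, n_speed_discrimination >= 0,
            catch_strategy_correlation >= 0, catch_strategy_correlation <= 1)
  structure(
    list(n_speed_change = as.integer(n_speed_change),
         n_speed_discrimination = as.integer(n_speed_discrimination),
         profiles = profiles, master_seed = as.integer(master_seed),
         noise_sd_meanlog = noise_sd_meanlog,
         noise_sd_sdlog = noise_sd_sdlog, lapse_rate = lapse_rate,
         catch_strategy_correlation = catch_strategy_correlation),
    class = "cohort_config"
  )
}

# Deterministic default profiles from the master seed.
cohort_profiles <- function(config) {
  if (!is.null(config$profiles)) return(config$profiles)
  with_seed(config$master_seed, {
    n_sc <- config$n_speed_change
    n_sd <- config$n_speed_discrimination
    seeds <- sample.int(.Machine$integer.max - 1L, n_sc + n_sd)
    noise <- stats::rlnorm(n_sc + n_sd, config$noise_sd_meanlog,
                           config$noise_sd_sdlog)
    # observed catch-cue mix among 7 speed-discrimination participants
    base_mix <- c("distance_cue", "distance_cue", "distance_cue",
                  "speed_cue", "speed_cue", "speed_cue", "duration_cue")
    catch_dur <- if (n_sd > 0) {
      if (n_sd == length(base_mix)) base_mix
      else sample(CATCH_STRATEGIES, n_sd, replace = TRUE,
                  prob = c(3, 3, 1) / 7)
    } else character(0)
    keep <- stats::runif(n_sd) < config$catch_strategy_correlation
    catch_dist <- ifelse(keep, catch_dur,
                         sample(CATCH_STRATEGIES, n_sd, replace = TRUE,
                                prob = c(3, 3, 1) / 7))
    c(
      lapply(seq_len(n_sc), function(i) {
        participant_profile(
          id = sprintf("SC%02d", i), condition_set = "speed_change",
          strategy = "end_speed", catch_strategy = "speed_cue",
          noise_sd = noise[i], lapse_rate = config$lapse_rate,
          seed = seeds[i])
      }),
      lapply(seq_len(n_sd), function(i) {
        participant_profile(
          id = sprintf("SD%02d", i),
          condition_set = c("duration", "distance"),
          strategy = "speed_cue",
          catch_strategy = c(duration = catch_dur[i],
                             distance = catch_dist[i]),
          noise_sd = noise[n_sc + i], lapse_rate = config$lapse_rate,
          seed = seeds[n_sc + i])
      })
    )
  })
}

catch_noise_sd <- function(catch_strategy, noise_sd, condition) {
  std <- extract_cues(condition$standard, condition$geometry)
  switch(catch_strategy,
         speed_cue = noise_sd,
         distance_cue = noise_sd * std$distance / std$mean_speed,
         duration_cue = noise_sd * std$duration / std$mean_speed)
}

#' Generate all trials for one participant
#'
#' Runs [simulate_experiment()] for every condition in the profile's
#' condition set, with the profile's main-trial observer and a catch-trial
#' observer built from `catch_strategy` (noise rescaled to the catch cue's
#' units). Deterministic given the profile seed.
#'
#' @param profile A [participant_profile()].
#' @param conditions Named list of built conditions covering the profile's
#'   `condition_set`; built on demand when `NULL`.
#' @param geometry A [looming_geometry()] used when building conditions.
#' @return Trial records with a `participant_id` column.
#' @export
generate_participant <- function(profile, conditions = NULL,
                                 geometry = looming_geometry()) {
  stopifnot(inherits(profile, "participant_profile"))
  if (is.null(conditions)) {
    conditions <- stats::setNames(
      lapply(profile$condition_set, build_condition, geometry = geometry),
      profile$condition_set)
  }
  if (!all(profile$condition_set %in% names(conditions))) {
    stop("conditions list does not cover the profile's condition_set",
         call. = FALSE)
  }
  cond_seeds <- with_seed(profile$seed,
                          sample.int(.Machine$integer.max - 1L,
                                     length(profile$condition_set)))
  out <- lapply(seq_along(profile$condition_set), function(i) {
    cname <- profile$condition_set[i]
    cond <- conditions[[cname]]
    obs <- observer_model(profile$strategy[[cname]], profile$noise_sd,
                          profile$lapse_rate)
    catch_obs <- if (cond$n_catch > 0) {
      observer_model(
        profile$catch_strategy[[cname]],
        catch_noise_sd(profile$catch_strategy[[cname]], profile$noise_sd,
                       cond),
        profile$lapse_rate)
    } else obs
    rec <- simulate_experiment(cond, obs, seed = cond_seeds[i],
                               catch_observer = catch_obs,
                               catch_switch_prob = profile$catch_switch_prob)
    cbind(participant_id = profile$id, rec)
  })
  do.call(rbind, out)
}

#' Generate a full synthetic cohort
#'
#' Generates trials for every participant in the configuration. With
#' `dir` given, writes one trial CSV per participant plus a
#' `manifest.json` recording the master seed, the profiles, and an md5
#' checksum per file (so a regenerated cohort can be verified); otherwise
#' returns the combined trials invisibly without touching disk.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory (created if missing).
#' @return List with `trials` (combined data frame), `profiles`, and — if
#'   written — `manifest` (the manifest list) and `dir`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- cohort_profiles(config)
  geometry <- looming_geometry()
  conditions <- stats::setNames(
    lapply(c("speed_change", "duration", "distance"), build_condition,
           geometry = geometry),
    c("speed_change", "duration", "distance"))
  trials_list <- lapply(profiles, generate_participant,
                        conditions = conditions, geometry = geometry)
  trials <- if (length(trials_list)) do.call(rbind, trials_list) else
    empty_trials()
  out <- list(trials = trials, profiles = profiles)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(seq_along(profiles), function(i) {
      path <- file.path(dir, paste0("trials_", profiles[[i]]$id, ".csv"))
      write_trials(trials_list[[i]], path)
      path
    }, character(1))
    manifest <- list(
      master_seed = config$master_seed,
      n_participants = length(profiles),
      profiles = lapply(profiles, unclass),
      files = lapply(files, function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f))))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
    out$dir <- dir
  }
  invisible(out)
}

TRIAL_COLUMNS <- c("participant_id", "condition", "block", "trial_index",
                   "level_index", "x_mode_I", "x_mode_II", "interval_order",
                   "is_catch", "chose_interval", "outcome")

empty_trials <- function() {
  df <- data.frame(participant_id = character(0), condition = character(0),
                   block = integer(0), trial_index = integer(0),
                   level_index = integer(0), x_mode_I = numeric(0),
                   x_mode_II = numeric(0), interval_order = integer(0),
                   is_catch = logical(0), chose_interval = integer(0),
                   outcome = integer(0))
  df
}

#' Write / read trial records
#'
#' Trial CSVs use one row per trial with the columns `participant_id`,
#' `condition`, `block`, `trial_index`, `level_index`, `x_mode_I`,
#' `x_mode_II`, `interval_order`, `is_catch`, `chose_interval`, `outcome`.
#' `read_trials()` validates the schema and reports malformed rows with
#' their row numbers; unknown extra columns are preserved.
#'
#' @param records Trial records data frame.
#' @param path CSV file path.
#' @return `read_trials()` returns the validated data frame.
#' @export
write_trials <- function(records, path) {
  stopifnot(all(TRIAL_COLUMNS %in% names(records)))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing)) {
    stop("trial file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$is_catch <- as.logical(df$is_catch)
  bad <- which(
    !(df$chose_interval %in% c(1L, 2L)) |
    !(df$interval_order %in% c(1L, 2L)) |
    !(df$outcome %in% c(0L, 1L)) |
    is.na(df$is_catch) |
    !(df$condition %in% c("speed_change", "duration", "distance")) |
    (!df$is_catch & (is.na(df$level_index) | df$level_index < 1))
  )
  if (length(bad)) {
    stop("malformed trial rows in ", path, " at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  df
}

#' Read every trial CSV in a directory
#'
#' @param dir Directory containing `trials_*.csv` files.
#' @return Combined trial records.
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "^trials_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no trial files (trials_*.csv) found in ", dir, call. = FALSE)
  }
  do.call(rbind, lapply(files, read_trials))
}
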