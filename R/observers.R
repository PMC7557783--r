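# Signal-detection observer models for the candidate decision strategies.

OBSERVER_STRATEGIES <- c("speed_change", "end_speed", "start_speed",
                         "speed_cue", "distance_cue", "duration_cue")

#' Observer model
#'
#' A stochastic 2IFC observer defined by a decision strategy, the standard
#' deviation of the Gaussian noise corrupting each cue reading, and a lapse
#' rate. Strategies:
#' \describe{
#'   \item{`speed_change`}{Compare the within-interval speed change
#'     (end − start) between intervals; the interval with the larger signed
#'     change is chosen. The standard's change is 0 and the test's is
#'     positive by design, so this is the double-difference strategy.}
#'   \item{`end_speed` / `start_speed`}{Compare one speed reading between
#'     intervals: the larger end speed, or the smaller start speed (the test
#'     interval starts slower than the standard), marks the test interval.}
#'   \item{`speed_cue`}{Pick the interval with the larger mean speed.}
#'   \item{`distance_cue`}{Pick the interval whose stimulus travelled
#'     further (further may be read as faster).}
#'   \item{`duration_cue`}{Pick the interval with the shorter motion
#'     duration (same distance in less time reads as faster).}
#' }
#' Every cue reading within a trial receives independent Gaussian noise with
#' standard deviation `noise_sd`, in the cue's own units. With probability
#' `lapse_rate` the choice is replaced by a fair coin.
#'
#' @param strategy One of `"speed_change"`, `"end_speed"`, `"start_speed"`,
#'   `"speed_cue"`, `"distance_cue"`, `"duration_cue"`.
#' @param noise_sd Standard deviation of each cue reading (cue units, >= 0).
#' @param lapse_rate Probability in \[0, 0.5\] of a random response.
#' @return An object of class `"observer_model"`.
#' @export
observer_model <- function(strategy, noise_sd = 1, lapse_rate = 0) {
  strategy <- match.arg(strategy, OBSERVER_STRATEGIES)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.numeric(lapse_rate), length(lapse_rate) == 1L,
            lapse_rate >= 0, lapse_rate <= 0.5)
  structure(list(strategy = strategy, noise_sd = noise_sd,
                 lapse_rate = lapse_rate),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Observer:", x$strategy, "(noise_sd =", x$noise_sd,
      ", lapse =", x$lapse_rate, ")\n")
  invisible(x)
}

#' Noiseless cue summary of an interval
#'
#' Summarizes the moving portion of a schedule (stationary holds excluded)
#' into the quantities an observer could read out: start and end speed, mean
#' speed, motion duration, distance travelled, and the within-interval speed
#' change (end − start; 0 for constant-speed intervals).
#'
#' @param schedule An [interval_schedule()].
#' @param geometry A [looming_geometry()].
#' @return An object of class `"interval_cues"`.
#' @export
extract_cues <- function(schedule, geometry = looming_geometry()) {
  moving <- Filter(function(s) s$world_speed != 0 && s$n_frames > 0,
                   schedule$segments)
  if (length(moving) == 0L) {
    start <- end <- mean_v <- dist <- dur <- 0
  } else {
    start <- moving[[1L]]$world_speed
    end <- moving[[length(moving)]]$world_speed
    frames <- vapply(moving, function(s) s$n_frames, integer(1))
    speeds <- vapply(moving, function(s) s$world_speed, numeric(1))
    dur <- sum(frames) / geometry$refresh_rate
    dist <- sum(speeds * frames) / geometry$refresh_rate
    mean_v <- dist / dur
  }
  structure(list(start_speed = start, end_speed = end, mean_speed = mean_v,
                 duration = dur, distance = dist, speed_change = end - start,
                 label = schedule$label),
            class = "interval_cues")
}

#' d-prime of a decision strategy by propagation of uncertainty
#'
#' For a speed-change design whose test interval steps from
#' `standard − delta/2` to `standard + delta/2`, each noisy speed reading
#' carries variance `noise_sd^2` and the strategies give:
#' \describe{
#'   \item{`speed_change`}{double difference (e1−s1) − (e2−s2): mean `delta`,
#'     variance `4 * noise_sd^2`, d' = delta / (2 noise_sd).}
#'   \item{`end_speed` / `start_speed`}{single cross-interval difference:
#'     mean `delta/2`, variance `2 * noise_sd^2`,
#'     d' = delta / (2 sqrt(2) noise_sd).}
#'   \item{`speed_cue` / `distance_cue` / `duration_cue`}{between-interval
#'     comparison of one cue in a speed-discrimination design where the full
#'     difference `delta` sits between the intervals: mean `delta`, variance
#'     `2 * noise_sd^2`, d' = delta / (sqrt(2) noise_sd).}
#' }
#' With `delta = 1` and unit noise these give 0.5, 0.354 and 0.707: the
#' within-interval change strategy beats the single-speed comparison by
#' sqrt(2), and a plain between-interval speed comparison beats both.
#'
#' @param strategy Strategy name (see [observer_model()]).
#' @param delta Full cue separation (cue units, >= 0): the within-test-
#'   interval speed change for the speed-change design, or the
#'   between-interval cue difference for speed discrimination.
#' @param noise_sd Standard deviation of one cue reading (> 0).
#' @return An object of class `"dprime_result"` with `strategy`,
#'   `mean_difference`, `variance`, `d_prime`.
#' @export
strategy_dprime <- function(strategy, delta, noise_sd = 1) {
  strategy <- match.arg(strategy, OBSERVER_STRATEGIES)
  stopifnot(is.numeric(delta), delta >= 0, is.numeric(noise_sd), noise_sd > 0)
  if (strategy == "speed_change") {
    m <- delta; v <- 4 * noise_sd^2
  } else if (strategy %in% c("end_speed", "start_speed")) {
    m <- delta / 2; v <- 2 * noise_sd^2
  } else {
    m <- delta; v <- 2 * noise_sd^2
  }
  structure(list(strategy = strategy, mean_difference = m, variance = v,
                 d_prime = m / sqrt(v)),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("Strategy %s: mean difference %.4g, variance %.4g, d' = %.4g\n",
              x$strategy, x$mean_difference, x$variance, x$d_prime))
  invisible(x)
}

# Decision variable read from one interval, for n independent trials.
# Positive-is-test orientation is handled by the sign column below.
read_decision_variable <- function(strategy, cues, noise_sd, n) {
  noise <- function() stats::rnorm(n, 0, noise_sd)
  switch(strategy,
    speed_change = (cues$end_speed + noise()) - (cues$start_speed + noise()),
    end_speed = cues$end_speed + noise(),
    start_speed = -(cues$start_speed + noise()),  # smaller start marks the test
    speed_cue = cues$mean_speed + noise(),
    distance_cue = cues$distance + noise(),
    duration_cue = -(cues$duration + noise())     # shorter duration reads faster
  )
}

#' Simulate many independent 2IFC choices between two fixed intervals
#'
#' Vectorized core of the observer: draws `n` independent trials in which
#' interval 1 carries `cues1` and interval 2 carries `cues2`, and applies
#' the observer's decision rule with fresh noise per cue reading per trial.
#' Exact ties are broken by a fair coin; lapses replace the choice by a fair
#' coin. Uses the current RNG state.
#'
#' @param observer An [observer_model()].
#' @param cues1,cues2 [extract_cues()] summaries of the two intervals.
#' @param n Number of independent trials.
#' @return Integer vector of choices in `{1, 2}`.
#' @export
simulate_choices <- function(observer, cues1, cues2, n = 1L) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(cues1, "interval_cues"), inherits(cues2, "interval_cues"),
            n >= 1L)
  dv1 <- read_decision_variable(observer$strategy, cues1, observer$noise_sd, n)
  dv2 <- read_decision_variable(observer$strategy, cues2, observer$noise_sd, n)
  choice <- ifelse(dv1 > dv2, 1L,
            ifelse(dv2 > dv1, 2L,
                   sample(c(1L, 2L), n, replace = TRUE)))
  if (observer$lapse_rate > 0) {
    lapse <- stats::runif(n) < observer$lapse_rate
    if (any(lapse)) {
      choice[lapse] <- sample(c(1L, 2L), sum(lapse), replace = TRUE)
    }
  }
  as.integer(choice)
}

#' Decide a single 2IFC trial
#'
#' @inheritParams simulate_choices
#' @return `1L` or `2L`, the chosen interval.
#' @export
decide_trial <- function(observer, cues1, cues2) {
  simulate_choices(observer, cues1, cues2, 1L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Stimulus axis values for one level of a condition (see level_axis()).
level_axis_values <- function(condition) {
  cues <- lapply(condition$test_levels, extract_cues, geometry = condition$geometry)
  std <- extract_cues(condition$standard, condition$geometry)
  if (condition$name == "speed_change") {
    x_I <- vapply(cues, function(c) c$speed_change, numeric(1))
    x_II <- vapply(cues, function(c) c$end_speed - std$end_speed, numeric(1))
  } else {
    x_I <- rep(NA_real_, length(cues))
    x_II <- vapply(cues, function(c) c$start_speed - std$start_speed, numeric(1))
  }
  list(x_I = x_I, x_II = x_II)
}

#' Simulate a full experimental run for one observer
#'
#' Runs the 2IFC method-of-constant-stimuli design of a built condition:
#' `trials_per_level` trials at each of the 7 levels (3 blocks of 10), plus
#' `n_catch` catch trials interleaved uniformly at random within blocks in
#' the speed-discrimination conditions. The interval containing the test
#' (or catch) stimulus is a fair Bernoulli draw per trial. Reproducible
#' given `seed`.
#'
#' @param condition A [build_condition()] result.
#' @param observer An [observer_model()] used on main trials.
#' @param seed Integer seed (optional; uses current RNG state if `NULL`).
#' @param catch_observer Observer used on catch trials; defaults to
#'   `observer`. Letting it differ supports generators in which the cue
#'   consulted on catch trials is not the main-task cue.
#' @param catch_switch_prob Probability, per catch trial, that the main
#'   observer is consulted instead of `catch_observer` (trial-to-trial cue
#'   switching; 0 = never).
#' @return A data frame of trial records with columns `condition`, `block`,
#'   `trial_index`, `level_index`, `x_mode_I`, `x_mode_II`, `interval_order`
#'   (which interval held the test/catch), `is_catch`, `chose_interval`,
#'   `outcome` (1 = chose the test/catch interval).
#' @export
simulate_experiment <- function(condition, observer, seed = NULL,
                                catch_observer = observer,
                                catch_switch_prob = 0) {
  stopifnot(inherits(condition, "condition_spec"),
            inherits(observer, "observer_model"),
            catch_switch_prob >= 0, catch_switch_prob <= 1)
  with_seed(seed, {
    geom <- condition$geometry
    std_cues <- extract_cues(condition$standard, geom)
    level_cues <- lapply(condition$test_levels, extract_cues, geometry = geom)
    axis <- level_axis_values(condition)
    n_levels <- length(level_cues)
    n_blocks <- 3L
    per_block <- condition$trials_per_level / n_blocks
    catch_per_block <- condition$n_catch / n_blocks
    catch_cues <- if (!is.null(condition$catch))
      extract_cues(condition$catch, geom)

    blocks <- lapply(seq_len(n_blocks), function(b) {
      lev <- rep(seq_len(n_levels), each = per_block)
      is_catch <- rep(FALSE, length(lev))
      if (catch_per_block > 0) {
        lev <- c(lev, rep(NA_integer_, catch_per_block))
        is_catch <- c(is_catch, rep(TRUE, catch_per_block))
      }
      ord <- sample.int(length(lev))          # random interleaving in block
      data.frame(block = b, level_index = lev[ord], is_catch = is_catch[ord])
    })
    trials <- do.call(rbind, blocks)
    trials$trial_index <- seq_len(nrow(trials))
    trials$interval_order <- sample(c(1L, 2L), nrow(trials), replace = TRUE)

    chose <- integer(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tc <- if (trials$is_catch[i]) catch_cues else
        level_cues[[trials$level_index[i]]]
      obs <- if (trials$is_catch[i]) {
        if (catch_switch_prob > 0 && stats::runif(1) < catch_switch_prob)
          observer else catch_observer
      } else observer
      if (trials$interval_order[i] == 1L) {
        chose[i] <- decide_trial(obs, tc, std_cues)
      } else {
        chose[i] <- decide_trial(obs, std_cues, tc)
      }
    }
    trials$chose_interval <- chose
    trials$outcome <- as.integer(chose == trials$interval_order)
    trials$x_mode_I <- ifelse(trials$is_catch, NA_real_,
                              axis$x_I[trials$level_index])
    trials$x_mode_II <- ifelse(trials$is_catch, NA_real_,
                               axis$x_II[trials$level_index])
    trials$condition <- condition$name
    trials[, c("condition", "block", "trial_index", "level_index",
               "x_mode_I", "x_mode_II", "interval_order", "is_catch",
               "chose_interval", "outcome")]
  })
}
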