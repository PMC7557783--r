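# Stimulus geometry: constant world speed in depth -> retinal expansion.

#' Arcminutes per radian
#'
#' Conversion constant used throughout: 1 rad = (180/pi) * 60 arcmin.
#' @keywords internal
ARCMIN_PER_RAD <- (180 / pi) * 60

#' Looming stimulus geometry
#'
#' Fixed physical parameters of the looming display: a pair of horizontal
#' lines with a simulated physical separation `object_separation` (cm),
#' viewed from `fixation_distance` (cm), rendered at `refresh_rate` frames
#' per second. Approach along the depth axis decreases the distance from the
#' eye; the angular separation of the lines grows as the simulated object
#' nears.
#'
#' @param object_separation Simulated separation of the two lines in cm.
#' @param fixation_distance Viewing distance to the fixation plane in cm.
#' @param refresh_rate Display refresh rate in frames per second.
#' @return An object of class `"looming_geometry"`.
#' @examples
#' geom <- looming_geometry()
#' angular_separation(97, geom)  # separation at the fixation plane
#' @export
looming_geometry <- function(object_separation = 2,
                             fixation_distance = 97,
                             refresh_rate = 85) {
  stopifnot(
    is.numeric(object_separation), length(object_separation) == 1L,
    is.finite(object_separation), object_separation > 0,
    is.numeric(fixation_distance), length(fixation_distance) == 1L,
    is.finite(fixation_distance), fixation_distance > 0,
    is.numeric(refresh_rate), length(refresh_rate) == 1L,
    is.finite(refresh_rate), refresh_rate > 0
  )
  structure(
    list(
      object_separation = object_separation,
      fixation_distance = fixation_distance,
      refresh_rate = refresh_rate
    ),
    class = "looming_geometry"
  )
}

#' @export
print.looming_geometry <- function(x, ...) {
  cat("Looming geometry: separation", x$object_separation, "cm, fixation",
      x$fixation_distance, "cm,", x$refresh_rate, "Hz\n")
  invisible(x)
}

check_distance <- function(distance, geometry) {
  if (!all(is.finite(distance)) || any(distance <= geometry$object_separation / 2)) {
    stop("distance must be finite and greater than object_separation/2 (",
         geometry$object_separation / 2, " cm)", call. = FALSE)
  }
}

#' Angular separation of the looming lines
#'
#' The retinal angle subtended by two lines a physical distance S apart at
#' viewing distance d is `2 * atan((S/2)/d)`, converted to arcmin. It is
#' strictly decreasing in distance and vanishes in the far limit.
#'
#' @param distance Distance(s) from the eye in cm; must exceed S/2.
#' @param geometry A [looming_geometry()].
#' @return Angular separation in arcmin (vectorized over `distance`).
#' @export
angular_separation <- function(distance, geometry = looming_geometry()) {
  check_distance(distance, geometry)
  S <- geometry$object_separation
  2 * atan((S / 2) / distance) * ARCMIN_PER_RAD
}

#' Retinal expansion rate under approach at constant world speed
#'
#' Analytic time derivative of [angular_separation()] when the simulated
#' object approaches at `world_speed` (cm/s): `S * v / (d^2 + (S/2)^2)` in
#' rad/s, converted to arcmin/s. Linear in speed; grows as the object nears,
#' which is why constant world speed yields an accelerating retinal speed.
#'
#' @param distance Distance(s) from the eye in cm; must exceed S/2.
#' @param world_speed Approach speed in cm/s (positive toward the observer).
#' @param geometry A [looming_geometry()].
#' @return Expansion rate in arcmin/s.
#' @examples
#' expansion_rate(117, 40)  # 20.1 arcmin/s at the rendered start distance
#' @export
expansion_rate <- function(distance, world_speed, geometry = looming_geometry()) {
  check_distance(distance, geometry)
  stopifnot(all(is.finite(world_speed)))
  S <- geometry$object_separation
  S * world_speed / (distance^2 + (S / 2)^2) * ARCMIN_PER_RAD
}

#' Quantize a duration to whole display frames
#'
#' Durations are realized on the display as integer frame counts:
#' `n_frames = round(duration * refresh_rate)` with half-counts rounded away
#' from zero, and the realized duration is `n_frames / refresh_rate`. At
#' 85 Hz this maps a nominal 0.41 s to 35 frames (0.412 s realized) and a
#' nominal 0.5 s to 43 frames (0.506 s).
#'
#' @param duration Nominal duration in seconds (>= 0).
#' @param refresh_rate Frames per second.
#' @return A list with `n_frames` and `realized_duration` (seconds).
#' @export
quantize_to_frames <- function(duration, refresh_rate = 85) {
  stopifnot(is.numeric(duration), all(is.finite(duration)), refresh_rate > 0)
  if (any(duration < 0)) stop("duration must be non-negative", call. = FALSE)
  # round half away from zero (base round() rounds half to even)
  n <- floor(duration * refresh_rate + 0.5)
  list(n_frames = as.integer(n), realized_duration = n / refresh_rate)
}

#' Piecewise-constant motion segment
#'
#' @param world_speed Speed toward the observer in cm/s (0 = stationary).
#' @param n_frames Number of display frames the segment lasts.
#' @return An object of class `"motion_segment"`.
#' @export
motion_segment <- function(world_speed, n_frames) {
  stopifnot(is.numeric(world_speed), length(world_speed) == 1L,
            is.finite(world_speed),
            length(n_frames) == 1L, n_frames >= 0,
            n_frames == as.integer(n_frames))
  structure(list(world_speed = unname(world_speed),
                 n_frames = as.integer(unname(n_frames))),
            class = "motion_segment")
}

#' Stimulus interval schedule
#'
#' An ordered list of [motion_segment()]s defining one 2IFC interval,
#' starting at `start_distance` cm from the eye. Labels distinguish the
#' standard, test and catch intervals of the experimental conditions.
#'
#' @param start_distance Starting distance from the eye in cm.
#' @param segments List of [motion_segment()] objects.
#' @param label One of `"standard"`, `"test"`, `"catch"`.
#' @return An object of class `"interval_schedule"`.
#' @export
interval_schedule <- function(start_distance, segments,
                              label = c("standard", "test", "catch")) {
  label <- match.arg(label)
  stopifnot(is.numeric(start_distance), length(start_distance) == 1L,
            is.finite(start_distance), start_distance > 0,
            is.list(segments), length(segments) >= 1L)
  ok <- vapply(segments, inherits, logical(1), "motion_segment")
  if (!all(ok)) stop("all segments must be motion_segment objects", call. = FALSE)
  structure(list(start_distance = start_distance, segments = segments,
                 label = label),
            class = "interval_schedule")
}

schedule_frame_speeds <- function(schedule) {
  unlist(lapply(schedule$segments,
                function(s) rep(s$world_speed, s$n_frames)))
}

#' Total simulated distance travelled over a schedule
#' @param schedule An [interval_schedule()].
#' @param geometry A [looming_geometry()].
#' @return Distance in cm.
#' @export
schedule_distance <- function(schedule, geometry = looming_geometry()) {
  sum(schedule_frame_speeds(schedule)) / geometry$refresh_rate
}

#' Duration of the moving portion of a schedule
#' @inheritParams schedule_distance
#' @return Seconds of nonzero-speed frames.
#' @export
schedule_motion_duration <- function(schedule, geometry = looming_geometry()) {
  v <- schedule_frame_speeds(schedule)
  sum(v != 0) / geometry$refresh_rate
}

#' Frame-by-frame retinal trace of a schedule
#'
#' Simulates the interval frame by frame. The distance at frame k is the
#' start distance minus the displacements of all preceding frames (each
#' frame advances the object by `world_speed / refresh_rate`); the angular
#' separation and expansion rate are evaluated at that distance with that
#' frame's world speed. Under constant positive world speed the expansion
#' rate therefore increases frame to frame (retinal acceleration), and it is
#' zero wherever the world speed is zero.
#'
#' @param schedule An [interval_schedule()].
#' @param geometry A [looming_geometry()].
#' @return A data frame of class `"retinal_trace"` with columns `time_s`,
#'   `world_speed_cm_s`, `distance_cm`, `separation_arcmin`,
#'   `expansion_arcmin_per_s`.
#' @export
simulate_trace <- function(schedule, geometry = looming_geometry()) {
  v <- schedule_frame_speeds(schedule)
  if (length(v) == 0L) stop("schedule has no frames", call. = FALSE)
  rate <- geometry$refresh_rate
  disp <- v / rate
  d <- schedule$start_distance - c(0, cumsum(disp)[-length(disp)])
  final <- schedule$start_distance - sum(disp)
  if (final <= geometry$object_separation / 2 ||
      any(d <= geometry$object_separation / 2)) {
    stop("schedule drives the stimulus past the eye (distance <= S/2)",
         call. = FALSE)
  }
  out <- data.frame(
    time_s = (seq_along(v) - 1L) / rate,
    world_speed_cm_s = v,
    distance_cm = d,
    separation_arcmin = angular_separation(d, geometry),
    expansion_arcmin_per_s = expansion_rate(d, v, geometry)
  )
  class(out) <- c("retinal_trace", "data.frame")
  out
}

#' Write a retinal trace to CSV
#' @param trace A `"retinal_trace"` data frame.
#' @param path Output file path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "retinal_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

# ---- condition builders -----------------------------------------------------

# Design constants shared by the three conditions (all at 85 Hz):
#   speed change : start 117 cm, 250 ms hold, 1 s motion, step change after
#                  500 ms of motion (42.5 frames -> 43, tie away from zero),
#                  standard 40 cm/s, levels (40,40) ... (10,70)
#   duration     : start 97 cm, fixed simulated distance 28.7 cm, level
#                  duration = quantize(28.7 / v), speeds 40..70 by 5
#   distance     : start 97 cm, fixed nominal duration 0.506 s (43 frames),
#                  distance = v * realized duration
#   catch        : 40 cm/s for a nominal 1.070 s (91 frames, 42.8 cm)
SPEED_CHANGE_LEVELS <- cbind(slow = seq(40, 10, by = -5),
                             fast = seq(40, 70, by = 5))
SPEED_DISCRIM_LEVELS <- seq(40, 70, by = 5)
STANDARD_SPEED <- 40
HOLD_DURATION_S <- 0.25
DURATION_CONDITION_DISTANCE <- 28.7
DISTANCE_CONDITION_DURATION <- 0.506
CATCH_DURATION_S <- 1.070

hold_segment <- function(geometry) {
  motion_segment(0, quantize_to_frames(HOLD_DURATION_S, geometry$refresh_rate)$n_frames)
}

#' Build one of the three experimental conditions
#'
#' Constructs the full schedule set for a condition of the 2IFC design:
#' \describe{
#'   \item{`speed_change`}{Standard: 1 s at 40 cm/s from 117 cm. Test levels:
#'     the first 500 ms of motion at `40 - k*5` cm/s and the remainder at
#'     `40 + k*5` cm/s (k = 0..6), so total distance and duration match the
#'     standard. No catch trials.}
#'   \item{`duration`}{Speed discrimination with duration available: every
#'     level covers the same simulated 28.7 cm, so faster levels are shorter.
#'     Speeds 40..70 cm/s; standard 40 cm/s (0.718 s realized).}
#'   \item{`distance`}{Speed discrimination with distance available: every
#'     level lasts the same 43 frames (0.506 s), so faster levels travel
#'     further. Speeds 40..70 cm/s.}
#' }
#' Both speed-discrimination conditions carry a catch interval: 40 cm/s (the
#' standard speed) held for a nominal 1.070 s, covering 42.8 cm — longer and
#' further than the standard, but at the same speed.
#'
#' @param name `"speed_change"`, `"duration"` or `"distance"`.
#' @param geometry A [looming_geometry()].
#' @return An object of class `"condition_spec"` with elements `name`,
#'   `standard`, `test_levels` (list of 7 schedules), `catch` (or `NULL`),
#'   `trials_per_level` (30), `n_catch` (30 or 0).
#' @export
build_condition <- function(name = c("speed_change", "duration", "distance"),
                            geometry = looming_geometry()) {
  name <- match.arg(name)
  rate <- geometry$refresh_rate
  hold <- hold_segment(geometry)
  q <- function(dur) quantize_to_frames(dur, rate)$n_frames

  if (name == "speed_change") {
    start <- geometry$fixation_distance + 20
    n_motion <- q(1.0)
    n_pre <- q(0.5)            # 42.5 -> 43 frames before the step change
    n_post <- n_motion - n_pre
    standard <- interval_schedule(
      start, list(hold, motion_segment(STANDARD_SPEED, n_motion)), "standard")
    test_levels <- lapply(seq_len(nrow(SPEED_CHANGE_LEVELS)), function(i) {
      interval_schedule(
        start,
        list(hold,
             motion_segment(SPEED_CHANGE_LEVELS[i, "slow"], n_pre),
             motion_segment(SPEED_CHANGE_LEVELS[i, "fast"], n_post)),
        "test")
    })
    catch <- NULL
    n_catch <- 0L
  } else {
    start <- geometry$fixation_distance
    if (name == "duration") {
      standard_frames <- q(DURATION_CONDITION_DISTANCE / STANDARD_SPEED)
      test_levels <- lapply(SPEED_DISCRIM_LEVELS, function(v) {
        interval_schedule(
          start,
          list(hold, motion_segment(v, q(DURATION_CONDITION_DISTANCE / v))),
          "test")
      })
    } else {
      standard_frames <- q(DISTANCE_CONDITION_DURATION)
      test_levels <- lapply(SPEED_DISCRIM_LEVELS, function(v) {
        interval_schedule(
          start, list(hold, motion_segment(v, standard_frames)), "test")
      })
    }
    standard <- interval_schedule(
      start, list(hold, motion_segment(STANDARD_SPEED, standard_frames)),
      "standard")
    catch <- interval_schedule(
      start, list(hold, motion_segment(STANDARD_SPEED, q(CATCH_DURATION_S))),
      "catch")
    n_catch <- 30L
  }

  structure(
    list(name = name, standard = standard, test_levels = test_levels,
         catch = catch, trials_per_level = 30L, n_catch = n_catch,
         geometry = geometry),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("Condition:", x$name, "-", length(x$test_levels), "levels x",
      x$trials_per_level, "trials,", x$n_catch, "catch trials\n")
  invisible(x)
}

schedule_to_list <- function(s) {
  list(start_distance = s$start_distance, label = s$label,
       segments = lapply(s$segments, function(m)
         list(world_speed = m$world_speed, n_frames = m$n_frames)))
}

schedule_from_list <- function(l) {
  interval_schedule(
    l$start_distance,
    lapply(l$segments, function(m) motion_segment(m$world_speed, m$n_frames)),
    l$label)
}

#' Serialize a condition to / from JSON
#'
#' Round-trips the condition's schedules (names, speeds in cm/s, frame
#' counts, start distances in cm) through a JSON config.
#'
#' @param condition A `"condition_spec"`.
#' @param path File path.
#' @return `condition_from_json()` returns a rebuilt `"condition_spec"`.
#' @export
condition_to_json <- function(condition, path) {
  stopifnot(inherits(condition, "condition_spec"))
  obj <- list(
    name = condition$name,
    trials_per_level = condition$trials_per_level,
    n_catch = condition$n_catch,
    geometry = unclass(condition$geometry),
    standard = schedule_to_list(condition$standard),
    test_levels = lapply(condition$test_levels, schedule_to_list),
    catch = if (!is.null(condition$catch)) schedule_to_list(condition$catch)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname condition_to_json
#' @export
condition_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- looming_geometry(obj$geometry$object_separation,
                           obj$geometry$fixation_distance,
                           obj$geometry$refresh_rate)
  structure(
    list(name = obj$name,
         standard = schedule_from_list(obj$standard),
         test_levels = lapply(obj$test_levels, schedule_from_list),
         catch = if (!is.null(obj$catch)) schedule_from_list(obj$catch),
         trials_per_level = as.integer(obj$trials_per_level),
         n_catch = as.integer(obj$n_catch),
         geometry = geom),
    class = "condition_spec"
  )
}
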