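# Cumulative-normal psychometric fitting and 75% thresholds.

#' Stimulus axis for psychometric analysis
#'
#' Maps the 7 levels of a condition onto the analysis axis (cm/s) under the
#' two parameterizations of speed-change performance:
#' \describe{
#'   \item{mode I}{the speed change within the test interval
#'     (e.g. the 10-to-70 level maps to 60 cm/s); defined only for the
#'     speed-change condition.}
#'   \item{mode II}{the difference between the test and standard interval
#'     speeds at matched points: end speed minus the 40 cm/s standard for
#'     the speed-change condition (10-to-70 maps to 30), test speed minus
#'     standard speed for the speed-discrimination conditions.}
#' }
#' Mode I values are exactly twice mode II values for every speed-change
#' level, so thresholds fitted on the two axes differ by exactly a factor
#' of 2 on the same response data.
#'
#' @param condition A [build_condition()] result.
#' @param analysis_mode `"I"` or `"II"`.
#' @return Numeric vector of 7 axis values in cm/s.
#' @export
level_axis <- function(condition, analysis_mode = c("II", "I")) {
  analysis_mode <- match.arg(analysis_mode)
  stopifnot(inherits(condition, "condition_spec"))
  axis <- level_axis_values(condition)
  if (analysis_mode == "I") {
    if (condition$name != "speed_change") {
      stop("analysis mode I (within-interval change) is undefined for the ",
           condition$name, " condition", call. = FALSE)
    }
    axis$x_I
  } else {
    axis$x_II
  }
}

#' Aggregate trial records to per-level counts
#'
#' Collapses main (non-catch) trials to one row per level on the requested
#' analysis axis: `x`, `n_correct`, `n_total`.
#'
#' @param trials Trial records from [simulate_experiment()] or
#'   [read_trials()] (one participant, one condition).
#' @param analysis_mode `"I"` or `"II"`.
#' @return A data frame with columns `x`, `n_correct`, `n_total`.
#' @export
aggregate_levels <- function(trials, analysis_mode = c("II", "I")) {
  analysis_mode <- match.arg(analysis_mode)
  main <- trials[!trials$is_catch, , drop = FALSE]
  xcol <- if (analysis_mode == "I") "x_mode_I" else "x_mode_II"
  if (all(is.na(main[[xcol]]))) {
    stop("axis values for analysis mode ", analysis_mode,
         " are not defined for these trials", call. = FALSE)
  }
  xs <- sort(unique(main[[xcol]]))
  out <- data.frame(
    x = xs,
    n_correct = vapply(xs, function(v)
      sum(main$outcome[main[[xcol]] == v]), numeric(1)),
    n_total = vapply(xs, function(v)
      sum(main[[xcol]] == v), numeric(1))
  )
  out
}

#' Fit a cumulative-normal psychometric function by maximum likelihood
#'
#' Fits `p(x) = guess + (1 - guess - lapse) * pnorm((x - mu) / sigma)` to
#' binomial per-level counts by maximizing the binomial log-likelihood.
#' The guess rate is fixed at 0.5 (2IFC). The lapse rate is fixed at 0 by
#' default; `lapse_policy = "grid"` refits over a fixed-lapse grid
#' (0 to 0.06 by 0.01) and keeps the best likelihood. Optimization is
#' bounded quasi-Newton (L-BFGS-B) on an internally rescaled axis with 8
#' restarts from coarse-grid seeds, so fits are equivariant under rescaling
#' of `x`: doubling all `x` exactly doubles `mu` and `sigma`.
#'
#' Degenerate data (performance at ceiling everywhere or never above
#' chance, or a slope collapsing to the lower bound) are flagged
#' `converged = FALSE` with a diagnostic and should be excluded from group
#' summaries.
#'
#' @param data Data frame with columns `x`, `n_correct`, `n_total`
#'   (at least 3 distinct levels).
#' @param guess_rate Lower asymptote; 0.5 for 2IFC.
#' @param lapse_policy `"fixed"` (lapse = `lapse`) or `"grid"`.
#' @param lapse Fixed lapse rate in \[0, 0.06\] used when
#'   `lapse_policy = "fixed"`.
#' @return An object of class `"psychometric_fit"`: `mu`, `sigma`,
#'   `guess_rate`, `lapse_rate`, `log_likelihood`, `converged`, `flags`,
#'   `data`.
#' @export
fit_psychometric <- function(data, guess_rate = 0.5,
                             lapse_policy = c("fixed", "grid"),
                             lapse = 0) {
  lapse_policy <- match.arg(lapse_policy)
  stopifnot(is.data.frame(data),
            all(c("x", "n_correct", "n_total") %in% names(data)))
  data <- data[data$n_total > 0, , drop = FALSE]
  if (length(unique(data$x)) < 3L) {
    stop("need at least 3 distinct levels with trials", call. = FALSE)
  }
  if (any(data$n_correct < 0 | data$n_correct > data$n_total)) {
    stop("invalid counts: need 0 <= n_correct <= n_total", call. = FALSE)
  }
  if (anyDuplicated(data$x)) stop("x values must be distinct", call. = FALSE)

  lapse_grid <- if (lapse_policy == "grid") seq(0, 0.06, by = 0.01) else lapse
  fits <- lapply(lapse_grid, function(lam)
    fit_psychometric_fixed(data, guess_rate, lam))
  best <- fits[[which.max(vapply(fits, function(f) f$log_likelihood,
                                 numeric(1)))]]
  best
}

# Core fixed-lapse MLE on a unit-rescaled axis.
fit_psychometric_fixed <- function(data, guess_rate, lapse) {
  sx <- max(abs(data$x))
  if (sx == 0) sx <- 1
  xs <- data$x / sx
  k <- data$n_correct
  n <- data$n_total
  span <- 1 - guess_rate - lapse

  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- guess_rate + span * stats::pnorm((xs - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }

  rng <- range(xs)
  width <- max(diff(rng), 0.1)
  starts <- expand.grid(
    mu = seq(rng[1], rng[2] + 0.5 * width, length.out = 4),
    log_sigma = log(width * c(0.1, 0.5))
  )
  lower <- c(rng[1] - 2 * width, log(width * 1e-4))
  upper <- c(rng[2] + 2 * width, log(width * 10))

  runs <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e6, maxit = 500)),  # ~1e-8 on logLik
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stop("psychometric optimization failed", call. = FALSE)
  values <- vapply(runs, function(r) r$value, numeric(1))
  best <- runs[[which.min(values)]]
  # a restart that stopped on a line-search hiccup still counts as converged
  # when a cleanly terminated restart reaches the same optimum
  clean <- vapply(runs, function(r) r$convergence == 0, logical(1))
  opt_converged <- any(clean & values <= min(values) + 1e-6)
  if (opt_converged && best$convergence != 0) {
    best <- runs[clean & values <= min(values) + 1e-6][[1L]]
  }

  mu <- best$par[1] * sx
  sigma <- exp(best$par[2]) * sx

  flags <- character(0)
  prop <- k / n
  if (all(prop >= 1 - lapse - 0.02)) flags <- c(flags, "all_ceiling")
  if (all(prop <= guess_rate + 2 * sqrt(guess_rate * (1 - guess_rate) / n))) {
    flags <- c(flags, "all_chance")
  }
  # perfect-step data leave the slope unidentified: the optimizer may stop
  # anywhere on a likelihood ridge where every level sits at an asymptote
  p_hat <- guess_rate + span * stats::pnorm((xs - best$par[1]) / exp(best$par[2]))
  if (best$par[2] <= lower[2] + 1e-6 ||
      all(p_hat < guess_rate + 1e-4 | p_hat > guess_rate + span - 1e-4)) {
    flags <- c(flags, "sigma_at_bound")
  }
  if (best$par[1] >= upper[1] - 1e-6 || best$par[1] <= lower[1] + 1e-6) {
    flags <- c(flags, "mu_at_bound")
  }

  structure(
    list(mu = mu, sigma = sigma, guess_rate = guess_rate, lapse_rate = lapse,
         log_likelihood = -best$value,
         converged = opt_converged && length(flags) == 0L,
         flags = flags, data = data),
    class = "psychometric_fit"
  )
}

#' Predicted proportion correct from a psychometric fit
#' @param object A `"psychometric_fit"`.
#' @param x Stimulus values (cm/s).
#' @param ... Unused.
#' @return Predicted probabilities.
#' @export
predict.psychometric_fit <- function(object, x, ...) {
  object$guess_rate + (1 - object$guess_rate - object$lapse_rate) *
    stats::pnorm((x - object$mu) / object$sigma)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit: mu = %.3f, sigma = %.3f, lapse = %.3f, logLik = %.2f%s\n",
    x$mu, x$sigma, x$lapse_rate, x$log_likelihood,
    if (x$converged) "" else paste0("  [NOT CONVERGED: ",
                                    paste(x$flags, collapse = ", "), "]")))
  invisible(x)
}

#' Threshold at a target proportion correct
#'
#' Inverts the fitted function at `p_target`:
#' `mu + sigma * qnorm((p_target - guess) / (1 - guess - lapse))`.
#' With guess 0.5 and lapse 0 the 75% threshold equals `mu` exactly.
#'
#' @param fit A converged `"psychometric_fit"`.
#' @param p_target Target proportion correct, strictly between the guess
#'   rate and `1 - lapse_rate`.
#' @return Threshold on the fitted stimulus axis (cm/s).
#' @export
threshold <- function(fit, p_target = 0.75) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) {
    stop("threshold is undefined for a non-converged fit (",
         paste(fit$flags, collapse = ", "), ")", call. = FALSE)
  }
  span <- 1 - fit$guess_rate - fit$lapse_rate
  q <- (p_target - fit$guess_rate) / span
  if (q <= 0 || q >= 1) {
    stop("p_target ", p_target, " is outside the attainable range (",
         fit$guess_rate, ", ", 1 - fit$lapse_rate, ")", call. = FALSE)
  }
  fit$mu + fit$sigma * stats::qnorm(q)
}

#' Parametric-bootstrap standard error of the threshold
#'
#' Resamples binomial counts from the fitted function, refits, and returns
#' the standard deviation of the resampled thresholds.
#'
#' @param fit A converged `"psychometric_fit"`.
#' @param n_boot Number of bootstrap resamples.
#' @param p_target Target proportion correct.
#' @param seed Integer seed.
#' @return List with `se` and the vector of resampled `thresholds`
#'   (non-converged resamples dropped).
#' @export
bootstrap_threshold_se <- function(fit, n_boot = 400, p_target = 0.75,
                                   seed = NULL) {
  stopifnot(inherits(fit, "psychometric_fit"), fit$converged)
  with_seed(seed, {
    p <- predict(fit, fit$data$x)
    ths <- vapply(seq_len(n_boot), function(b) {
      d <- fit$data
      d$n_correct <- stats::rbinom(nrow(d), d$n_total, p)
      f <- tryCatch(
        fit_psychometric_fixed(d, fit$guess_rate, fit$lapse_rate),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) NA_real_ else threshold(f, p_target)
    }, numeric(1))
    ths <- ths[is.finite(ths)]
    list(se = stats::sd(ths), thresholds = ths)
  })
}
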