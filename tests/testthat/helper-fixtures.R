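# Shared fixtures: conditions are deterministic, build once per test run.

geom <- looming_geometry()
cond_speed_change <- build_condition("speed_change", geom)
cond_duration <- build_condition("duration", geom)
cond_distance <- build_condition("distance", geom)
all_conditions <- list(speed_change = cond_speed_change,
                       duration = cond_duration,
                       distance = cond_distance)

# A small two-participant cohort used by pipeline tests.
tiny_cohort <- function(master_seed = 11) {
  cohort_config(n_speed_change = 3, n_speed_discrimination = 3,
                master_seed = master_seed)
}

# Binomial responses from a known psychometric function.
simulate_level_data <- function(mu, sigma, x, n_per_level, lapse = 0,
                                guess = 0.5) {
  p <- guess + (1 - guess - lapse) * pnorm((x - mu) / sigma)
  data.frame(x = x, n_correct = rbinom(length(x), n_per_level, p),
             n_total = n_per_level)
}
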