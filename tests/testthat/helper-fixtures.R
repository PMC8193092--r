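# Shared fixtures: all synthetic, built in code at test time.

noiseless_series <- function(params, weeks = 1:18) {
  data.frame(week = weeks, value = logistic_value(params, weeks))
}

random_params <- function(n) {
  # realistic ranges for weekly harvest trajectories
  tibble::tibble(
    nu_max = stats::runif(n, 0.5, 500),
    r = stats::runif(n, 0.3, 2.5),
    t_max = stats::runif(n, 4, 14)
  )
}

small_design <- function(weeks = 1:18, reps = 3) {
  experiment_design(harvest_weeks = weeks, replicates = reps)
}

# lupin-in-mixture biomass truth used across recovery tests
lupin_mix_biomass <- function() logistic_params(15.26, 1.15, 9.71)
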