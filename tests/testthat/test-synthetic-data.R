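test_that("noiseless trajectories lie exactly on the logistic curve", {
  p <- logistic_params(10, 1, 5)
  tr <- generate_trajectory(p, 1:18, noise_spec(cv_or_sd = 0), n_rep = 3)
  expect_equal(nrow(tr), 54)
  at5 <- tr$value[tr$week == 5]
  expect_equal(at5, rep(5, 3))                      # half saturation
  expect_equal(tr$value, logistic_value(p, tr$week))
  far <- generate_trajectory(p, 20, noise_spec(cv_or_sd = 0), n_rep = 2)
  expect_equal(far$value, rep(10, 2), tolerance = 1e-6)  # asymptote
})

test_that("noisy replicate means track the curve and seeds reproduce", {
  p <- lupin_mix_biomass()
  ns <- noise_spec(cv_or_sd = 0.10, seed = 99)
  tr1 <- generate_trajectory(p, 1:18, ns, n_rep = 3)
  tr2 <- generate_trajectory(p, 1:18, ns, n_rep = 3)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$value >= 0))
  # Monte-Carlo check against the noiseless half-saturation value 7.63:
  # average over many replicates at the week nearest t_max
  trM <- generate_trajectory(p, rep(9.71, 1), noise_spec(cv_or_sd = 0.10,
                                                         seed = 7),
                             n_rep = 300)
  expect_equal(mean(trM$value), 15.26 / 2, tolerance = 0.1 * 15.26 / 2)
})

test_that("increasing the CV increases replicate scatter", {
  p <- logistic_params(10, 1, 5)
  sds <- vapply(c(0.05, 0.15, 0.40), function(cv) {
    v <- vapply(1:30, function(s) {
      tr <- generate_trajectory(p, 10, noise_spec(cv_or_sd = cv, seed = s),
                                n_rep = 10)
      stats::sd(tr$value)
    }, numeric(1))
    mean(v)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("unknown noise models are rejected up front", {
  expect_error(noise_spec("banana"), "unknown noise model")
  expect_error(noise_spec("additive-gaussian", cv_or_sd = -1))
})

test_that("additive-gaussian noise is truncated at zero", {
  p <- logistic_params(0.5, 1, 10)   # tiny values, large sd
  tr <- generate_trajectory(p, 1:18, noise_spec("additive-gaussian", 2, 3),
                            n_rep = 5)
  expect_true(all(tr$value >= 0))
})

test_that("full-design generation matches the design arithmetic", {
  d <- generate_experiment(noise = noise_spec(cv_or_sd = 0.1, seed = 5))
  # (3 mono + 3 single + 2x2 mixture combos) x 18 weeks x 3 replicates
  expect_equal(nrow(d), 10 * 18 * 3)
  expect_equal(sort(unique(d$species)), c("camelina", "lupin", "oat"))
  expect_true(all(d$biomass_g >= 0) && all(d$n_mg >= 0) && all(d$p_mg >= 0))
  # yields only in the final two weeks
  expect_true(all(is.na(d$plot_yield_g[!d$week %in% 17:18])))
  expect_true(all(!is.na(d$plot_yield_g[d$week %in% 17:18])))
})

test_that("the same seed gives a byte-identical CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_harvest(generate_experiment(noise = noise_spec(cv_or_sd = 0.1,
                                                       seed = 21)), f1)
  write_harvest(generate_experiment(noise = noise_spec(cv_or_sd = 0.1,
                                                       seed = 21)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("missing truth entries are reported by key", {
  design <- small_design()
  truth <- default_truth(design)
  truth$params <- truth$params[!(truth$params$species == "lupin" &
                                   truth$params$response == "p" &
                                   truth$params$context == "monoculture"), ]
  expect_error(generate_experiment(design, truth),
               "missing truth.*lupin/monoculture.*p")
})

test_that("isotope generation inverts the dilution formula exactly", {
  beta <- tibble::tibble(week = 5:8, beta_permil = -0.5)
  ref <- tibble::tibble(week = 5:8, delta15n_permil = 3.0)
  iso0 <- generate_isotope_data(0, beta, ref, noise_spec(cv_or_sd = 0))
  expect_equal(iso0$delta15n_permil[iso0$role == "legume"],
               rep(3.0, 12))                       # no fixation: ref value
  iso100 <- generate_isotope_data(100, beta, ref, noise_spec(cv_or_sd = 0))
  expect_equal(iso100$delta15n_permil[iso100$role == "legume"],
               rep(-0.5, 12))                      # full fixation: beta
  iso <- generate_isotope_data(83.06, beta, ref, noise_spec(cv_or_sd = 0))
  expect_equal(unique(iso$delta15n_permil[iso$role == "legume"]), 0.0929)
})

test_that("isotope generation demands a beta for every requested week", {
  beta <- tibble::tibble(week = 5:6, beta_permil = -0.5)
  ref <- tibble::tibble(week = 5:9, delta15n_permil = 3.0)
  expect_error(
    generate_isotope_data(tibble::tibble(week = 5:9, ndfa_true = 70),
                          beta, ref),
    "beta.*7, 8, 9")
})

test_that("design invariants are enforced", {
  expect_error(experiment_design(harvest_weeks = c(3, 2, 1)))
  expect_error(experiment_design(replicates = 0))
  expect_error(experiment_design(mixtures = list(c("oat", "oat"))),
               "two distinct species")
  expect_error(experiment_design(mixtures = list(c("oat", "wheat"))),
               "two distinct species")
})

test_that("truth sets serialise to YAML and validate their ranges", {
  truth <- default_truth()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(truth, f)
  back <- yaml::read_yaml(f)
  expect_equal(back$legume, "lupin")
  expect_equal(length(back$params), nrow(truth$params))
  bad <- truth$ndfa_true
  bad$ndfa_true[1] <- 130
  expect_error(truth_set(truth$params, bad))
})
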