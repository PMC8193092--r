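test_that("starting-value heuristic lands near the truth on clean data", {
  s <- noiseless_series(logistic_params(10, 1, 5))
  iv <- initial_values(s)
  expect_equal(iv$nu_max, 10.5, tolerance = 1e-4)   # 1.05 x observed max
  expect_equal(iv$t_max, 5)                         # first week >= half max
  expect_gt(iv$r, 0.5)
  expect_lt(iv$r, 2)
})

test_that("degenerate series are rejected with informative errors", {
  expect_error(initial_values(data.frame(week = 1:6, value = rep(2, 6))),
               "constant")
  expect_error(initial_values(data.frame(week = 1, value = 3)),
               "at least 5")
  expect_error(initial_values(data.frame(week = 1:5, value = rep(0, 5))),
               "no positive values")
  expect_error(fit_logistic(data.frame(week = c(1, 1, 2, 2, 3),
                                       value = c(1, 1, 2, 2, 3))[1:4, ]),
               "at least 5")
})

test_that("noiseless trajectories are recovered to numerical precision", {
  truths <- list(lupin_mix_biomass(),
                 logistic_params(24.9, 0.58, 8.95),
                 logistic_params(2.25, 1.37, 9.48))
  for (p in truths) {
    fit <- fit_logistic(noiseless_series(p))
    expect_true(fit$converged)
    expect_equal(fit$params$nu_max, p$nu_max, tolerance = 1e-6)
    expect_equal(fit$params$r, p$r, tolerance = 1e-6)
    expect_equal(fit$params$t_max, p$t_max, tolerance = 1e-6)
    expect_lt(fit$residual_sse, 1e-10)
  }
})

test_that("fits from noisy replicates are unbiased enough to use", {
  p <- lupin_mix_biomass()
  rel_err <- vapply(1:40, function(s) {
    tr <- generate_trajectory(p, 1:18, noise_spec(cv_or_sd = 0.10, seed = s),
                              n_rep = 1)
    fit <- fit_logistic(tr)
    abs(fit$params$nu_max / p$nu_max - 1)
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("truncation before the plateau is flagged, not silently trusted", {
  p <- lupin_mix_biomass()
  s <- noiseless_series(p, weeks = 1:4)             # all pre-inflection
  s$value <- s$value * c(1.02, 0.98, 1.01, 0.99)    # break exact identifiability
  fit <- tryCatch(fit_logistic(s), error = function(e) NULL)
  if (!is.null(fit)) {
    unreliable <- !fit$converged ||
      !is.finite(fit$std_errors[["nu_max"]]) ||
      fit$std_errors[["nu_max"]] > fit$params$nu_max
    expect_true(unreliable)
  } else {
    succeed("truncated series rejected outright")
  }
})

test_that("two-stage fit matches a grid-refinement oracle on clean data", {
  set.seed(31)
  ps <- random_params(8)
  for (i in seq_len(nrow(ps))) {
    p <- logistic_params(ps$nu_max[i], ps$r[i], ps$t_max[i])
    s <- noiseless_series(p)
    # compare SSEs at unit scale: SSE carries units of value^2, so the
    # agreement threshold is only meaningful after normalisation
    s$value <- s$value / max(s$value)
    fit <- fit_logistic(s)
    # oracle: coarse 3-D grid around plausible ranges, then optim polish
    sse <- function(par) {
      pred <- par[1] / (1 + exp(pmin(pmax(par[2] * (par[3] - s$week), -700),
                                     700)))
      sum((s$value - pred)^2)
    }
    grid <- expand.grid(nu = max(s$value) * c(0.9, 1.0, 1.1, 1.3),
                        r = seq(0.2, 3, by = 0.2),
                        tm = seq(2, 16, by = 0.5))
    gsse <- apply(grid, 1, sse)
    best <- as.numeric(grid[which.min(gsse), ])
    pol <- stats::optim(best, sse, method = "L-BFGS-B",
                        lower = c(1e-6, 1e-6, 0),
                        upper = c(Inf, Inf, 36),
                        control = list(factr = 1, pgtol = 1e-14,
                                       maxit = 2000))
    # a second local polish from the first optimum guards against an
    # early L-BFGS-B stall on the flat valley floor
    pol <- stats::optim(pol$par, sse, method = "L-BFGS-B",
                        lower = c(1e-6, 1e-6, 0),
                        upper = c(Inf, Inf, 36),
                        control = list(factr = 1, pgtol = 1e-14,
                                       maxit = 2000))
    expect_lt(abs(fit$residual_sse - pol$value), 1e-8)
  }
})

test_that("more harvests do not hurt parameter recovery", {
  p <- lupin_mix_biomass()
  rmse_at <- function(weeks) {
    errs <- vapply(1:30, function(s) {
      tr <- generate_trajectory(p, weeks, noise_spec(cv_or_sd = 0.10,
                                                     seed = s), n_rep = 1)
      fit <- fit_logistic(tr)
      (fit$params$nu_max / p$nu_max - 1)^2
    }, numeric(1))
    sqrt(mean(errs))
  }
  expect_lte(rmse_at(1:18), rmse_at(seq(2, 18, by = 2)) * 1.05)
})

test_that("fit_all covers the full design deterministically", {
  d <- generate_experiment(noise = noise_spec(cv_or_sd = 0.05, seed = 8))
  fits <- suppressWarnings(fit_all(d))
  expect_equal(nrow(fits), 10 * 3 * 3)              # combos x responses x reps
  fits2 <- suppressWarnings(fit_all(d))
  expect_equal(as.data.frame(fits), as.data.frame(fits2))
  expect_true(all(c("nu_max", "r", "t_max", "converged") %in% names(fits)))

  pooled <- suppressWarnings(fit_all(d, pooled = TRUE))
  expect_equal(nrow(pooled), 10 * 3)
})

test_that("summaries aggregate converged replicate fits as mean and sd/sqrt(n)", {
  d <- generate_experiment(noise = noise_spec(cv_or_sd = 0.05, seed = 12))
  fits <- suppressWarnings(fit_all(d))
  sm <- summarize_fits(fits)
  expect_equal(nrow(sm), 10 * 3)
  one <- fits[fits$species == "lupin" & fits$context == "mixture" &
                fits$response == "biomass" & fits$converged, ]
  row <- sm[sm$species == "lupin" & sm$context == "mixture" &
              sm$response == "biomass", ]
  expect_equal(row$nu_max, mean(one$nu_max))
  expect_equal(row$nu_max_se, stats::sd(one$nu_max) / sqrt(nrow(one)))
  expect_equal(row$n_replicates, nrow(one))
})

test_that("noiseless full-design recovery reproduces the truth table", {
  design <- small_design()
  truth <- default_truth(design)
  d <- generate_experiment(design, truth, noise_spec(cv_or_sd = 0, seed = 1))
  fits <- suppressWarnings(fit_all(d))
  sm <- summarize_fits(fits)
  joined <- merge(sm, truth$params,
                  by = c("species", "context", "partner", "response"),
                  suffixes = c("_fit", "_true"))
  expect_equal(nrow(joined), 30)
  expect_equal(joined$nu_max_fit, joined$nu_max_true, tolerance = 1e-5)
  expect_equal(joined$t_max_fit, joined$t_max_true, tolerance = 1e-5)
})

test_that("keys with too few points are skipped with a warning", {
  d <- generate_experiment(noise = noise_spec(cv_or_sd = 0.05, seed = 3))
  # cripple one trajectory: keep only 3 weeks of camelina single biomass
  drop <- d$species == "camelina" & d$context == "single" & d$week > 3
  d$biomass_g[drop] <- NA_real_
  w <- capture_warnings(fits <- fit_all(d))
  expect_match(w, "skipping camelina/single/biomass", all = FALSE)
  expect_equal(nrow(fits), 90 - 3)
  expect_length(attr(fits, "skipped"), 3)
})
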