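test_that("LER is the sum of partial relative yields", {
  res <- compute_ler(c(oat = 5.1, lupin = 8.6), c(oat = 10, lupin = 10))
  expect_equal(res$partial$partial_ler[res$partial$species == "oat"], 0.51)
  expect_equal(res$partial$partial_ler[res$partial$species == "lupin"], 0.86)
  expect_equal(res$total, 1.37)
  expect_equal(res$total, sum(res$partial$partial_ler))

  # identical mixture and monoculture performance: every partial is 1
  same <- compute_ler(c(a = 3, b = 7), c(a = 3, b = 7))
  expect_equal(same$total, 2.0)
})

test_that("LER is invariant to rescaling all yields", {
  y <- c(oat = 120, camelina = 15)
  m <- c(oat = 125, camelina = 83)
  base <- compute_ler(y, m)
  for (c_ in c(0.01, 3, 1000)) {
    scaled <- compute_ler(y * c_, m * c_)
    expect_equal(scaled$total, base$total)
    expect_equal(scaled$partial$partial_ler, base$partial$partial_ler)
  }
})

test_that("replicate-level LER inputs yield mean and SE", {
  y <- tibble::tibble(species = rep(c("oat", "lupin"), each = 3),
                      replicate = rep(1:3, 2),
                      yield = c(50, 55, 60, 80, 85, 90))
  m <- tibble::tibble(species = rep(c("oat", "lupin"), each = 3),
                      replicate = rep(1:3, 2),
                      yield = c(100, 100, 100, 100, 100, 100))
  res <- compute_ler(y, m)
  expect_equal(res$total, 0.55 + 0.85)
  expect_false(is.na(res$total_se))
  expect_equal(res$n_replicates, 3)
})

test_that("LER rejects bad inputs", {
  expect_error(compute_ler(c(a = 1), c(b = 1)), "species mismatch")
  expect_error(compute_ler(c(a = 1), c(a = 0)), "strictly positive")
  expect_error(compute_ler(c(a = -1), c(a = 2)), "non-negative")
})

test_that("percent contrasts round half away from zero and invert consistently", {
  expect_identical(percent_contrast(15.26, 11.35), 34L)
  expect_identical(percent_contrast(61.26, 38.7), 58L)
  expect_identical(percent_contrast(5, 5), 0L)
  expect_identical(percent_contrast(1.115, 1), 12L)   # 11.5 -> 12, away from 0
  expect_error(percent_contrast(1, 0), "must be > 0")

  set.seed(41)
  for (i in 1:50) {
    a <- stats::runif(1, 0.1, 100)
    b <- stats::runif(1, 0.1, 100)
    p_ab <- percent_contrast(a, b)
    p_ba <- percent_contrast(b, a)
    # inverse up to the half-unit integer rounding of each percent, which
    # propagates multiplicatively with the ratio
    bound <- 0.005 * (a / b + b / a) + 1e-9
    expect_lt(abs((1 + p_ab / 100) * (1 + p_ba / 100) - 1), bound)
  }
})

test_that("peak-rate contrasts reproduce published mixture effects", {
  expect_identical(
    peak_rate_contrast(list(r = 1.15, nu_max = 15.26),
                       list(r = 0.92, nu_max = 11.35)), 68L)
  expect_identical(
    peak_rate_contrast(list(r = 2.04, nu_max = 17.45),
                       list(r = 0.94, nu_max = 15.15)), 150L)
  expect_identical(
    peak_rate_contrast(list(r = 1, nu_max = 10), list(r = 1, nu_max = 10)),
    0L)
})

test_that("temporal shifts are antisymmetric and labelled by significance", {
  oat <- list(t_max = 6.72, t_max_se = 0.48, n_replicates = 3)
  lupin <- list(t_max = 8.98, t_max_se = 0.46, n_replicates = 3)
  sh <- temporal_shift(oat, lupin)
  expect_equal(sh$delta_t_max, -2.26)
  expect_equal(sh$se, sqrt(0.48^2 + 0.46^2))
  expect_equal(sh$direction, "earlier")             # oat peaks ~2 weeks first

  rev <- temporal_shift(lupin, oat)
  expect_equal(rev$delta_t_max, 2.26)
  expect_equal(rev$se, sh$se)
  expect_equal(rev$direction, "later")

  same <- temporal_shift(oat, oat)
  expect_equal(same$delta_t_max, 0)
  expect_equal(same$direction, "none")
})

test_that("temporal_differentiation builds intra and inter tables", {
  sm <- field_estimates()
  sm$n_replicates <- 3
  n_sub <- sm[sm$response == "n", ]
  intra <- temporal_differentiation(n_sub, "intra")
  expect_true(all(intra$response == "n"))
  expect_equal(nrow(intra), 3 * choose(4, 2) / 3 + 2 * choose(3, 2))
  inter <- temporal_differentiation(n_sub, "inter")
  expect_equal(nrow(inter), 2)                      # one row per mixture
  row <- inter[grepl("lupin", inter$key_b), ]
  expect_equal(row$delta_t_max, 6.72 - 8.98)
})

test_that("exudation summaries use the t-based band", {
  d <- tibble::tibble(
    species = "oat", context = "monoculture", partner = NA_character_,
    block_id = 1:3, week = 5, individual_id = 1,
    biomass_g = 1, n_mg = 1, p_mg = 1,
    oa_umol = c(1, 2, 3), root_dw_g = 1
  )
  sm <- exudation_summary(d)
  expect_equal(sm$mean_oa_per_g, 2)
  expect_equal(sm$se, stats::sd(1:3) / sqrt(3), tolerance = 1e-6)
  expect_equal(sm$band_half_width, 0.5773503 * 4.302653, tolerance = 1e-4)

  # identical values: zero-width band
  d0 <- d
  d0$oa_umol <- 4
  expect_equal(exudation_summary(d0)$band_half_width, 0)

  # n = 1: mean reported, band undefined
  s1 <- exudation_summary(d[1, ])
  expect_equal(s1$mean_oa_per_g, 1)
  expect_true(is.na(s1$band_half_width))

  # zero root mass excluded with warning
  dz <- d
  dz$root_dw_g[2] <- 0
  expect_warning(sz <- exudation_summary(dz), "root dry weight")
  expect_equal(sz$n, 2)
})
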