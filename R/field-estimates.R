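# Reference estimates from a published field intercropping study of oat,
# lupin and camelina (Mediterranean raised-bed garden, 18 weekly destructive
# harvests, 3 replicates). Bundled so contrasts, worked examples and the
# synthetic generator's default truth have realistic magnitudes.

#' Published logistic parameter estimates for oat, lupin and camelina
#'
#' Mean +/- SE (n = 3 replicate fits) of the logistic parameters fitted to
#' cumulative aboveground biomass (g/individual), P uptake and N uptake
#' (mg/individual) trajectories of oat, lupin and camelina grown as isolated
#' single plants, in monoculture, or intercropped (oat-lupin and
#' oat-camelina mixtures), from a published field study. The camelina-single
#' nitrogen asymptote and rate did not converge in that study and are NA.
#'
#' @return A tibble with columns `species`, `context` (`single`,
#'   `monoculture`, `mixture`), `partner` (NA unless mixture), `response`
#'   (`biomass`, `p`, `n`), `nu_max`, `nu_max_se`, `r`, `r_se`, `t_max`,
#'   `t_max_se`. Units: `nu_max` in g/individual for biomass and
#'   mg/individual for N and P; `r` per week; `t_max` in weeks since
#'   emergence.
#' @examples
#' field_estimates()
#' @export
field_estimates <- function() {
  row <- function(species, context, partner, response, ...) {
    v <- c(...)
    tibble::tibble(
      species = species, context = context, partner = partner,
      response = response,
      nu_max = v[1], nu_max_se = v[2], r = v[3], r_se = v[4],
      t_max = v[5], t_max_se = v[6]
    )
  }
  dplyr::bind_rows(
    # biomass (g/individual)
    row("oat", "mixture", "lupin", "biomass", 1.62, 0.21, 0.37, 0.10, 10.48, 1.09),
    row("oat", "mixture", "camelina", "biomass", 2.45, 0.29, 0.40, 0.09, 11.59, 0.88),
    row("oat", "monoculture", NA, "biomass", 1.50, 0.12, 0.47, 0.11, 10.23, 0.63),
    row("oat", "single", NA, "biomass", 21.16, 4.77, 0.55, 0.25, 12.91, 1.26),
    row("lupin", "mixture", "oat", "biomass", 15.26, 1.09, 1.15, 0.49, 9.71, 0.43),
    row("lupin", "monoculture", NA, "biomass", 11.35, 0.65, 0.92, 0.27, 9.44, 0.38),
    row("lupin", "single", NA, "biomass", 126.8, 7.37, 2.18, 0.93, 11.68, 0.24),
    row("camelina", "mixture", "oat", "biomass", 0.52, 0.08, 1.97, 2.40, 10.60, 0.74),
    row("camelina", "monoculture", NA, "biomass", 0.73, 0.11, 0.68, 0.34, 11.02, 0.91),
    row("camelina", "single", NA, "biomass", 19.56, 3.18, 0.82, 0.55, 10.92, 0.99),
    # phosphorus (mg/individual)
    row("oat", "mixture", "lupin", "p", 5.36, 0.72, 1.13, 0.82, 7.85, 0.74),
    row("oat", "mixture", "camelina", "p", 7.15, 0.49, 1.18, 0.43, 8.31, 0.36),
    row("oat", "monoculture", NA, "p", 7.23, 0.92, 1.30, 0.88, 8.56, 0.61),
    row("oat", "single", NA, "p", 38.91, 9.89, 0.68, 0.47, 9.82, 1.34),
    row("lupin", "mixture", "oat", "p", 61.26, 5.44, 1.29, 0.60, 9.61, 0.41),
    row("lupin", "monoculture", NA, "p", 38.70, 3.37, 1.11, 0.46, 8.95, 0.43),
    row("lupin", "single", NA, "p", 33.56, 2.49, 2.49, 1.37, 11.07, 0.20),
    row("camelina", "mixture", "oat", "p", 2.25, 0.55, 1.37, 1.70, 9.48, 1.04),
    row("camelina", "monoculture", NA, "p", 2.33, 0.39, 1.76, 1.83, 9.32, 0.69),
    row("camelina", "single", NA, "p", 36.02, 8.58, 3.89, 18.22, 8.76, 1.21),
    # nitrogen (mg/individual)
    row("oat", "mixture", "lupin", "n", 17.45, 1.65, 2.04, 1.72, 6.72, 0.48),
    row("oat", "mixture", "camelina", "n", 24.90, 2.59, 0.58, 0.18, 8.95, 0.70),
    row("oat", "monoculture", NA, "n", 15.15, 1.01, 0.94, 0.33, 7.68, 0.43),
    row("oat", "single", NA, "n", 282.0, 56.41, 0.61, 0.26, 11.01, 1.05),
    row("lupin", "mixture", "oat", "n", 516.4, 46.22, 1.36, 0.73, 8.98, 0.46),
    row("lupin", "monoculture", NA, "n", 367.6, 26.07, 1.13, 0.45, 8.42, 0.41),
    row("lupin", "single", NA, "n", 5072, 506.8, 2.12, 1.16, 11.37, 0.32),
    row("camelina", "mixture", "oat", "n", 16.42, 4.04, 1.38, 1.72, 10.02, 1.06),
    row("camelina", "monoculture", NA, "n", 14.61, 2.00, 0.91, 0.47, 9.91, 0.70),
    row("camelina", "single", NA, "n", NA, NA, NA, NA, 16.61, 12.12)
  )
}

#' Published partial Land Equivalent Ratios
#'
#' Partial LERs (mean +/- SE, plot-level grain yield of the final harvest
#' weeks) of each species in the oat-lupin and oat-camelina mixtures from
#' the same published field study. Summing partials within a mixture gives
#' the total LER (1.37 for oat-lupin, 1.14 for oat-camelina).
#'
#' @return A tibble with columns `mixture`, `species`, `partial_ler`,
#'   `partial_ler_se`.
#' @export
field_partial_ler <- function() {
  tibble::tribble(
    ~mixture,       ~species,   ~partial_ler, ~partial_ler_se,
    "oat-lupin",    "oat",      0.51,         0.01,
    "oat-lupin",    "lupin",    0.86,         0.23,
    "oat-camelina", "oat",      0.96,         0.33,
    "oat-camelina", "camelina", 0.18,         0.06
  )
}

#' Published weekly nitrogen fixation estimates for lupin
#'
#' Mean percentage of lupin nitrogen derived from the atmosphere
#' (%Ndfa +/- SE, n = 3) per harvest week at three diversity levels, from
#' the same published field study (weeks 5-16; fixation is not measurable
#' before nodulation).
#'
#' @return A tibble with columns `week`, `diversity` (`mixture`,
#'   `monoculture`, `single`), `ndfa`, `ndfa_se`.
#' @export
field_ndfa <- function() {
  wk <- 5:16
  mixture <- c(83.06, 76, 79.41, 78.98, 76.07, 76.51, 72.38, 67.18,
               74.10, 76.63, 72.68, 64.92)
  mixture_se <- c(3.36, 3, 5.52, 3.46, 1.13, 6.75, 3.56, 10.99,
                  7.10, 13.16, 6.57, 8.17)
  mono <- c(77.16, 69.33, 70.63, 72.67, 76.91, 74.13, 70.27, 54.03,
            66.87, 76.53, 71.21, 70.05)
  mono_se <- c(2.33, 3.96, 4.26, 6.93, 3.69, 6.39, 8.03, 6.62,
               16.63, 6.64, 8.41, 3.66)
  single <- c(44.90, 43.83, 76.63, 57.69, 57.39, 47.67, 48.60, 38.66,
              45.71, 36.91, 37.14, 28.14)
  single_se <- c(3.72, 14.43, 13.16, 1.39, 12.23, 12.79, 10.99, 7.99,
                 7.61, 12.45, 11.14, 5.11)
  dplyr::bind_rows(
    tibble::tibble(week = wk, diversity = "mixture", ndfa = mixture,
                   ndfa_se = mixture_se),
    tibble::tibble(week = wk, diversity = "monoculture", ndfa = mono,
                   ndfa_se = mono_se),
    tibble::tibble(week = wk, diversity = "single", ndfa = single,
                   ndfa_se = single_se)
  )
}
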