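# Natural-abundance 15N estimation of the share of legume nitrogen derived
# from atmospheric N2 fixation (isotope dilution), with reference-plant
# selection rules and week-specific beta calibration.

#' Percentage of legume N derived from the atmosphere
#'
#' The isotope-dilution estimate
#' \%Ndfa = 100 * (delta_ref - delta_legume) / (delta_ref - beta), where
#' delta_ref is the delta-15N of a non-fixing reference plant, delta_legume
#' the legume's delta-15N and beta the legume's signature when growing on
#' atmospheric N2 alone. Values outside 0..100 are returned unchanged
#' (clamping would hide calibration problems); use [ndfa_flag()] to label
#' them.
#'
#' @param delta_ref,delta_legume,beta delta-15N in permil; vectorised;
#'   `delta_ref` must differ from `beta`.
#' @return Numeric percent(s).
#' @examples
#' ndfa(delta_ref = 3.0, delta_legume = 0.0929, beta = -0.5) # 83.06
#' @export
ndfa <- function(delta_ref, delta_legume, beta) {
  stopifnot(is.numeric(delta_ref), is.numeric(delta_legume),
            is.numeric(beta))
  if (any(delta_ref == beta)) {
    stop("delta_ref equals beta: the isotope-dilution denominator is zero",
         call. = FALSE)
  }
  100 * (delta_ref - delta_legume) / (delta_ref - beta)
}

#' Flag out-of-range fixation estimates
#'
#' @param ndfa_percent Numeric vector of \%Ndfa values.
#' @return Logical vector: TRUE where the estimate falls outside 0..100.
#' @export
ndfa_flag <- function(ndfa_percent) {
  !is.na(ndfa_percent) & (ndfa_percent < 0 | ndfa_percent > 100)
}

#' Reference-plant delta-15N for one week and diversity level
#'
#' The reference is the mean delta-15N of oat records at the same week and
#' diversity level when any exist, otherwise of camelina records — the
#' conventional "cereal first, other non-legume second" rule. For the
#' mixture diversity level the oat growing with the non-legume partner
#' (i.e. not with the legume itself) is used when identifiable.
#'
#' @param dataset Harvest tibble with a `delta15n_permil` column.
#' @param week Harvest week.
#' @param diversity `"mixture"`, `"monoculture"` or `"single"`.
#' @param legume Fixing species to exclude (default `"lupin"`).
#' @param preferred Reference species in order of preference.
#' @return A list: `delta` (mean permil), `species` used, `n` records.
#' @export
select_reference <- function(dataset, week, diversity, legume = "lupin",
                             preferred = c("oat", "camelina")) {
  stopifnot("delta15n_permil" %in% names(dataset))
  cand <- dataset[dataset$week == week & dataset$context == diversity &
                    dataset$species != legume &
                    !is.na(dataset$delta15n_permil), , drop = FALSE]
  if (diversity == "mixture" && "partner" %in% names(cand)) {
    away <- cand[is.na(cand$partner) | cand$partner != legume, , drop = FALSE]
    if (nrow(away) > 0) cand <- away
  }
  for (sp in preferred) {
    hit <- cand[cand$species == sp, , drop = FALSE]
    if (nrow(hit) > 0) {
      return(list(delta = mean(hit$delta15n_permil), species = sp,
                  n = nrow(hit)))
    }
  }
  stop("no non-legume delta-15N records at week ", week, ", diversity '",
       diversity, "'", call. = FALSE)
}

#' Weekly nitrogen-fixation table per diversity level
#'
#' For every (week, diversity level) with legume delta-15N records, the
#' fixation percentage is computed per legume replicate against the
#' reference-plant mean of [select_reference()] and the week's beta value,
#' then summarised as mean +/- SE over replicates.
#'
#' @param dataset Harvest tibble with `delta15n_permil`.
#' @param beta_table Tibble (`week`, `beta_permil`); must cover every week
#'   with legume records.
#' @param legume Fixing species (default `"lupin"`).
#' @param alpha Unused here; reserved for display layers.
#' @return A tibble per (week, diversity): `ndfa` (mean \%), `ndfa_se`,
#'   `n`, `delta15n_ref`, `ref_species`, `delta15n_legume` (mean),
#'   `beta_permil`, `flagged` (any replicate outside 0..100).
#' @export
ndfa_timeseries <- function(dataset, beta_table, legume = "lupin",
                            alpha = 0.05) {
  stopifnot("delta15n_permil" %in% names(dataset),
            all(c("week", "beta_permil") %in% names(beta_table)))
  leg <- dataset[dataset$species == legume &
                   !is.na(dataset$delta15n_permil), , drop = FALSE]
  if (nrow(leg) == 0) {
    stop("no legume delta-15N records found for species '", legume, "'",
         call. = FALSE)
  }
  missing_beta <- setdiff(unique(leg$week), beta_table$week)
  if (length(missing_beta) > 0) {
    stop("no beta value for week(s) with legume data: ",
         paste(sort(missing_beta), collapse = ", "), call. = FALSE)
  }
  groups <- unique(leg[, c("week", "context")])
  groups <- groups[order(groups$week, groups$context), ]
  purrr::pmap_dfr(groups, function(week, context) {
    g <- leg[leg$week == week & leg$context == context, ]
    ref <- select_reference(dataset, week, context, legume = legume)
    beta <- beta_table$beta_permil[match(week, beta_table$week)]
    vals <- ndfa(ref$delta, g$delta15n_permil, beta)
    n <- length(vals)
    tibble::tibble(
      week = week, diversity = context,
      ndfa = mean(vals),
      ndfa_se = if (n >= 2) stats::sd(vals) / sqrt(n) else NA_real_,
      n = n,
      delta15n_ref = ref$delta, ref_species = ref$species,
      delta15n_legume = mean(g$delta15n_permil),
      beta_permil = beta,
      flagged = any(ndfa_flag(vals))
    )
  })
}
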