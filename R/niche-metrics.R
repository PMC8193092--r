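# Comparative statistics between community contexts: Land Equivalent Ratio
# decomposition, percent contrasts of accumulation maxima and peak rates,
# temporal differentiation of peak timing, and organic-acid exudation
# summaries.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Land Equivalent Ratio from mixture and monoculture yields
#'
#' The LER is the sum over species of partial relative yields Y_i / M_i,
#' where Y_i is the yield of species i in the mixture and M_i its yield in
#' monoculture; values above 1 indicate a yield advantage of the mixture.
#' Inputs are either named numeric vectors (one yield per species) or data
#' frames with columns `species`, `yield` and optionally `replicate`; with
#' replicate-level inputs, partial and total LERs are computed per
#' replicate and reported as mean +/- SE.
#'
#' @param mixture_yields Per-species yields in the mixture (g/plot).
#' @param monoculture_yields Per-species yields in monoculture (g/plot);
#'   same species set, strictly positive.
#' @return A list of class `ler_result`: `partial` (tibble with `species`,
#'   `partial_ler`, and `partial_ler_se` when replicated), `total`,
#'   `total_se` (NA unless replicated), `n_replicates`.
#' @examples
#' compute_ler(c(oat = 5.1, lupin = 8.6), c(oat = 10, lupin = 10))
#' @export
compute_ler <- function(mixture_yields, monoculture_yields) {
  ym <- as_yield_table(mixture_yields, "mixture_yields")
  mm <- as_yield_table(monoculture_yields, "monoculture_yields")
  if (!setequal(unique(ym$species), unique(mm$species))) {
    stop("species mismatch between mixture and monoculture yields",
         call. = FALSE)
  }
  if (any(mm$yield <= 0)) {
    stop("monoculture yields must be strictly positive", call. = FALSE)
  }
  if (any(ym$yield < 0)) {
    stop("mixture yields must be non-negative", call. = FALSE)
  }
  mono_mean <- stats::aggregate(yield ~ species, data = mm, FUN = mean)
  m_of <- stats::setNames(mono_mean$yield, mono_mean$species)
  ym$partial <- ym$yield / m_of[ym$species]

  per_rep <- stats::aggregate(partial ~ species + replicate, data = ym,
                              FUN = mean)
  n_rep <- length(unique(per_rep$replicate))
  se <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  partial <- per_rep |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(partial_ler = mean(.data$partial),
                     partial_ler_se = se(.data$partial), .groups = "drop")
  totals <- per_rep |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(total = sum(.data$partial), .groups = "drop")
  structure(list(
    partial = partial,
    total = sum(partial$partial_ler),
    total_se = se(totals$total),
    n_replicates = n_rep
  ), class = "ler_result")
}

as_yield_table <- function(x, what) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(tibble::tibble(species = names(x), replicate = 1L,
                          yield = unname(x)))
  }
  if (is.data.frame(x) && all(c("species", "yield") %in% names(x))) {
    out <- tibble::as_tibble(x)
    if (!"replicate" %in% names(out)) out$replicate <- 1L
    return(out[, c("species", "replicate", "yield")])
  }
  stop("`", what, "` must be a named numeric vector or a data frame ",
       "with columns species, yield (and optionally replicate)",
       call. = FALSE)
}

#' @export
print.ler_result <- function(x, ...) {
  cat(sprintf("<ler_result> total LER = %.2f%s over %d species\n",
              x$total,
              if (is.finite(x$total_se %||% NA_real_))
                sprintf(" +/- %.2f", x$total_se) else "",
              nrow(x$partial)))
  for (i in seq_len(nrow(x$partial))) {
    cat(sprintf("  %s: %.2f\n", x$partial$species[i],
                x$partial$partial_ler[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed percent contrast between two quantities
#'
#' Reports a / b as a signed percent difference, rounded to the nearest
#' integer (half away from zero): `round((a/b - 1) * 100)`. This is the
#' reporting convention for statements like "accumulated 34% more biomass".
#'
#' @param a,b Positive quantities (b strictly positive); vectorised.
#' @return Integer percent(s).
#' @examples
#' percent_contrast(15.26, 11.35) # +34
#' @export
percent_contrast <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(b <= 0)) stop("reference quantity `b` must be > 0", call. = FALSE)
  as.integer(round_half_away((a / b - 1) * 100))
}

#' Percent contrast of peak instantaneous rates between two summaries
#'
#' Computes the peak rate I = r * NU_max / 4 from each summary's mean
#' parameters and applies [percent_contrast()]. Using ratios of mean
#' parameters (not means of per-replicate ratios) is the convention under
#' which published percent contrasts reproduce from parameter-table means.
#'
#' @param summary_a,summary_b Lists or one-row data frames with elements
#'   `r` and `nu_max` (mean parameters); must describe the same response.
#' @return Signed integer percent by which `summary_a`'s peak rate exceeds
#'   `summary_b`'s.
#' @examples
#' peak_rate_contrast(list(r = 1.15, nu_max = 15.26),
#'                    list(r = 0.92, nu_max = 11.35)) # +68
#' @export
peak_rate_contrast <- function(summary_a, summary_b) {
  ia <- summary_peak(summary_a)
  ib <- summary_peak(summary_b)
  percent_contrast(ia, ib)
}

summary_peak <- function(s) {
  s <- as.list(s)
  stopifnot(all(c("r", "nu_max") %in% names(s)))
  as.numeric(s$r) * as.numeric(s$nu_max) / 4
}

#' Temporal differentiation of peak timing between two trajectories
#'
#' The shift in peak-rate timing Delta t_max = t_max(A) - t_max(B) between
#' two fitted trajectories, with the SE of the difference propagated as
#' sqrt(SE_A^2 + SE_B^2) under independent errors, and a direction label
#' (`"earlier"` / `"later"` / `"none"`) describing A relative to B, from a
#' Welch t-test on the summary statistics at level `alpha`. Intra-specific
#' shifts compare one species across contexts; inter-specific shifts
#' compare the two partners within one mixture.
#'
#' @param summary_a,summary_b Lists or one-row data frames with `t_max`,
#'   `t_max_se` and `n_replicates` (n defaults to 3).
#' @param alpha Significance level for the direction label (default 0.05).
#' @return A tibble of class `temporal_shift` with `delta_t_max` (weeks,
#'   A - B), `se`, `statistic`, `df`, `p_value`, `direction` — the label
#'   describing A relative to B (negative shift = A peaks earlier).
#' @export
temporal_shift <- function(summary_a, summary_b, alpha = 0.05) {
  a <- as.list(summary_a)
  b <- as.list(summary_b)
  stopifnot(all(c("t_max", "t_max_se") %in% names(a)),
            all(c("t_max", "t_max_se") %in% names(b)))
  na <- as.numeric(a$n_replicates %||% 3)
  nb <- as.numeric(b$n_replicates %||% 3)
  delta <- as.numeric(a$t_max) - as.numeric(b$t_max)
  se_a <- as.numeric(a$t_max_se)
  se_b <- as.numeric(b$t_max_se)
  se_d <- sqrt(se_a^2 + se_b^2)
  if (is.finite(se_d) && se_d > 0) {
    stat <- delta / se_d
    df <- se_d^4 / (se_a^4 / (na - 1) + se_b^4 / (nb - 1))
    p <- 2 * stats::pt(-abs(stat), df)
  } else {
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- na + nb - 2
    p <- if (delta == 0) 1 else 0
  }
  direction <- if (delta == 0 || p >= alpha) "none"
               else if (delta < 0) "earlier" else "later"
  structure(tibble::tibble(delta_t_max = delta, se = se_d, statistic = stat,
                           df = df, p_value = p, direction = direction),
            class = c("temporal_shift", "tbl_df", "tbl", "data.frame"))
}

#' Table of temporal shifts across a summary table
#'
#' In `"intra"` mode every pair of contexts of one species (within one
#' response) is compared; in `"inter"` mode the two partner species within
#' each mixture are compared. Shifts are computed with [temporal_shift()].
#'
#' @param summaries A summary tibble from [summarize_fits()] (or
#'   [field_estimates()] augmented with `n_replicates`).
#' @param mode `"intra"` or `"inter"`.
#' @param alpha Significance level for direction labels.
#' @return A tibble with the two trajectory keys, `delta_t_max`, `se`,
#'   `p_value` and `direction` per comparison.
#' @export
temporal_differentiation <- function(summaries, mode = c("intra", "inter"),
                                     alpha = 0.05) {
  mode <- match.arg(mode)
  s <- tibble::as_tibble(summaries)
  stopifnot(all(c("species", "context", "response", "t_max", "t_max_se")
                %in% names(s)))
  if (!"n_replicates" %in% names(s)) s$n_replicates <- 3
  if (!"partner" %in% names(s)) s$partner <- NA_character_
  key_label <- function(row) {
    paste0(row$species, ":", row$context,
           ifelse(is.na(row$partner), "", paste0("+", row$partner)))
  }
  pairs <- if (mode == "intra") intra_pairs(s) else inter_pairs(s)
  if (nrow(pairs) == 0) {
    stop("no comparable trajectory pairs found for mode '", mode, "'",
         call. = FALSE)
  }
  purrr::pmap_dfr(pairs, function(ia, ib) {
    a <- s[ia, ]
    b <- s[ib, ]
    shift <- temporal_shift(a, b, alpha = alpha)
    tibble::tibble(response = a$response,
                   key_a = key_label(a), key_b = key_label(b),
                   delta_t_max = shift$delta_t_max, se = shift$se,
                   p_value = shift$p_value, direction = shift$direction)
  })
}

intra_pairs <- function(s) {
  idx <- seq_len(nrow(s))
  grp <- split(idx, paste(s$species, s$response))
  purrr::map_dfr(grp, function(ii) {
    if (length(ii) < 2) return(NULL)
    cmb <- utils::combn(ii, 2)
    tibble::tibble(ia = cmb[1, ], ib = cmb[2, ])
  })
}

inter_pairs <- function(s) {
  mixes <- s[s$context == "mixture" & !is.na(s$partner), ]
  if (nrow(mixes) == 0) return(tibble::tibble(ia = integer(), ib = integer()))
  done <- character()
  rows <- list()
  for (i in seq_len(nrow(mixes))) {
    a <- mixes[i, ]
    pair_id <- paste(sort(c(a$species, a$partner)), a$response,
                     collapse = "|")
    if (pair_id %in% done) next
    j <- which(s$context == "mixture" & s$species == a$partner &
                 s$partner == a$species & s$response == a$response)
    if (length(j) == 1) {
      ia <- which(s$species == a$species & s$context == "mixture" &
                    s$partner == a$partner & s$response == a$response)
      rows[[length(rows) + 1]] <- tibble::tibble(ia = ia, ib = j)
      done <- c(done, pair_id)
    } else {
      stop("missing mixture counterpart for ", a$species, " + ", a$partner,
           " (", a$response, ")", call. = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Organic-acid exudation per gram root, by group
#'
#' Converts per-plant organic-acid totals to umol per g root dry weight,
#' averages per (species, context, week) and attaches a t-based error band:
#' half-width = SE x t(0.975, n - 1). Records with zero or missing root dry
#' weight are excluded with a warning; groups with n = 1 report a mean but
#' no band.
#'
#' @param dataset Harvest tibble containing `oa_umol` and `root_dw_g`.
#' @return A tibble per (species, context, week): `mean_oa_per_g`, `se`,
#'   `band_half_width`, `n`.
#' @export
exudation_summary <- function(dataset) {
  stopifnot(all(c("oa_umol", "root_dw_g") %in% names(dataset)))
  d <- dataset[!is.na(dataset$oa_umol), ]
  bad <- is.na(d$root_dw_g) | d$root_dw_g <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with zero or missing root dry weight ",
            "excluded from exudation summary", call. = FALSE)
    d <- d[!bad, ]
  }
  d$oa_per_g <- d$oa_umol / d$root_dw_g
  d |>
    dplyr::group_by(.data$species, .data$context, .data$week) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_oa_per_g = mean(.data$oa_per_g),
      se = dplyr::if_else(n >= 2, stats::sd(.data$oa_per_g) / sqrt(n),
                          NA_real_),
      band_half_width = dplyr::if_else(
        n >= 2,
        # pmax keeps qt off df = 0 for the n = 1 branch, which if_else
        # still evaluates before discarding
        se * stats::qt(0.975, pmax(n - 1, 1)),
        NA_real_),
      .groups = "drop"
    ) |>
    dplyr::select("species", "context", "week", "mean_oa_per_g", "se",
                  "band_half_width", "n")
}
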