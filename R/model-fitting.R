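# Two-stage nonlinear least-squares estimation of the logistic parameters,
# per (species, context, response, replicate) trajectory: a damped
# (Levenberg-Marquardt) fit supplies starting values for a bounded
# Gauss-Newton polishing pass, and replicate-level estimates are aggregated
# to mean +/- SE summaries.

MIN_FIT_POINTS <- 5L

#' Heuristic starting values for a logistic fit
#'
#' The asymptote starts at 1.05 x the largest observation, the inflection
#' week at the earliest week whose value reaches half the observed maximum,
#' and the rate at the slope of a straight-line fit of
#' logit(value / NU_max0) against week over the interior of the curve
#' (points between 10% and 90% of the provisional asymptote, where the
#' logit transform is close to linear in t), floored at 0.05/week.
#'
#' @param observations Data frame with columns `week` and `value`.
#' @return A [logistic_params()] object.
#' @export
initial_values <- function(observations) {
  check_series(observations)
  wk <- observations$week
  v <- observations$value
  vmax <- max(v)
  nu_max0 <- 1.05 * vmax
  t_max0 <- min(wk[v >= vmax / 2])
  ratio <- v / nu_max0
  interior <- ratio > 0.10 & ratio < 0.90
  if (sum(interior) < 2 || length(unique(wk[interior])) < 2) {
    # very steep curves leave < 2 points in the narrow band; widen it
    interior <- ratio > 0.02 & ratio < 0.98
  }
  r0 <- 0.05
  if (sum(interior) >= 2 && length(unique(wk[interior])) >= 2) {
    lv <- stats::qlogis(ratio[interior])
    r0 <- max(unname(stats::coef(stats::lm(lv ~ wk[interior]))[2]), 0.05,
              na.rm = TRUE)
  }
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.05
  logistic_params(nu_max0, r0, t_max0)
}

check_series <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("week", "value") %in% names(observations)))
  observations <- observations[is.finite(observations$value), ]
  if (nrow(observations) < MIN_FIT_POINTS) {
    stop("need at least ", MIN_FIT_POINTS,
         " observations to fit a logistic curve", call. = FALSE)
  }
  if (length(unique(observations$week)) < 3) {
    stop("need observations at >= 3 distinct weeks", call. = FALSE)
  }
  if (max(observations$value) <= 0) {
    stop("series is non-identifiable: no positive values", call. = FALSE)
  }
  if (stats::sd(observations$value) == 0) {
    stop("series is non-identifiable: constant values carry no growth signal",
         call. = FALSE)
  }
  invisible(observations)
}

#' Fit the logistic accumulation model to one trajectory
#'
#' Stage 1 minimises the residual sum of squares with the damped
#' Levenberg-Marquardt algorithm ([minpack.lm::nlsLM()]) from
#' [initial_values()] (or a caller-supplied start); stage 2 polishes the
#' stage-1 optimum with bounded Gauss-Newton ([stats::nls()], `"port"`
#' algorithm). Bounds are NU_max > 0, r > 0, 0 < t_max < 2 x the last
#' observed week. If the polishing pass fails (as it does by design on
#' zero-residual data) the stage-1 optimum is kept. Non-convergence is
#' reported through the `converged` flag, never as an error.
#'
#' @param observations Data frame with columns `week` and `value`
#'   (>= 5 points at >= 3 distinct weeks).
#' @param init Optional [logistic_params()] starting values.
#' @param max_iter Iteration cap per stage (default 1000).
#' @param tol Convergence tolerance on the relative offset / gradient
#'   (default 1e-8).
#' @return A list of class `logistic_fit`: `params` ([logistic_params()]),
#'   `std_errors` (named numeric), `covariance` (3x3), `residual_sse`,
#'   `n_points`, `converged`, `n_iterations`, `stage` (`"polished"` or
#'   `"stage1"`).
#' @export
fit_logistic <- function(observations, init = NULL, max_iter = 1000,
                         tol = 1e-8) {
  observations <- check_series(observations)
  df <- data.frame(week = as.numeric(observations$week),
                   value = as.numeric(observations$value))
  if (is.null(init)) init <- initial_values(df)
  init <- as_logistic_params(init)
  lower <- c(nu_max = 1e-10, r = 1e-6, t_max = 1e-6)
  upper <- c(nu_max = Inf, r = Inf, t_max = 2 * max(df$week))
  start <- pmin(pmax(c(nu_max = init$nu_max, r = init$r, t_max = init$t_max),
                     lower), upper)

  stage1 <- tryCatch(
    minpack.lm::nlsLM(
      value ~ nu_max / (1 + exp(pmin(pmax(r * (t_max - week), -709), 709))),
      data = df, start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                           ptol = tol)
    ),
    error = function(e) NULL
  )
  if (is.null(stage1)) {
    return(failed_fit(start, nrow(df),
                      sse = sum((df$value - logistic_value(init, df$week))^2)))
  }
  co1 <- stats::coef(stage1)

  stage2 <- tryCatch(
    stats::nls(
      value ~ nu_max / (1 + exp(pmin(pmax(r * (t_max - week), -709), 709))),
      data = df, start = as.list(co1), algorithm = "port",
      lower = lower, upper = upper,
      control = stats::nls.control(maxiter = max_iter, tol = tol,
                                   warnOnly = TRUE)
    ),
    error = function(e) NULL
  )

  fit <- if (!is.null(stage2) && stage2_improves(stage2, stage1)) stage2
         else stage1
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(co)
  conv_info <- fit$convInfo
  converged <- isTRUE(conv_info$isConv) && all(is.finite(co)) &&
    all(co > 0 | names(co) == "t_max")
  structure(list(
    params = logistic_params(co[["nu_max"]], co[["r"]], co[["t_max"]]),
    std_errors = se,
    covariance = vc,
    residual_sse = sum(stats::resid(fit)^2),
    n_points = nrow(df),
    converged = converged,
    n_iterations = if (!is.null(conv_info$finIter)) conv_info$finIter else NA_integer_,
    stage = if (identical(fit, stage2)) "polished" else "stage1"
  ), class = "logistic_fit")
}

stage2_improves <- function(stage2, stage1) {
  s2 <- sum(stats::resid(stage2)^2)
  s1 <- sum(stats::resid(stage1)^2)
  is.finite(s2) && s2 <= s1 + 1e-12 * (1 + s1)
}

failed_fit <- function(start, n_points, sse) {
  structure(list(
    params = logistic_params(start[["nu_max"]], start[["r"]],
                             start[["t_max"]]),
    std_errors = c(nu_max = NA_real_, r = NA_real_, t_max = NA_real_),
    covariance = matrix(NA_real_, 3, 3),
    residual_sse = sse,
    n_points = n_points,
    converged = FALSE,
    n_iterations = NA_integer_,
    stage = "failed"
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> NU_max = %.4g (SE %.3g), r = %.4g (SE %.3g), t_max = %.4g (SE %.3g)\n  SSE %.4g over %d points; %s\n",
    x$params$nu_max, x$std_errors[["nu_max"]], x$params$r,
    x$std_errors[["r"]], x$params$t_max, x$std_errors[["t_max"]],
    x$residual_sse, x$n_points,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit every trajectory of a harvest dataset
#'
#' One logistic fit per (species, context, partner, response, replicate)
#' when `pooled = FALSE` (the default, matching replicate-level summaries
#' with n = 3), or one pooled fit per (species, context, partner, response)
#' across replicates when `pooled = TRUE`. Keys with fewer than 5 usable
#' points (or an otherwise non-identifiable series) are skipped with a
#' structured warning, never an error. Output order is deterministic.
#'
#' @param dataset A harvest tibble in the [read_harvest()] schema.
#' @param responses Which response columns to fit; any of `"biomass"`,
#'   `"n"`, `"p"`.
#' @param pooled Fit replicates jointly instead of separately.
#' @return A tibble of class `fit_table` with one row per fit: the key
#'   columns, `nu_max`, `r`, `t_max`, their `*_se`, `residual_sse`,
#'   `n_points`, `converged`, `n_iterations`. Skipped keys are recorded in
#'   the `skipped` attribute.
#' @export
fit_all <- function(dataset, responses = c("biomass", "n", "p"),
                    pooled = FALSE) {
  responses <- match.arg(responses, several.ok = TRUE)
  col_of <- c(biomass = "biomass_g", n = "n_mg", p = "p_mg")
  long <- purrr::map_dfr(responses, function(resp) {
    tibble::tibble(
      species = dataset$species, context = dataset$context,
      partner = dataset$partner, replicate = dataset$block_id,
      week = dataset$week, response = resp,
      value = dataset[[col_of[[resp]]]]
    )
  })
  if (pooled) long$replicate <- 0L
  keys <- long |>
    dplyr::distinct(.data$species, .data$context, .data$partner,
                    .data$response, .data$replicate) |>
    dplyr::arrange(.data$species, .data$context, .data$partner,
                   .data$response, .data$replicate)

  skipped <- list()
  rows <- purrr::pmap(keys, function(species, context, partner, response,
                                     replicate) {
    sel <- long$species == species & long$context == context &
      (long$partner %in% partner | (is.na(partner) & is.na(long$partner))) &
      long$response == response & long$replicate == replicate
    series <- long[sel, c("week", "value")]
    series <- series[is.finite(series$value), ]
    fit <- tryCatch(fit_logistic(series), error = function(e) e)
    if (inherits(fit, "error")) {
      key <- paste(species, context, response, replicate, sep = "/")
      warning("skipping ", key, ": ", conditionMessage(fit), call. = FALSE)
      skipped[[length(skipped) + 1]] <<- key
      return(NULL)
    }
    tibble::tibble(
      species = species, context = context, partner = partner,
      response = response, replicate = replicate,
      nu_max = fit$params$nu_max, r = fit$params$r, t_max = fit$params$t_max,
      nu_max_se = fit$std_errors[["nu_max"]], r_se = fit$std_errors[["r"]],
      t_max_se = fit$std_errors[["t_max"]],
      residual_sse = fit$residual_sse, n_points = fit$n_points,
      converged = fit$converged, n_iterations = fit$n_iterations
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- unlist(skipped)
  class(out) <- c("fit_table", class(out))
  out
}

#' Summarise replicate fits to mean +/- SE per trajectory
#'
#' Aggregates converged per-replicate fits to mean and standard error
#' (sd / sqrt(n)) of each logistic parameter, the convention of published
#' parameter tables with n = 3 replicates. Non-converged fits are excluded
#' and counted.
#'
#' @param fits A `fit_table` from [fit_all()].
#' @return A tibble with one row per (species, context, partner, response):
#'   `nu_max`, `r`, `t_max` means, their `*_se`, `n_replicates`,
#'   `n_excluded`. SEs are NA when fewer than 2 converged replicates remain.
#' @export
summarize_fits <- function(fits) {
  se <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  fits |>
    dplyr::group_by(.data$species, .data$context, .data$partner,
                    .data$response) |>
    dplyr::summarise(
      n_excluded = sum(!.data$converged),
      dplyr::across(c("nu_max", "r", "t_max"),
                    list(mean = ~ mean(.x[.data$converged]),
                         se = ~ se(.x[.data$converged]))),
      n_replicates = sum(.data$converged),
      .groups = "drop"
    ) |>
    dplyr::rename(nu_max = "nu_max_mean", r = "r_mean", t_max = "t_max_mean") |>
    dplyr::select("species", "context", "partner", "response",
                  "nu_max", "nu_max_se", "r", "r_se", "t_max", "t_max_se",
                  "n_replicates", "n_excluded")
}
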