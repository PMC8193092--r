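# Harvest-table file schema, validation, and the end-to-end pipeline.
#
# The tidy harvest CSV holds one row per sampled individual per weekly
# destructive harvest. Units: biomass g/individual, N and P mg/individual,
# delta-15N permil, organic acids umol/plant, root dry weight g, plot
# yield g/plot. Weeks are integers since seedling emergence, 1-based.

HARVEST_REQUIRED <- c("species", "context", "partner", "block_id", "week",
                      "individual_id", "biomass_g", "n_mg", "p_mg")
HARVEST_OPTIONAL <- c("delta15n_permil", "oa_umol", "root_dw_g",
                      "plot_yield_g")
HARVEST_CONTEXTS <- c("single", "monoculture", "mixture")

#' Read and validate a harvest CSV
#'
#' Schema validation is strict: all required columns present, contexts from
#' the fixed vocabulary, `partner` set exactly for mixture rows, keys
#' (species, context, partner, block, week, individual) unique, numeric
#' measurements non-negative. Violations raise an error naming the column
#' and the offending row numbers.
#'
#' @param path CSV file path (UTF-8, with header).
#' @return A validated tibble.
#' @export
read_harvest <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_harvest(dat)
}

#' Validate an in-memory harvest table
#'
#' @param dat A data frame in the harvest schema.
#' @return The validated tibble (invisibly usable), with columns in
#'   canonical order.
#' @export
validate_harvest <- function(dat) {
  missing <- setdiff(HARVEST_REQUIRED, names(dat))
  if (length(missing) > 0) {
    stop("harvest table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- tibble::as_tibble(dat)
  for (col in setdiff(HARVEST_OPTIONAL, names(dat))) dat[[col]] <- NA_real_

  bad_ctx <- which(!dat$context %in% HARVEST_CONTEXTS)
  if (length(bad_ctx) > 0) {
    stop("invalid context at row(s) ", row_list(bad_ctx),
         " (expected single/monoculture/mixture)", call. = FALSE)
  }
  bad_partner <- which((dat$context == "mixture") == is.na(dat$partner))
  if (length(bad_partner) > 0) {
    stop("partner must be set exactly for mixture rows; violated at row(s) ",
         row_list(bad_partner), call. = FALSE)
  }
  bad_week <- which(!is.finite(dat$week) | dat$week < 1 |
                      dat$week != floor(dat$week))
  if (length(bad_week) > 0) {
    stop("week must be a positive integer; violated at row(s) ",
         row_list(bad_week), call. = FALSE)
  }
  for (col in c("biomass_g", "n_mg", "p_mg", "oa_umol", "root_dw_g",
                "plot_yield_g")) {
    bad <- which(!is.na(dat[[col]]) & dat[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative ", col, " at row(s) ", row_list(bad), call. = FALSE)
    }
  }
  key <- paste(dat$species, dat$context, dat$partner, dat$block_id,
               dat$week, dat$individual_id)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (species, context, partner, block, week, individual) ",
         "key at row(s) ", row_list(dup), call. = FALSE)
  }
  dat[, c(HARVEST_REQUIRED, HARVEST_OPTIONAL)]
}

row_list <- function(rows, max_shown = 5) {
  shown <- utils::head(rows, max_shown)
  txt <- paste(shown, collapse = ", ")
  if (length(rows) > max_shown) {
    txt <- paste0(txt, ", ... (", length(rows), " total)")
  }
  txt
}

#' Write a harvest table to CSV
#'
#' Floating-point columns are serialised at 9 significant digits so that
#' identical inputs produce byte-identical files.
#'
#' @param dat Harvest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harvest <- function(dat, path) {
  out <- validate_harvest(dat)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param seed Top-level integer seed.
#' @param design An [experiment_design()].
#' @param truth A `truth_set` (defaults to [default_truth()] of the
#'   design).
#' @param noise A [noise_spec()]; its seed is overridden by `seed`.
#' @param alpha Significance level for all tests.
#' @param output_dir Directory for output CSVs, or NULL to skip writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = experiment_design(),
                       truth = default_truth(design),
                       noise = noise_spec(), alpha = 0.05,
                       output_dir = NULL) {
  noise <- noise_spec(noise$model, noise$cv_or_sd, seed = seed)
  structure(list(seed = as.integer(seed), design = design, truth = truth,
                 noise = noise, alpha = alpha, output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a harvest dataset, fits every trajectory,
#' summarises parameters, computes intra-specific contrasts of accumulation
#' maxima and peak rates (mixture and single vs monoculture), temporal
#' shifts, LER from final-week plot yields, the weekly nitrogen-fixation
#' table with its diversity-level test, the exudation summary, and
#' letter displays per (species, response, parameter). Deterministic given
#' the seed. If `config$output_dir` is set, each artifact is written as a
#' CSV with 9-significant-digit numeric formatting.
#'
#' @param config A [run_config()].
#' @param dataset Optional harvest tibble; when NULL one is simulated from
#'   the config.
#' @return A list of class `pipeline_result` with elements `dataset`,
#'   `fits`, `summaries`, `contrasts`, `temporal_intra`, `temporal_inter`,
#'   `ler`, `ndfa`, `ndfa_diversity`, `exudation`, `letters`, `warnings`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  warnings <- character()
  note <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  if (is.null(dataset)) {
    dataset <- generate_experiment(config$design, config$truth,
                                   config$noise)
  }
  dataset <- validate_harvest(dataset)

  fits <- note(fit_all(dataset))
  summaries <- summarize_fits(fits)
  contrasts <- note(context_contrasts(summaries))
  temporal_intra <- note(temporal_differentiation(summaries, "intra",
                                                  config$alpha))
  temporal_inter <- note(temporal_differentiation(summaries, "inter",
                                                  config$alpha))
  ler <- note(pipeline_ler(dataset, config$design))
  has_iso <- any(!is.na(dataset$delta15n_permil))
  ndfa_tab <- NULL
  ndfa_div <- NULL
  if (has_iso && !is.null(config$truth$beta_by_week)) {
    ndfa_tab <- note(ndfa_timeseries(dataset, config$truth$beta_by_week,
                                     legume = config$truth$legume))
    ndfa_div <- note(diversity_effect_ndfa(ndfa_tab, config$alpha))
  }
  exu <- if (any(!is.na(dataset$oa_umol)))
    note(exudation_summary(dataset)) else NULL
  letters <- note(parameter_letters(fits, config$alpha))

  result <- structure(list(
    dataset = dataset, fits = fits, summaries = summaries,
    contrasts = contrasts, temporal_intra = temporal_intra,
    temporal_inter = temporal_inter, ler = ler, ndfa = ndfa_tab,
    ndfa_diversity = ndfa_div, exudation = exu, letters = letters,
    warnings = warnings, config = config
  ), class = "pipeline_result")
  if (!is.null(config$output_dir)) write_artifacts(result)
  result
}

# Mixture (and single) vs monoculture percent contrasts of NU_max and of
# the peak rate I = r * NU_max / 4, per species x response.
context_contrasts <- function(summaries) {
  purrr::pmap_dfr(
    summaries[summaries$context != "monoculture", ],
    function(species, context, partner, response, nu_max, r, ...) {
      mono <- summaries[summaries$species == species &
                          summaries$context == "monoculture" &
                          summaries$response == response, ]
      if (nrow(mono) != 1 || !is.finite(mono$nu_max) || !is.finite(nu_max)) {
        return(NULL)
      }
      tibble::tibble(
        species = species, response = response, context = context,
        partner = partner,
        numax_vs_mono_pct = percent_contrast(nu_max, mono$nu_max),
        imax_vs_mono_pct = peak_rate_contrast(
          list(r = r, nu_max = nu_max),
          list(r = mono$r, nu_max = mono$nu_max))
      )
    })
}

pipeline_ler <- function(dataset, design) {
  final_weeks <- utils::tail(design$harvest_weeks, 2)
  y <- dataset[!is.na(dataset$plot_yield_g) &
                 dataset$week %in% final_weeks, ]
  if (nrow(y) == 0) return(NULL)
  mono <- y[y$context == "monoculture",
            c("species", "block_id", "week", "plot_yield_g")]
  purrr::map_dfr(design$mixtures, function(m) {
    mix <- y[y$context == "mixture" & y$species %in% m &
               y$partner %in% m, ]
    if (nrow(mix) == 0 || !all(m %in% mix$species) ||
        !all(m %in% mono$species)) {
      return(NULL)
    }
    res <- compute_ler(
      tibble::tibble(species = mix$species,
                     replicate = paste(mix$week, mix$block_id),
                     yield = mix$plot_yield_g),
      tibble::tibble(species = mono$species[mono$species %in% m],
                     replicate = paste(mono$week, mono$block_id)[
                       mono$species %in% m],
                     yield = mono$plot_yield_g[mono$species %in% m])
    )
    tibble::tibble(
      mixture = paste(m, collapse = "-"),
      species = c(res$partial$species, "total"),
      ler = c(res$partial$partial_ler, res$total),
      ler_se = c(res$partial$partial_ler_se, res$total_se)
    )
  })
}

parameter_letters <- function(fits, alpha) {
  conv <- fits[fits$converged, ]
  combos <- unique(conv[, c("species", "response")])
  purrr::pmap_dfr(combos, function(species, response) {
    g <- conv[conv$species == species & conv$response == response, ]
    purrr::map_dfr(c("nu_max", "r", "t_max"), function(param) {
      ctx <- ifelse(g$context == "mixture",
                    paste0(g$context, "+", g$partner), g$context)
      est <- tibble::tibble(context = ctx, value = g[[param]])
      cmp <- tryCatch(compare_contexts(est, alpha = alpha),
                      error = function(e) NULL)
      if (is.null(cmp)) return(NULL)
      tibble::tibble(species = species, response = response,
                     parameter = param,
                     context = cmp$letters$context,
                     mean = cmp$letters$mean,
                     letter = cmp$letters$letter,
                     anova_p = cmp$anova_p)
    })
  })
}

write_artifacts <- function(result) {
  dir <- result$config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(x, name) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(invisible())
    num <- vapply(x, is.double, logical(1))
    x[num] <- lapply(x[num], function(v) signif(v, 9))
    readr::write_csv(x, file.path(dir, paste0(name, ".csv")), na = "")
  }
  write_harvest(result$dataset, file.path(dir, "harvest.csv"))
  emit(result$fits, "fits")
  emit(result$summaries, "summaries")
  emit(result$contrasts, "contrasts")
  emit(result$temporal_intra, "temporal_intra")
  emit(result$temporal_inter, "temporal_inter")
  emit(result$ler, "ler")
  emit(result$ndfa, "ndfa")
  emit(result$exudation, "exudation")
  emit(result$letters, "letters")
  writeLines(
    c(paste0("seed: ", result$config$seed),
      paste0("noise: ", result$config$noise$model, " cv_or_sd=",
             result$config$noise$cv_or_sd),
      paste0("alpha: ", result$config$alpha),
      paste0("warnings: ", length(result$warnings)),
      result$warnings),
    file.path(dir, "run-log.txt")
  )
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  dataset: %d records, %d trajectories fitted (%d converged)\n",
              nrow(x$dataset), nrow(x$fits), sum(x$fits$converged)))
  if (!is.null(x$ler) && nrow(x$ler) > 0) {
    tot <- x$ler[x$ler$species == "total", ]
    for (i in seq_len(nrow(tot))) {
      cat(sprintf("  LER %s: %.2f\n", tot$mixture[i], tot$ler[i]))
    }
  }
  if (!is.null(x$ndfa_diversity)) {
    cat(sprintf("  Ndfa diversity effect: %s\n",
                if (x$ndfa_diversity$significant) "significant"
                else "not significant"))
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("  %d warning(s) recorded\n", length(x$warnings)))
  }
  invisible(x)
}
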