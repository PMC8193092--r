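# Seeded synthetic destructive-harvest data with known ground truth.
#
# The generator emulates the field design the package targets: three crop
# species (oat, lupin, camelina) grown as isolated single plants, in
# monoculture and in two 2-species mixtures, harvested weekly (18 harvests,
# 3 replicates per harvest), with per-individual biomass, N and P values
# lying on logistic trajectories plus replicate noise, and legume delta-15N
# consistent with a prescribed nitrogen-fixation level.

substream <- function(seed, i) {
  # deterministic per-task seeds derived from one top-level seed; kept < 2^31
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * i) %% 2147483647)
}

#' Experimental design of a destructive-harvest intercropping trial
#'
#' @param species Character vector of species identifiers.
#' @param mixtures List of length-2 character vectors naming the 2-species
#'   mixtures; each species must appear in `species`.
#' @param harvest_weeks Strictly increasing integer weeks since seedling
#'   emergence (default 1..18, one harvest per week).
#' @param replicates Replicate plots harvested per week (default 3).
#' @param sowing_densities Named numeric vector of seeds/m^2 per species;
#'   defaults follow common cultivation practice for the three crops.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(species = c("oat", "lupin", "camelina"),
                              mixtures = list(c("oat", "lupin"),
                                              c("oat", "camelina")),
                              harvest_weeks = 1:18,
                              replicates = 3,
                              sowing_densities = c(oat = 400, lupin = 160,
                                                   camelina = 592)) {
  stopifnot(
    is.character(species), length(species) >= 1, !anyDuplicated(species),
    is.numeric(harvest_weeks), length(harvest_weeks) >= 1,
    all(diff(harvest_weeks) > 0),
    is.numeric(replicates), length(replicates) == 1, replicates >= 1
  )
  for (m in mixtures) {
    if (length(m) != 2 || anyDuplicated(m) || !all(m %in% species)) {
      stop("each mixture must name exactly two distinct species from `species`",
           call. = FALSE)
    }
  }
  structure(
    list(species = species, mixtures = mixtures,
         harvest_weeks = as.integer(harvest_weeks),
         replicates = as.integer(replicates),
         sowing_densities = sowing_densities),
    class = "experiment_design"
  )
}

#' Species-context combinations of a design
#'
#' Every species appears once as isolated single plant and once in
#' monoculture; each mixture contributes one combination per member species.
#'
#' @param design An [experiment_design()].
#' @return A tibble with columns `species`, `context`, `partner` (NA unless
#'   mixture), ordered deterministically.
#' @export
design_combos <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  base <- tidyr::expand_grid(species = design$species,
                             context = c("single", "monoculture")) |>
    dplyr::mutate(partner = NA_character_)
  mix <- purrr::map_dfr(design$mixtures, function(m) {
    tibble::tibble(species = m, context = "mixture", partner = rev(m))
  })
  dplyr::bind_rows(base, mix) |>
    dplyr::arrange(.data$species, .data$context, .data$partner)
}

#' Replicate noise specification
#'
#' @param model `"multiplicative-lognormal"` (mean-preserving log-normal
#'   scatter with coefficient of variation `cv_or_sd`; guarantees positive
#'   responses) or `"additive-gaussian"` (Gaussian with standard deviation
#'   `cv_or_sd` in response units, truncated at 0).
#' @param cv_or_sd Non-negative CV (unitless) or SD (response units).
#' @param seed Integer seed; all randomness of a generator call flows from
#'   it through deterministic substreams.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(model = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                       cv_or_sd = 0.10, seed = 1L) {
  if (is.character(model) && length(model) >= 1 &&
      !model[1] %in% c("multiplicative-lognormal", "additive-gaussian")) {
    stop("unknown noise model: ", model[1], call. = FALSE)
  }
  model <- match.arg(model)
  stopifnot(is.numeric(cv_or_sd), length(cv_or_sd) == 1, cv_or_sd >= 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(model = model, cv_or_sd = as.numeric(cv_or_sd),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(mean_values, noise) {
  if (noise$cv_or_sd == 0) return(mean_values)
  n <- length(mean_values)
  if (noise$model == "multiplicative-lognormal") {
    # sdlog chosen so the log-normal factor has mean 1 and CV = cv_or_sd
    sdlog <- sqrt(log(1 + noise$cv_or_sd^2))
    mean_values * exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  } else {
    pmax(mean_values + stats::rnorm(n, sd = noise$cv_or_sd), 0)
  }
}

#' Generate one noisy logistic trajectory
#'
#' Draws an `n_rep`-replicate grid of observations whose expected value at
#' week t is the logistic curve NU_max / (1 + exp(r (t_max - t))). With
#' `cv_or_sd = 0` the observations lie exactly on the curve; the same seed
#' always reproduces the same draws; values are never negative.
#'
#' @param truth A [logistic_params()] object (or coercible list).
#' @param weeks Ordered weeks at which observations are taken.
#' @param noise A [noise_spec()].
#' @param n_rep Number of replicates per week.
#' @return A tibble with columns `week`, `replicate`, `value`.
#' @export
generate_trajectory <- function(truth, weeks, noise = noise_spec(),
                                n_rep = 3) {
  p <- as_logistic_params(truth)
  stopifnot(inherits(noise, "noise_spec"),
            is.numeric(weeks), length(weeks) >= 1, n_rep >= 1)
  grid <- tidyr::expand_grid(week = weeks, replicate = seq_len(n_rep))
  mu <- logistic_value(p, grid$week)
  vals <- withr::with_seed(noise$seed, apply_noise(mu, noise))
  tibble::tibble(week = grid$week, replicate = grid$replicate, value = vals)
}

fill_camelina_single_n <- function(params) {
  # the reference field estimates leave camelina-single N unresolved;
  # a plausible synthetic value keeps the full-design truth complete
  idx <- is.na(params$nu_max)
  params$nu_max[idx] <- 300
  params$r[idx] <- 0.9
  params$t_max[idx] <- 11.5
  params
}

#' Default ground-truth parameter set for the standard design
#'
#' Logistic parameters per (species, context, response) follow the bundled
#' field estimates ([field_estimates()] means; the unresolved
#' camelina-single nitrogen entry is filled with a plausible synthetic
#' value). Prescribed lupin nitrogen fixation is 75% (mixture), 72%
#' (monoculture) and 45% (single) for weeks 5-16, the beta calibration is a
#' constant -0.5 permil and the reference-plant delta-15N a constant 3
#' permil — magnitudes typical of natural-abundance studies.
#'
#' @param design An [experiment_design()]; truth is restricted to its
#'   combinations.
#' @return A list of class `truth_set` with elements `params` (tibble:
#'   species, context, partner, response, nu_max, r, t_max),
#'   `ndfa_true` (tibble: diversity, week, ndfa_true), `beta_by_week`
#'   (tibble: week, beta_permil), `ref_delta_by_week` (tibble: week,
#'   delta15n_permil) and `legume` (species name).
#' @export
default_truth <- function(design = experiment_design()) {
  params <- field_estimates() |>
    dplyr::select("species", "context", "partner", "response",
                  "nu_max", "r", "t_max") |>
    fill_camelina_single_n() |>
    dplyr::semi_join(design_combos(design),
                     by = c("species", "context", "partner"))
  iso_weeks <- intersect(5:16, design$harvest_weeks)
  ndfa_true <- tidyr::expand_grid(
    diversity = c("mixture", "monoculture", "single"),
    week = iso_weeks
  ) |>
    dplyr::mutate(ndfa_true = c(mixture = 75, monoculture = 72,
                                single = 45)[.data$diversity])
  truth_set(
    params = params,
    ndfa_true = ndfa_true,
    beta_by_week = tibble::tibble(week = iso_weeks, beta_permil = -0.5),
    ref_delta_by_week = tibble::tibble(week = iso_weeks,
                                       delta15n_permil = 3.0),
    legume = "lupin"
  )
}

#' Construct and validate a ground-truth set
#'
#' @param params Tibble of logistic parameters per (species, context,
#'   partner, response) with columns `nu_max`, `r`, `t_max`.
#' @param ndfa_true Tibble (`diversity`, `week`, `ndfa_true` in 0..100) of
#'   prescribed legume nitrogen fixation, or NULL to omit isotope data.
#' @param beta_by_week Tibble (`week`, `beta_permil`).
#' @param ref_delta_by_week Tibble (`week`, `delta15n_permil`).
#' @param legume Name of the nitrogen-fixing species.
#' @return A list of class `truth_set`.
#' @export
truth_set <- function(params, ndfa_true = NULL, beta_by_week = NULL,
                      ref_delta_by_week = NULL, legume = "lupin") {
  stopifnot(is.data.frame(params),
            all(c("species", "context", "partner", "response", "nu_max",
                  "r", "t_max") %in% names(params)),
            all(params$nu_max > 0), all(params$r > 0),
            all(is.finite(params$t_max)))
  if (!is.null(ndfa_true)) {
    stopifnot(all(ndfa_true$ndfa_true >= 0), all(ndfa_true$ndfa_true <= 100))
  }
  structure(list(params = params, ndfa_true = ndfa_true,
                 beta_by_week = beta_by_week,
                 ref_delta_by_week = ref_delta_by_week, legume = legume),
            class = "truth_set")
}

#' Serialise a truth set to YAML
#'
#' @param truth A `truth_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  out <- list(
    params = purrr::transpose(as.list(truth$params)),
    ndfa_true = if (!is.null(truth$ndfa_true))
      purrr::transpose(as.list(truth$ndfa_true)),
    beta_by_week = if (!is.null(truth$beta_by_week))
      purrr::transpose(as.list(truth$beta_by_week)),
    ref_delta_by_week = if (!is.null(truth$ref_delta_by_week))
      purrr::transpose(as.list(truth$ref_delta_by_week)),
    legume = truth$legume
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

plants_per_plot <- function(design, species, context) {
  # plot area 0.25 m^2; mixtures follow a substitutive design (half the
  # monoculture seed number per species)
  dens <- design$sowing_densities[species]
  n <- dens * 0.25
  n[context == "mixture"] <- n[context == "mixture"] / 2
  n[context == "single"] <- 1
  unname(n)
}

#' Generate delta-15N records from a prescribed fixation level
#'
#' Inverts the isotope-dilution relation: the noiseless legume signature is
#' delta_legume = delta_ref - (Ndfa/100) * (delta_ref - beta), so applying
#' [ndfa()] to noiseless output returns the prescribed level exactly. Noise
#' is additive Gaussian on the permil scale (`cv_or_sd` read as SD in
#' permil) for either noise model, since isotope signatures may be negative.
#'
#' @param ndfa_true Tibble (`week`, `ndfa_true`) or a single value in
#'   0..100 applied to all weeks of `beta_by_week`.
#' @param beta_by_week Tibble (`week`, `beta_permil`).
#' @param ref_delta_by_week Tibble (`week`, `delta15n_permil`).
#' @param noise A [noise_spec()].
#' @param n_rep Replicates per week.
#' @param legume,reference Species labels attached to the records.
#' @return Tibble with columns `species`, `role` (`legume`/`reference`),
#'   `week`, `replicate`, `delta15n_permil`.
#' @export
generate_isotope_data <- function(ndfa_true, beta_by_week,
                                  ref_delta_by_week, noise = noise_spec(),
                                  n_rep = 3, legume = "lupin",
                                  reference = "oat") {
  if (is.numeric(ndfa_true) && length(ndfa_true) == 1) {
    ndfa_true <- tibble::tibble(week = beta_by_week$week,
                                ndfa_true = ndfa_true)
  }
  stopifnot(all(ndfa_true$ndfa_true >= 0), all(ndfa_true$ndfa_true <= 100))
  missing_beta <- setdiff(ndfa_true$week, beta_by_week$week)
  if (length(missing_beta) > 0) {
    stop("no beta value for week(s): ",
         paste(missing_beta, collapse = ", "), call. = FALSE)
  }
  missing_ref <- setdiff(ndfa_true$week, ref_delta_by_week$week)
  if (length(missing_ref) > 0) {
    stop("no reference delta-15N for week(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  tab <- ndfa_true |>
    dplyr::inner_join(beta_by_week, by = "week") |>
    dplyr::inner_join(ref_delta_by_week, by = "week") |>
    dplyr::mutate(
      delta_legume = .data$delta15n_permil -
        (.data$ndfa_true / 100) * (.data$delta15n_permil - .data$beta_permil)
    )
  grid <- tidyr::expand_grid(week = tab$week, replicate = seq_len(n_rep))
  leg <- tibble::tibble(
    species = legume, role = "legume", week = grid$week,
    replicate = grid$replicate,
    delta15n_permil = rep(tab$delta_legume, each = n_rep)
  )
  ref <- tibble::tibble(
    species = reference, role = "reference", week = grid$week,
    replicate = grid$replicate,
    delta15n_permil = rep(tab$delta15n_permil, each = n_rep)
  )
  out <- dplyr::bind_rows(leg, ref)
  if (noise$cv_or_sd > 0) {
    out$delta15n_permil <- withr::with_seed(
      noise$seed,
      out$delta15n_permil + stats::rnorm(nrow(out), sd = noise$cv_or_sd)
    )
  }
  out
}

#' Generate a full synthetic destructive-harvest dataset
#'
#' Assembles one harvest record per (species-context combination, harvest
#' week, replicate): biomass, N and P drawn around the truth trajectories,
#' optional legume/reference delta-15N consistent with the prescribed
#' fixation levels, organic-acid and root-mass columns, and plot-level
#' yields for the final two harvest weeks (used for LER).
#'
#' @param design An [experiment_design()].
#' @param truth A `truth_set`; must cover every design combination for the
#'   responses biomass, n and p.
#' @param noise A [noise_spec()]; the top-level seed from which every
#'   substream is derived.
#' @param isotopes,exudation,plot_yields Logical switches for the optional
#'   column groups (all on by default).
#' @return A tibble in the harvest schema of [read_harvest()].
#' @export
generate_experiment <- function(design = experiment_design(),
                                truth = default_truth(design),
                                noise = noise_spec(),
                                isotopes = TRUE, exudation = TRUE,
                                plot_yields = TRUE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "truth_set"), inherits(noise, "noise_spec"))
  combos <- design_combos(design)
  responses <- c("biomass", "n", "p")
  tasks <- tidyr::expand_grid(combos, response = responses)
  key_cols <- c("species", "context", "partner", "response")
  missing <- dplyr::anti_join(tasks, truth$params, by = key_cols)
  if (nrow(missing) > 0) {
    stop("missing truth parameters for: ",
         paste(apply(missing[key_cols], 1, paste, collapse = "/"),
               collapse = "; "), call. = FALSE)
  }
  tasks <- dplyr::inner_join(tasks, truth$params, by = key_cols) |>
    dplyr::mutate(task_id = dplyr::row_number())

  long <- purrr::pmap_dfr(tasks, function(species, context, partner,
                                          response, nu_max, r, t_max,
                                          task_id) {
    tr <- generate_trajectory(
      logistic_params(nu_max, r, t_max), design$harvest_weeks,
      noise_spec(noise$model, noise$cv_or_sd,
                 seed = substream(noise$seed, task_id)),
      n_rep = design$replicates
    )
    tr$species <- species
    tr$context <- context
    tr$partner <- partner
    tr$response <- response
    tr
  })

  wide <- long |>
    tidyr::pivot_wider(names_from = "response", values_from = "value") |>
    dplyr::rename(biomass_g = "biomass", n_mg = "n", p_mg = "p",
                  block_id = "replicate") |>
    dplyr::mutate(individual_id = 1L) |>
    dplyr::select("species", "context", "partner", "block_id", "week",
                  "individual_id", "biomass_g", "n_mg", "p_mg")

  n_tasks <- nrow(tasks)
  wide$delta15n_permil <- NA_real_
  if (isotopes && !is.null(truth$ndfa_true)) {
    wide <- add_isotopes(wide, design, truth,
                         seed = substream(noise$seed, n_tasks + 1),
                         sd_permil = if (noise$cv_or_sd > 0) 0.3 else 0)
  }
  if (exudation) {
    wide <- add_exudation(wide, noise,
                          seed = substream(noise$seed, n_tasks + 2))
  }
  wide$plot_yield_g <- NA_real_
  if (plot_yields) {
    final_weeks <- utils::tail(design$harvest_weeks, 2)
    sel <- wide$week %in% final_weeks
    wide$plot_yield_g[sel] <- wide$biomass_g[sel] *
      plants_per_plot(design, wide$species[sel], wide$context[sel])
  }
  dplyr::arrange(wide, .data$species, .data$context, .data$partner,
                 .data$block_id, .data$week)
}

add_isotopes <- function(wide, design, truth, seed, sd_permil) {
  ndfa <- truth$ndfa_true |>
    dplyr::inner_join(truth$beta_by_week, by = "week") |>
    dplyr::inner_join(truth$ref_delta_by_week, by = "week") |>
    dplyr::mutate(
      delta_legume = .data$delta15n_permil -
        (.data$ndfa_true / 100) * (.data$delta15n_permil - .data$beta_permil)
    )
  iso_weeks <- unique(truth$ndfa_true$week)
  sel_ref <- wide$species != truth$legume & wide$week %in% iso_weeks
  ref_tab <- truth$ref_delta_by_week
  wide$delta15n_permil[sel_ref] <-
    ref_tab$delta15n_permil[match(wide$week[sel_ref], ref_tab$week)]
  sel_leg <- wide$species == truth$legume & wide$week %in% iso_weeks
  div <- wide$context[sel_leg]
  key <- paste(div, wide$week[sel_leg])
  lookup <- stats::setNames(ndfa$delta_legume,
                            paste(ndfa$diversity, ndfa$week))
  wide$delta15n_permil[sel_leg] <- lookup[key]
  if (sd_permil > 0) {
    sel <- !is.na(wide$delta15n_permil)
    wide$delta15n_permil[sel] <- withr::with_seed(
      seed,
      wide$delta15n_permil[sel] + stats::rnorm(sum(sel), sd = sd_permil)
    )
  }
  wide
}

add_exudation <- function(wide, noise, seed) {
  # phenomenological levels: camelina exudes most organic acids, lupin
  # least; root mass scales with shoot biomass (root:shoot ~ 0.15)
  oa_per_g <- c(oat = 3, lupin = 1.5, camelina = 5)
  withr::with_seed(seed, {
    wide$root_dw_g <- pmax(wide$biomass_g * 0.15, 1e-4)
    rate <- oa_per_g[wide$species]
    rate[is.na(rate)] <- 2
    mu <- unname(rate) * wide$root_dw_g
    wide$oa_umol <- apply_noise(mu, noise_spec(noise$model,
                                               max(noise$cv_or_sd, 0),
                                               seed = seed))
  })
  wide
}
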