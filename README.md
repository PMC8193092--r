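# temponiche

Temporal niche analysis of intercropping experiments from weekly
destructive harvests.

Intercropping — growing two or more crops together on the same field —
can outyield monocultures, and one proposed mechanism is *temporal niche
differentiation*: partner species capturing resources at different times.
Testing that idea requires tracking whole trajectories of biomass and
nutrient accumulation over a season, not just final yields. `temponiche`
provides the full analysis chain for such experiments (the motivating
design is a cereal–legume–brassica system: oat, lupin and camelina grown
as isolated single plants, in monocultures and in two-species mixtures,
destructively harvested every week), together with a seeded synthetic
data generator so that every stage can be verified by parameter recovery.

## The model

Cumulative aboveground biomass (g individual⁻¹) or N/P uptake
(mg individual⁻¹) at week *t* after seedling emergence is modelled by a
three-parameter logistic curve,

    NU(t) = NU_max / (1 + exp(r (t_max − t))),

where `NU_max` is the maximum cumulative uptake (asymptote), `r` the
relative uptake rate (week⁻¹) and `t_max` the week of the inflection.
The instantaneous rate is

    dNU/dt = r NU(t) (1 − NU(t)/NU_max),

which peaks at `t_max` with the closed-form maximum

    I_max = r NU_max / 4.

Around this core the package provides:

* **Two-stage nonlinear least squares** per (species × community context
  × response × replicate): a Levenberg–Marquardt fit supplies starting
  values for a bounded Gauss–Newton polish, with heuristic
  initialisation, convergence flags, and mean ± SE aggregation across
  replicates (`fit_logistic()`, `fit_all()`, `summarize_fits()`).
* **Comparative statistics**: Land Equivalent Ratio decomposition
  (`compute_ler()`), integer percent contrasts of accumulation maxima and
  peak rates (`percent_contrast()`, `peak_rate_contrast()`), and temporal
  shifts of peak timing with propagated SEs
  (`temporal_differentiation()`).
* **Biological N₂ fixation** of the legume by ¹⁵N natural abundance:
  %Ndfa = 100 (δ¹⁵N_ref − δ¹⁵N_legume)/(δ¹⁵N_ref − β) with
  reference-plant selection rules (oat when available, otherwise
  camelina, matched by week and diversity level) and a week-specific β
  calibration table (`ndfa()`, `ndfa_timeseries()`).
* **Significance machinery**: one-way ANOVA with Tukey HSD and a
  deterministic compact letter display for context comparisons
  (`compare_contexts()`, `diversity_effect_ndfa()`).
* **A synthetic generator** (`generate_experiment()`,
  `generate_trajectory()`, `generate_isotope_data()`) emulating the full
  design — 18 weekly harvests × 3 replicates, mean-preserving
  multiplicative log-normal noise, legume δ¹⁵N consistent with prescribed
  fixation levels — with all randomness derived from one seed.

## Worked example

Simulate a full season at 10% replicate noise, fit every trajectory and
run the whole analysis:

```r
library(temponiche)
res <- run_pipeline(run_config(seed = 42, noise = noise_spec(cv_or_sd = 0.10)))
res
#> <pipeline_result>
#>   dataset: 540 records, 90 trajectories fitted (90 converged)
#>   LER oat-lupin: 1.11
#>   LER oat-camelina: 1.03
#>   Ndfa diversity effect: significant
```

540 records is the design arithmetic: 10 species–context combinations ×
18 weeks × 3 replicates; 90 fits = 10 combinations × 3 responses × 3
replicates. The fitted summaries recover the generating parameters —
e.g. lupin-in-mixture biomass is estimated as `NU_max` 14.8 ± 0.6 g,
`t_max` 9.6 weeks against a truth of 15.26 g and 9.71 weeks. Both
mixtures show LER > 1 (overyielding) under the default truth, and the
fixation test flags the isolated single lupins as the diversity level
with lower %Ndfa:

```r
res$ndfa_diversity
#> <diversity_effect> significant (ANOVA p = 1.706e-13)
#>   lower than the top level: single
#>   context      mean     n letter
#> 1 mixture      78.3    12 a
#> 2 monoculture  73.8    12 a
#> 3 single       47.5    12 b
```

Published parameter estimates for the three crops are bundled
(`field_estimates()`, `field_partial_ler()`, `field_ndfa()`), so printed
contrasts can be reproduced directly:

```r
peak_rate_contrast(list(r = 1.15, nu_max = 15.26),   # lupin in mixture
                   list(r = 0.92, nu_max = 11.35))   # lupin monoculture
#> [1] 68
```

— lupin's peak biomass accumulation rate is 68% higher when intercropped
with oat than in monoculture.

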