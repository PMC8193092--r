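---
title: "Models and methods for temporal niche analysis of intercrops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for temporal niche analysis of intercrops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temponiche)
```

This vignette documents the statistical models behind `temponiche`, the
numerical choices made in implementing them, what the synthetic data
generator does and does not emulate, and the package's known
limitations.

## The logistic accumulation model

Destructive weekly harvests of an intercropping trial yield, per species
and community context, a cross-sectional time series of cumulative
aboveground biomass (g individual⁻¹) and N and P uptake
(mg individual⁻¹). These trajectories are described by the
three-parameter logistic

$$\mathrm{NU}(t) = \frac{\mathrm{NU}_{max}}{1 + e^{\,r\,(t_{max} - t)}},$$

with asymptote $\mathrm{NU}_{max}$ (maximum cumulative uptake), relative
rate $r$ and inflection week $t_{max}$. Its derivative,
$r\,\mathrm{NU}(1 - \mathrm{NU}/\mathrm{NU}_{max})$, is the
instantaneous uptake rate; it is unimodal with closed-form maximum
$I_{max} = r\,\mathrm{NU}_{max}/4$ attained exactly at $t_{max}$.
Temporal niche differentiation is quantified on this scale: shifts in
$t_{max}$ between contexts (intra-specific) or between partners within a
mixture (inter-specific).

Two conventions worth making explicit:

* **Units of $r$.** $t$ is counted in integer weeks since seedling
  emergence (1-based), and $r$ is treated as week⁻¹ throughout —
  consistent with the magnitudes of the bundled field estimates and the
  weekly harvest axis. `weekly_to_daily()` converts rates for per-day
  reporting.
* **Overflow.** The exponent $r(t_{max}-t)$ is clamped at ±709 before
  exponentiation; beyond that range the curve already equals 0 or
  $\mathrm{NU}_{max}$ to machine precision, so the clamp changes nothing
  numerically while keeping the function total.

## Fitting: two-stage nonlinear least squares

Each (species, context, response, replicate) series is fitted by
unweighted least squares in two stages: a damped Levenberg–Marquardt
minimisation (`minpack.lm::nlsLM`) from heuristic starting values,
followed by a bounded Gauss–Newton polish (`stats::nls`, `"port"`
algorithm) started from the stage-1 optimum. The polish is kept only if
it does not worsen the residual sum of squares; on zero-residual
(noiseless) input `stats::nls` fails by design, in which case the
stage-1 optimum already is the answer. Bounds are
$\mathrm{NU}_{max} > 0$, $r > 0$, $0 < t_{max} < 2\,t_{last}$;
tolerances (1e-8 on the relative offset) and the 1000-iteration cap are
fixed and recorded in the fit object.

Starting values follow a deliberately simple heuristic:
$\mathrm{NU}_{max,0} = 1.05 \times$ the largest observation;
$t_{max,0}$ = the earliest week reaching half the observed maximum;
$r_0$ = the slope of a straight-line fit of
$\mathrm{logit}(y/\mathrm{NU}_{max,0})$ against week over the interior
points (10–90% of the provisional asymptote, where the logit transform
is nearly linear in $t$; the band widens to 2–98% if fewer than two
points fall inside it), floored at 0.05 week⁻¹. The floor and band
matter only for pathological series; on clean sigmoid data the heuristic
lands within a factor ~2 of the truth, well inside both optimisers'
basins of attraction.

Degenerate inputs are refused early with informative errors: fewer than
5 points, fewer than 3 distinct weeks, all-zero or constant series.
Series truncated before the inflection are genuinely non-identifiable
for the asymptote; the fit then either fails to converge or returns an
asymptote SE exceeding the estimate itself, and both outcomes are
surfaced (flag, SEs) rather than masked.

**Replicates.** The default fits each replicate's series separately and
summarises parameters as mean ± sd/√n across converged replicate fits
(n = 3 in the standard design) — the convention of published parameter
tables with per-parameter SEs. A pooled fit across replicates is
available (`fit_all(pooled = TRUE)`) for users who prefer one fit per
trajectory; it changes the SE interpretation, not the point estimates on
balanced clean data.

## Comparative statistics

* **LER.** The Land Equivalent Ratio is the sum over species of partial
  relative yields $Y_i/M_i$ (mixture yield over monoculture yield). The
  pipeline uses plot-level yields from the final two harvest weeks, the
  stage at which grain yield is assessed; the week filter is an
  argument. Partials are computed per replicate against the monoculture
  mean and aggregated as mean ± SE. LER is reported to 2 decimals.
* **Percent contrasts** are integers, rounded half away from zero, of
  $100\,(a/b - 1)$. Peak-rate contrasts apply this to
  $I = \bar r \,\overline{\mathrm{NU}}_{max}/4$ computed from *mean*
  parameters — the ratio-of-means convention, which is the one that
  reproduces published contrast values from parameter-table means. A
  per-replicate-ratio alternative would weight replicates differently;
  it is deliberately not the default.
* **Temporal shifts** are differences of mean $t_{max}$, with the SE of
  the difference propagated as $\sqrt{SE_A^2 + SE_B^2}$ (independent
  errors) and a direction label (earlier/later/none) from a Welch t-test
  on the summary statistics. The label is deliberately conservative: no
  label is assigned when the test does not reject.

## Nitrogen fixation from ¹⁵N natural abundance

The share of legume N derived from the atmosphere is the isotope
dilution estimate

$$\%\mathrm{Ndfa} = 100\,\frac{\delta^{15}N_{ref} - \delta^{15}N_{legume}}
{\delta^{15}N_{ref} - \beta},$$

where the reference $\delta^{15}N_{ref}$ is the mean signature of a
non-fixing plant at the same week and diversity level and $\beta$ is the
legume's signature when growing on atmospheric N₂ alone, supplied as a
per-week calibration table. Choices:

* **Reference selection** follows the cereal-first rule: oat when
  available, otherwise camelina, matched by week × diversity level. For
  the mixture level, the oat growing with the *non-legume* partner is
  used where identifiable — the oat grown with the legume itself is a
  biased reference, since it may access fixed N. The mapping is fixed;
  pooling references across diversity levels is intentionally not
  offered.
* **Out-of-range estimates** (< 0 or > 100%) are returned unchanged and
  flagged, never clamped: out-of-range values are diagnostic of
  calibration problems (wrong β, unsuitable reference) that clamping
  would hide.
* **The diversity-level test** treats weekly means as replicate
  observations (ANOVA + Tukey across levels). This is appropriate when
  fixation shows no systematic trend across weeks — which the package
  checks implicitly through the per-week table — and would overstate
  degrees of freedom if a strong week trend existed.

## Significance letters

Published parameter tables annotate context means with superscript
letters; the underlying test is conventionally one-way ANOVA at
α = 0.05, with Tukey HSD pairwise comparisons gated on the ANOVA
rejecting, and that is what `compare_contexts()` implements (Welch's
ANOVA with Holm-adjusted pairwise Welch t-tests is available for
heteroscedastic groups of n = 3). The compact letter display uses the
insert–absorb construction, with groups ordered by descending mean so
the labelling is deterministic and invariant to input row order. Because
Tukey is gated on the ANOVA, the all-groups-share-one-letter event under
a true null occurs at rate 1 − α by construction; the test suite checks
this type-I property by simulation.

## The synthetic data generator

The generator emulates the *design* of a weekly destructive-harvest
intercropping trial: three species (oat, lupin, camelina), three
diversity levels (isolated single plants, monocultures, and oat–lupin /
oat–camelina mixtures), 18 weekly harvests × 3 replicates, sowing
densities 400/160/592 seeds m⁻² with a substitutive (half-density)
mixture design on 0.25 m² plots. Its defaults are the study conditions:

* **Truth parameters** default to the bundled field estimates
  (`field_estimates()` means), so simulated trajectories have realistic
  magnitudes and the full pipeline's recovery can be judged against a
  published parameter table. The one unresolved entry there
  (camelina-single N) is filled with a plausible synthetic value
  (NU_max 300 mg, r 0.9 week⁻¹, t_max 11.5), chosen to sit between that
  species' community values and the other species' single-plant values.
* **Noise** defaults to multiplicative log-normal with CV 10% and a
  mean-one factor, so the expected value at every week lies exactly on
  the logistic curve and responses are guaranteed positive — the natural
  first model for strictly positive biomass data of this precision. An
  additive Gaussian model (truncated at 0) is provided for sensitivity
  checks; truncation slightly biases its mean near zero, which is the
  price of positivity in that model.
* **Fixation levels** default to 75% (mixture), 72% (monoculture) and
  45% (single) over weeks 5–16, with a constant β of −0.5‰ and reference
  δ¹⁵N of 3.0‰ — magnitudes typical of natural-abundance work with
  lupin, and a single-plant deficit matching the qualitative pattern the
  analysis is meant to detect. Isotope noise is additive on the permil
  scale (SD 0.3‰ in the full generator), since signatures may be
  negative.
* **Seeding.** All randomness flows from one top-level seed through
  documented substreams (`seed + 104729·i mod 2³¹−1` over
  deterministically ordered generation tasks), so a dataset is exactly
  reproducible and adding one optional column group does not reshuffle
  another's draws.

What the generator does **not** emulate: block random effects
(replicates are independent draws around one truth; the field design's
replicate structure is not published at that granularity, and a shared
block effect would only inflate between-replicate SEs), any agronomic
process (weather, soil water, light competition — trajectories are
phenomenological logistic curves), within-plot individual-level
variance components, or measurement error structure specific to
instruments. Passing recovery tests on this generator therefore
demonstrates the *estimator chain* is correct and well calibrated for
logistic-plus-noise data; it does not validate the logistic model
itself against real harvest data.

## Verification scale

The test suite verifies analytic identities on 1,000 random parameter
sets (grid maximum of the rate vs closed form, to 1e-6 relative);
derivative and conservation oracles by finite differences and numerical
integration; noiseless recovery to 1e-6 relative; noisy recovery over
200 seeds × 3 replicates at CV 10% (median relative NU_max error
below 5%, median absolute t_max error below 0.5 weeks); exact
round-trips of the isotope chain (1e-10); and the type-I rate of the
letter display over 500 simulated null datasets. These sizes were chosen
so the full suite runs in well under a minute on a single core while
keeping Monte-Carlo standard errors around 1% for the rate checks.

## Known limitations

* The logistic is the only growth form offered; species with asymmetric
  trajectories (e.g. senescence-driven decline) need a different model
  and are out of scope.
* Unweighted least squares assumes homoscedastic residuals on the
  response scale; with multiplicative noise the estimator remains
  consistent but not efficient. A variance-stabilised or weighted fit is
  a possible extension.
* SEs of derived quantities (peak rates, contrasts) are not propagated
  through the nonlinearity; contrasts are reported as point percentages,
  matching the convention of the field's reporting.
* The Ndfa SE reflects replicate scatter of the legume only; uncertainty
  in the reference mean and in β is not propagated.
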