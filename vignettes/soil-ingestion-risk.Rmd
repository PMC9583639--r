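---
title: "Modelling health risks from accidental ingestion of soil-borne potentially toxic elements"
author: "soilrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling health risks from accidental ingestion of soil-borne potentially toxic elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
library(dplyr)
```

## The problem

People unintentionally swallow small amounts of soil and dust — hand-to-mouth
contact, resuspended particles settling on food, outdoor play. Where surface
soil carries potentially toxic elements (PTEs: here Al, As, Cd, Co, Cr, Cu,
Fe, Mn, Ni, Pb and Zn), this *nondietary ingestion* route is a genuine
chronic exposure pathway, and the standard way to quantify it is the USEPA
dose-equation framework. `soilrisk` implements that framework twice over:

* **deterministically**, turning a point concentration and a receptor
  scenario (age/sex group) into a point risk estimate; and
* **probabilistically**, propagating full distributions of concentration,
  soil ingestion rate and body weight through the same equations by Monte
  Carlo, with a simulation-level bootstrap for the sampling uncertainty of
  the reported summaries.

## The dose and risk model

For a receptor with body weight $BW$ (kg) ingesting $IR$ mg of soil per day
on $EF$ days per year over $ED$ years, soil carrying $C$ mg/kg of an element
delivers the average daily dose

$$\mathrm{ADD} = \frac{C \cdot IR \cdot EF \cdot ED \cdot CF}{BW \cdot AT \cdot 365},$$

in mg/(kg day), where $CF = 10^{-6}$ kg/mg converts ingested milligrams of
soil to kilograms and $AT$ (years) is the averaging time. For chronic
noncancer assessment $AT = ED$ (the dose is averaged over the exposed period
only), so $ED$ cancels and the chronic dose is
$C \cdot IR \cdot EF \cdot CF / (BW \cdot 365)$. The noncancer metric is the
hazard quotient against the element's oral reference dose $RfD$:

$$\mathrm{HQ} = \mathrm{ADD} / RfD,$$

also called the chronic toxic risk (CTR). For carcinogens the same intake is
averaged over the whole lifetime $LT$ (75 yr here), giving the lifetime
average daily dose LADD ($AT \to LT$), and the incremental lifetime
carcinogenic risk is

$$\mathrm{CR} = \mathrm{LADD} \times SF$$

with $SF$ the oral slope factor. Risk zones partition the output scale:
HQ below 0.1 is insignificant, 0.1–1 (upper bound inclusive) warrants
further investigation, above 1 poses risk; CR at or below $10^{-6}$ is safe,
then acceptable up to $10^{-5}$, low-priority up to $10^{-4}$, and
high-priority (unacceptable) at $10^{-4}$ and above. The boundary
assignments follow the printed inequality conventions of the regulatory
taxonomy: the closed ends are `CR <= 1e-6` (safe) and `CR >= 1e-4` (high
priority), so each open interval's lower boundary joins the safer zone.

```{r deterministic}
adult <- exposure_scenario("adult_combined", ir = 20, bw = 80.8)
add <- average_daily_dose(188, adult)   # nationwide mean As, mg/kg
c(add = add, hq = hazard_quotient(add, rfd = 3e-4))
```

### Default parameters and their provenance

* **Toxicity constants** (`default_toxicity()`): RfDs and SFs from IRIS/RAIS.
  Chromium is handled as its two environmental forms: soil Cr is speciated
  80/20 into Cr(III)/Cr(VI) by `speciate_chromium()` (the hexavalent
  fraction is an argument), because the two forms differ in toxicity by
  three orders of magnitude. Lead has no IRIS oral RfD, so only its CR is
  quantified.
* **Adult scenarios** (`default_scenarios()`): IR 20 mg/day, EF 350 day/yr,
  ED = AT = LT = 75 yr, CF $10^{-6}$. The adult body weights (74.7 / 87.7 /
  80.8 kg female/male/combined) are calibrated defaults consistent with
  Exposure Factors Handbook adult means; they reproduce published adult CTR
  benchmarks for Turkish soils to within 1%.
* **Child scenarios**: the handbook's central ingestion rates (30 mg/day
  under 1 yr, 50 mg/day for 1–6 and 6–11 yr) and central body weights. These
  are planning defaults with a provenance note, not calibrated values —
  treat child risks as screening estimates and override the scenarios when
  population-specific factors exist.
* **Year length**: 365 day/yr in the denominator; EF (350/365) already
  absorbs the exposure-day accounting.

The package deliberately does **not** sum hazard quotients across elements
into a hazard index; risks are reported per element form.

## The probabilistic model

Population risk replaces the three point inputs with distributions:

* **Concentration**: fitted to data by `fit_best()`, which estimates each
  candidate family (lognormal, gamma, Weibull by default) by maximum
  likelihood and keeps the family with the smallest Anderson–Darling
  statistic. AD is tail-sensitive, which is the right emphasis when the
  fitted upper tail drives the 95th-percentile risk. Moment matching is the
  documented fallback if an MLE fails to converge (the optimizer's failure
  is silenced and the family simply competes with its moment fit, or drops
  out).
* **Ingestion rate**: lognormal with location 0, median 50 mg/day and 95th
  percentile 200 mg/day, i.e. $\mu = \ln 50$,
  $\sigma = \ln(200/50)/z_{0.95} = 0.8428$. "Central tendency" is read as
  the lognormal *median*: a mean-50/P95-200 lognormal has no real solution,
  and the median interpretation is the one under which the stated pair is
  self-consistent. Both anchor points and the percentile are arguments.
* **Body weight**: the published Turkish scaled-beta distribution
  $BW = 111.15 \cdot B$, $B \sim \mathrm{Beta}(12.76, 8.15)$ (analytic mean
  67.8 kg), sampled by `body_weight_distribution()`.

`simulate_risk()` draws the three inputs independently per trial (the
source model implies no correlation structure; 10,000 trials by default,
EF 350, ED 75 yr, AT 27,375 days, LT 75 yr fixed), pushes them through the
equations above and summarises the trial vector (mean, median, quartiles,
95th-percentile "upper bound", maximum, CV). Draws outside a distribution's
support or non-finite draws are re-drawn up to a bounded retry count and
never silently imputed; exceeding the bound is a hard error, so a trial
vector is never shortened. The `point` distribution family collapses the
whole apparatus onto the deterministic equations, which the tests use as an
exact oracle.

```{r mc}
conc <- fitted_dist("lognormal", c(meanlog = log(188), sdlog = 1.0))
spec <- simulation_spec(conc, "As", n_trials = 10000, seed = 1)
sim <- simulate_risk(spec, "ctr")
glance(sim)
upper_bound(sim)
```

### Bootstrap of the simulation

`bootstrap_uncertainty()` quantifies how much the reported summaries move
because of the random sampling itself: it re-runs the whole simulation
(default 200 repetitions of 1,000 trials, the convention for this design)
on independent seed substreams spawned from one master seed, and reports
the standard error of the trial mean and the interquartile range of the
trial median across repetitions. Re-running — rather than resampling one
trial vector — is the interpretation consistent with "repeating the
simulation", and it is what the substream seeding makes cheap and exactly
reproducible.

## Site-category comparisons

Concentrations (hence exposures) are compared across urban, suburban,
industrial and agricultural sites with the two-sided Mann–Whitney U test at
$\alpha = 0.05$ (`mann_whitney()`, `compare_site_categories()`); rural and
uncategorized groups are excluded as chronically undersized, and any
included category with fewer than 3 records is skipped with a recorded
reason. The implementation uses the exact null distribution for
$n_a n_b \le 400$ tie-free data and the tie-corrected normal approximation
otherwise; midranks handle ties. Because the dose equation is strictly
increasing in concentration, rank-based decisions are identical for
concentrations, exposures, CTR and CR — asserted in the tests, so one
comparison serves all four scales. No multiplicity correction is applied
across the six pairs, matching the per-pair reporting convention of the
underlying design; direction is reported post hoc from rank sums.

## The synthetic data generator

Real compiled concentration datasets are assembled from dozens of surveys
and are not redistributable, so `generate_concentrations()` produces
datasets with the *statistical structure* the analysis assumes: per
(element, site category) lognormal concentrations specified by median and
geometric SD, plus a multiplicative hotspot mechanism for industrial sites
(a fraction of draws, default 10%, is multiplied by a factor, default 5)
mimicking extreme measurements near organised industrial zones.
`default_turkey_like_spec()` keys the urban and industrial medians to
published nationwide means for Turkish surface soil, scales suburban (0.9),
agricultural (0.7) and rural (0.5) medians from urban (rural As pinned to
its published 2.5 mg/kg), and chooses geometric SDs so the implied CVs sit
inside the published 0.83–3.85 envelope. Reusing published *means* as
synthetic *medians* is a fixture convention, not a claim about the real
data: it keeps magnitudes realistic while the lognormal right tail pushes
synthetic means above the anchors.

What the generator does **not** emulate: spatial autocorrelation within
provinces, between-study analytical biases, censoring at detection limits,
and element-element correlations. Tests passing on synthetic data therefore
validate the *machinery* — equations, fitting, simulation, testing — not
any claim about real Turkish soils.

```{r synth}
recs <- generate_concentrations(default_turkey_like_spec(n_per_group = 30))
summarize_concentrations(recs, "element") |> head(4)
compare_site_categories(recs, "As") |>
  select(group_a, group_b, p_value, reject, direction) |> head(3)
```

## Numerical conventions and edge cases

* Percentiles everywhere are linear-interpolation order statistics (R
  `quantile` type 7), fixed so summaries are bit-stable across runs.
* CV uses the sample (n−1) standard deviation; a single observation
  reports CV 0, a zero mean reports CV `NA`.
* `fit_best()` requires at least 10 observations, refuses constant data,
  and excludes positive-support families (with a warning) when the data
  contain non-positive values.
* Zone classification is total on $[0,\infty)$ and monotone; boundary ties
  follow the printed inequality directions noted above.
* All stochastic entry points (`generate_concentrations()`,
  `simulate_risk()`, `bootstrap_uncertainty()`) take explicit seeds and
  restore the caller's RNG state (`withr`); identical inputs give identical
  output to the bit.
* The normality battery pairs Anderson–Darling with the
  Lilliefors-corrected Kolmogorov–Smirnov test, since the normal parameters
  are estimated from the sample.

Problem sizes used in the shipped tests — $10^5$ draws for the
ingestion-rate round-trip, $10^6$ for the body-weight mean, 5,000
observations for parameter recovery, 10,000 Monte Carlo trials, 200
bootstrap repetitions, 2,000 null simulations for the rank test's size —
are the package's chosen verification sizes: large enough that Monte Carlo
error is far inside each tolerance.

## Known limitations

* Ingestion is the only route: dermal contact, inhalation and dietary
  pathways are out of scope, as are bioaccessibility adjustments and
  blood-lead (IEUBK-style) modelling, so absolute risks are
  route-specific, not aggregate.
* The probabilistic model uses one population body-weight distribution;
  child-age variability enters only through the deterministic scenarios.
* Hazard quotients are not aggregated across elements.
* The Monte Carlo assumes independent inputs; a correlation structure, if
  ever needed, belongs in the sampling step of `simulate_risk()`.
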