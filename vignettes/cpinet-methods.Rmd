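---
title: "Methods: contact metrics, synthetic facility and risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact metrics, synthetic facility and risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpinet)
```

## The measurement model

Wearable proximity sensors in hospital studies emit one packet per
detected close-proximity interaction (CPI) every 30 seconds; a packet
carries a timestamp and the two anonymous identifiers. `cpinet` treats
the packet as the atomic observation and derives everything else from
it:

* **contact episode** — a maximal run of packets for one pair whose
  spacing never exceeds a tolerance (default 60 s, so one missed packet
  does not split an episode). The raw studies never define an episode;
  the daily statistics below only need packet counts and partner sets,
  so this choice affects episode-level outputs only. Episodes are split
  at midnight so that daily aggregation stays exact.
* **daily distinct contacts** (person-day) — the number of different
  individuals someone met over a calendar day. Present days with no
  packets are explicit zero rows and count as zeros in averages; this
  is a deliberate choice (a present-but-isolated day is information,
  not missingness) and is the main way in which averages here can sit
  below figures computed on contact-active days only.
* **daily cumulative duration** (pair-day) — 30 s times the number of
  packets a pair exchanged that day. Each packet represents one full
  detection window.

Mirrored packets (both sensors reporting the same interval) collapse to
one record; a packet reported by a single sensor is kept — one report
suffices. Off-grid timestamps are floored to the 30-s grid and logged
rather than rejected.

Category-level summaries follow the conventions of the figure they
feed: distinct-contact frequency averages over **person-days**,
pair-duration averages over **pair-days**. A switch
(`grouping = "individual"`) averages within individuals first, for
sensitivity. Confidence intervals are Student-t on the averaged units.
Mixing matrices are ward-conditioned: rows are the categories
administratively attached to a ward, columns the categories
hospital-wide, and a cell is the mean over the row group's person-days
(contact matrix) or the mean over the relevant pair-days in minutes
(duration matrix). Cells with no supporting pair-days are missing, not
zero. Whether the original figures pooled person-days or individuals is
not documented; person-day pooling is the default here because it
matches the person-day units of the risk models.

Hourly profiles count raw packets per `[h:00, h+1:00)` bin — "hourly
frequency" means recorded packets, not episodes — with a flag to count
distinct pairs instead. Quantiles are linear-interpolation (type 7).
The cyclic profile smoother is a Gaussian kernel on the circle of
hours; it is a generic replacement for the penalized regression
smoother sometimes drawn over such profiles, which is out of scope
because its family and penalty are not specified in the source
material.

## The synthetic facility

Real hospital sensor streams are rarely deposited, so the package ships
a generator whose defaults describe one fixed world: a five-ward
long-term-care facility with 136 patients and ~174 staff present on any
day, mean patient stay 49 days (seven weeks), a morning-peaked
circadian initiation profile rising from 5 to 11 a.m., reduced weekend
initiation but a 1.6x weekend duration boost (weekend contacts are
fewer and longer), and a two-day battery-change gap mid-horizon.

Contacts arise per co-present pair as an inhomogeneous Poisson process:

```
intensity(hour) = pair_rate[cat_a, cat_b] x circadian(hour)
                  x dow(day) x ward_factor x planted modifiers
```

with `ward_factor = 6` within a ward, `0.15` across wards and `1` for
pairs involving transversal staff (who roam the whole facility). The
within/across ratio is a free parameter — field studies show cross-ward
mixing exists but publish no rates — and is documented as such.
Episode lengths are geometric on the 30-s grid (memoryless, matching
the heavy short-contact tail of sensor data), with category-pair means.

The default `pair_rate` matrix was calibrated once, analytically,
against the published category means of daily distinct contacts
(porter ≈ 25 > physician ≈ 21 > HCW ≈ 14 > patient ≈ 11) using the
identity: expected distinct partners = Σ over partner groups of
`n_partners x (1 - exp(-24 x rate x ward_factor))`. Duration means put
patient–patient contact far above HCW–patient contact (50 vs 10
packets), reproducing the long patient–patient contacts specific to
long-term care. The generator reproduces orderings and rough
magnitudes, **not** the published point values: a green ordering test
establishes that the pipeline recovers the structure a calibrated
world plants, nothing about any real hospital. Features of real data
deliberately not emulated: sensor dropout other than whole-day gaps,
visitor contacts, intra-day patient movement, and any geometry of the
building.

Patient turnover uses a bed model: each census slot holds a succession
of patients with i.i.d. exponential stays; by memorylessness the first
occupant's remaining stay is exponential too, so the daily census is
stationary and exactly equals the configured census. Ward-linked
covariates default to: neurologic wards draw mostly `neurology`
reasons, the nutrition ward `nutrition`, the geriatric ward
`geriatric`, with a surgical remainder.

All randomness flows from one seed; roster and contact generation use
derived substreams so each stage is individually reproducible, and the
same seed yields byte-identical output.

## Dichotomization and the mixed model

Risk analyses run on person-days (the published sample sizes are
person-day counts), separately for staff and patients. Outcomes are
dichotomized at `mean + k * sd` of the population's person-day
distribution — `k = 1` for the main analysis, `k ∈ {0, 2, 3}` as
sensitivity — using the **sample** standard deviation (the estimator is
not documented in the source; sample sd is the R default and the
difference is negligible at thousands of person-days). Values equal to
the threshold classify as low (strict `>`): a tie rule must be fixed
and this one keeps "high" a strict exceedance. Administration and
animation staff and patients in a persistent vegetative state are
excluded at the roster-filter level; zero-record present days are
included (a day off with the sensor on is a real low day).

The model is a logistic GLMM with one ward-level random intercept,

$$\mathrm{logit}\, P(\text{high}_{ij}) = x_{ij}'\beta + u_{w(i)},
  \quad u_w \sim N(0, \sigma_w^2),$$

fitted by Laplace-approximated maximum likelihood (`lme4::glmer`).
Per-level inference is Wald on the log-odds scale (`OR = exp(est)`,
CI `exp(est ± 1.96 SE)`, stars at 0.05/0.01/0.001); per-factor
inference is a likelihood-ratio test against the model without the
factor, `df = levels - 1`. Complete separation is detected as
`|log-OR| > 15` and reported as separation rather than as a numeric
odds ratio — published tables from sparse strata exhibit exactly this
(an OR printed as 0.00 with an astronomically wide CI). No
multiple-testing correction is applied, matching the source procedure.

`simulate_glmm_table()` draws tables directly from this model class
and backs the recovery experiments: with a planted OR of 3 at n = 5,000
person-days across 5 wards, the Wald CI covers truth in ≥ 90% of 100
replicates, and the LRT on an effect-free factor rejects at close to
the nominal 5%.

## Numerical choices and degenerate inputs

* Timestamps are integer local-clock seconds since a study epoch;
  calendar day = `origin + t %/% 86400`. No time-zone arithmetic is
  performed.
* Percent shares are rounded half-up to 2 decimals; durations are
  reported in minutes (1 decimal in displays).
* A single-unit category yields an NA confidence interval (flagged, not
  dropped); a zero-variance outcome warns and thresholds at the mean;
  an all-zero or all-one outcome returns a flagged degenerate result
  without fitting.
* Gap intervals remove whole calendar dates everywhere (packets,
  person-days, profiles); the temporal profiles additionally accept a
  list of ISO weeks to exclude, mirroring the practice of dropping the
  entire battery-change weeks.
* Whether hourly distributions should pool all weeks or average within
  weeks first is not documented; pooling is used.

## Known limitations

* The generator's cross-ward and staff-staff rates are weakly
  identified by published material and are free parameters.
* Episode-level outputs depend on the 60-s tolerance; daily statistics
  do not.
* The GLMM uses a single random intercept; random slopes, interactions
  and model selection are deliberately out of scope.
* `lme4`'s Laplace approximation can understate random-intercept
  variance with few clusters (5 wards); the recovery tests quantify the
  practical effect on fixed-effect coverage.
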