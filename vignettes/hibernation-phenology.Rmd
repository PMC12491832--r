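---
title: "Extracting and modelling bat hibernation phenology from RFID gate logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and modelling bat hibernation phenology from RFID gate logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batphen)
```

## The problem

A hibernaculum entrance fitted with RFID readers records every passage of a
PIT-tagged bat. From such a stream, `batphen` reconstructs, for every
individual and winter, when hibernation started, when it ended and how long
it lasted, and then asks how those dates shift across years and with
temperature in each species, sex and age class. This vignette is the
package's own account of the method: the definitions, the model, the
generator used to test it, and the places where a design decision had to be
made.

## Calendar conventions and pass building

Two conventions keep winters intact. A **bat day** runs from noon to noon;
the half-open rule is `[12:00, next 12:00)`, so a timestamp at exactly noon
belongs to the starting day. This makes a single night's activity fall on
one date regardless of whether it happens before or after midnight. A
**bat year** runs from 1 July to 30 June and is labelled by the calendar
year of its 1 July, so an entire winter sits inside one analysis year.

Raw hits become **passes** in two steps. Same-reader hits of one tag within
`burst_window` seconds (default 5 s) are collapsed to the earliest hit of
the burst — a bat crawling slowly through the gate can re-trigger one
antenna repeatedly. Then, within one tag and entrance, an inner and an outer
hit within `pairing_window` seconds (default 60 s) form one directed pass:
outer→inner is an entry, inner→outer an exit. Pairing is greedy
left-to-right in time; this is deterministic and adequate at realistic
traffic levels, though it is not a globally optimal matching — two bats'
worth of interleaved hits at the same entrance within the same minute could
in principle be mis-paired (the tag identity prevents cross-tag pairing, so
only re-triggers of the same tag are at stake). Both windows are tunable;
the defaults reflect that a 20 cm crawl between readers takes seconds, not
minutes. Leftover hits, and all single-reader (`"only"`) data, become passes
of unknown direction. Every hit is consumed by exactly one pass, an
invariant the tests enforce.

## The hibernation definition

For one individual and one bat year, candidate gaps are the intervals
between *consecutive* passes. A gap is eligible if its opening pass falls on
a bat day between 1 July and 1 February and its closing pass between
31 December and 30 April. The hibernation record is the eligible gap of
maximal duration. Numerical choices made here, all deliberate:

* **Window bounds are inclusive on both ends.** "Between" is read laxly and
  applied uniformly.
* **Gap endpoints are the bat days of the bounding passes themselves**, not
  shifted by a day: the hibernation bout is delimited by recorded activity.
* **Ties go to the earliest start.** Equal-length eligible gaps are rare but
  must resolve deterministically.
* **Dual-reader mode discards rather than re-searches.** If the selected
  longest gap does not open with a confirmed entry and close with a
  confirmed exit, the record is dropped; no fallback to the next-longest
  gap. Falling back would bias records toward intervals bounded by whatever
  happened to be well-recorded.
* **Durations use true calendar arithmetic** (leap years included); a
  zero-length gap (two passes on one bat day) is never a record.
* Fewer than two passes, or no eligible gap, yields no record — bats never
  re-detected after tagging simply contribute nothing.

Records are joined with capture data (species, sex, age at tagging);
juveniles count as adults from their second bat year onwards. Start and end
dates are also encoded as integer day indices from 1 July of the bat year,
the response scale of the models. Known monitoring outages are handled by an
exclusion list that masks start, end or duration per species and bat year;
masking start or end also masks duration, and masking is idempotent. No
outlier filtering is applied beyond the exclusion list: mid-winter arousals
or a missed true entry can produce genuinely odd records, and removing them
by eye would introduce subjective bias.

## Validation procedures

Two checks probe whether the extraction is trustworthy. First,
`single_reader_reanalysis()` re-runs the extraction as if only one reader
existed (default: the inner one) and `end_date_concordance()` reports the
per-species fraction of (tag, bat year) records whose end dates agree
exactly between the two modes. Second, `final_departure()` finds the first
confirmed exit after the record's end date that is not followed by an entry
within 24 hours — the 24 h look-ahead uses exact timestamps, not calendar
days, because "within 24 h" is an interval statement — and
`departure_within()` reports the fraction of departures falling strictly
less than 7 bat days after the end date ("less than one week" read
literally).

## The mixed models

For response $y_{it}$ (start or end day index, or duration in days) of
individual $i$ in bat year $t$, fitted separately per species:

$$y_{it} = \beta_0 + \beta_1 t + \gamma_{c} + \delta_{c} t + u_i +
\varepsilon_{it}, \qquad u_i \sim N(0, \sigma_u^2)$$

with $c$ the sex-age class of bat $i$ in year $t$. The year covariate is
centred at the first bat year for numerical stability (slopes are
unaffected). The per-class marginal slope $\beta_1 + \delta_c$ is computed
as a finite difference of fixed-effect design rows (response at year $t+1$
minus at $t$ for that class), which makes the estimates invariant to the
contrast coding of the class factor — reordering factor levels, or fitting
under sum contrasts, changes nothing, and the tests verify agreement with
`emmeans::emtrends` as an independent route. The **overall** slope is the
unweighted mean of the four class slopes; its standard error uses the full
fixed-effect covariance. An unweighted mean was chosen over a
sample-size-weighted one because the overall row is meant as an
equal-footing summary of the class responses, not of the tagged sample
composition.

Temperature models replace the year covariate by the median air temperature
of a species-specific two-month window — August–September (start) and
February–March (end) for *M. daubentonii*, November–December and
January–February for *M. nattereri* — with a random intercept per bat year
instead of per individual. Each window month is resolved to the calendar
year it occupies within the bat year (July–December in the labelling year,
January–June in the following one). The median over all hourly samples is
used rather than the mean to damp short extreme spells;
`temperature_collinearity()` reports how strongly the window median tracks
the extremes of the daily means, the standard justification for keeping a
single parsimonious temperature summary. A model facing fewer than three
distinct window temperatures refuses to fit.

Estimation is by REML via `lme4::lmer`; p-values use the Wald normal
approximation. When the mixed fit is singular or fails, the model drops to
the corresponding fixed-effects `lm` with a warning and a flag on the
returned object. This fallback is not an edge case to be ashamed of: on
noise-free synthetic data the residual variance is zero, and for the
duration response the shared individual intercept cancels out of
$\text{end} - \text{start}$ exactly, so the individual variance component is
genuinely zero there under the generator. The point estimates of the
marginal slopes are what matter in those settings, and the fallback
preserves them exactly.

## What the generator emulates — and what it does not

`sim_config()` describes a 13-bat-year, two-species study with up to 150
newly tagged bats per species per year, roughly six months of hibernation
for *M. daubentonii* and three for *M. nattereri*. Its moving parts:

* **Class schedules.** Baseline entry/end days (days since 1 July) per
  species × sex-age class, linear year trends (days/year) and a temperature
  sensitivity of entry (days/°C) acting through the deviation of the
  species' entry-window median from its long-run mean. Default trend and
  temperature-effect magnitudes are of the order reported for this study
  system (adult males the most responsive class). The deviation coupling
  means the configured days/°C is directly recoverable by the temperature
  model.
* **Individual heterogeneity.** A per-bat intercept $N(0, 5\,\text{d})$
  entering both entry and end, plus an independent residual
  $N(0, 5\,\text{d})$ per individual-year. These spreads are stated
  assumptions — within-class phenological variance is not something the
  study system pins down — chosen so that class means are estimable but
  individual records are visibly noisy.
* **Demography.** Annual survival 0.8 as a per-year Bernoulli; dead bats
  emit nothing. This creates the unbalanced, cohort-stacked panels real
  monitoring produces. Juveniles (half of each tagged cohort) become adults
  after their first bat year.
* **Behavioural clutter.** Poisson(2) autumn swarming visit nights in the 30
  nights before entry, each an entry/exit pair within one night, and a 5%
  per-winter chance of one brief mid-winter exit/re-entry. Crossing times
  are drawn within the night (18:00–06:00), bats being nocturnal, so a
  crossing's bat day equals its scheduled date by construction.
* **Observation failure.** Each reader hit survives with probability
  `p_detect` (default 0.98) independently; outage windows delete all hits
  inside them.
* **Weather.** Hourly temperature = annual mean 10 °C + seasonal sinusoid
  (amplitude 8 °C, peak mid-July) + warming trend (0.05 °C/year) + a
  per-calendar-year anomaly (sd 0.8 °C) + hourly noise (sd 3 °C). The
  anomaly term exists because i.i.d. hourly noise alone would leave
  two-month window medians essentially identical across years (the median
  of ~1450 samples has negligible sampling spread), making any temperature
  effect unidentifiable; real yearly mean anomalies are of order 1 °C.
* **Determinism.** Every stage derives its own RNG stream from the single
  config seed; identical configs give byte-identical outputs.

Schedules violating entry < exit after noise are redrawn up to ten times,
then clamped to entry = exit − 1 with a message; endpoints are clamped into
the eligibility windows the extractor searches. Under the default noise
levels clamping is rare (a handful of schedules per ten thousand).

What the generator does **not** emulate: multi-hibernaculum movement,
within-winter torpor-bout structure, body-mass dynamics, non-stationary
swarming behaviour, correlated detection failure (e.g. a failing reader
degrading over weeks), or weather realism beyond
sinusoid + trend + anomaly + noise. Tests passing on this generator
therefore show that the pipeline recovers truth *under its stated
assumptions*; they do not show that real detection streams satisfy those
assumptions.

## Parameter-recovery design

Two recovery experiments back the estimators, run at study scale (13 bat
years × 150 new tags/species/year, about 4–5 thousand records per species).
They deliberately use *separated* configurations:

* Year-trend recovery configures the published-style class trends with the
  temperature effect and warming set to zero.
* Temperature-effect recovery configures −9.25 days/°C on entry with year
  trends and warming set to zero.

The reason is a property of the data-generating model, not of the
estimator: with both a warming trend and a temperature sensitivity active,
part of the temperature-mediated shift is linear in year, so neither the
configured trend nor the configured days/°C alone is the estimand of the
corresponding model. (The README's worked example shows exactly this: under
the full default conditions the fitted year slope exceeds the configured
trend by the warming × sensitivity product.) Separating the mechanisms makes
each configured parameter the true marginal effect its model estimates.
Zero-effect null configurations accompany both experiments. The test suite
runs 20 seeds for the year-trend experiment and 10 per temperature
experiment; the detection-degradation experiment (record counts and
concordance against `p_detect` ∈ {1, 0.95, 0.9, 0.8}) uses 20 paired seeds
at 4 bat years × 25 tags/species/year. These sizes are the package's chosen
compromise between Monte Carlo error and a test suite that stays pleasant
to run.

One scale note: the recovery experiments fit on phenology tables built
directly from the simulator's ground truth. The end-to-end identity — that
the detections→passes→extraction route reproduces the truth table exactly
under clean settings — is established separately, so routing forty
study-scale simulations through detection rendering would re-test that
identity at great cost without sharpening the estimator check.

## Known limitations

* Greedy pass pairing can mis-pair hits when one tag re-triggers both
  readers in odd orders within the pairing window; the burst collapse
  absorbs the common cases.
* The longest-gap search considers only passes within the focal bat year,
  so a hibernation bout opened by a pass in late June would be anchored to
  the following 1 July boundary rather than that pass.
* With heavy detection failure the single-reader reanalysis and dual-mode
  extraction degrade differently (dual discards, single silently bridges
  missed passes); concordance between them is a diagnostic, not a ground
  truth.
* The temperature models use one covariate value per bat year; they cannot
  separate within-season timing cues from between-year climate, and with
  13 year-level values their effective sample size for the temperature
  slope is 13, however many bats are tagged.
* p-values are asymptotic Wald; for responses with few effective year
  levels they are anti-conservative relative to degree-of-freedom-corrected
  alternatives.
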