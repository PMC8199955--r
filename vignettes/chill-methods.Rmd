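---
title: "Models and methods behind chillsuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chillsuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillsuit)
```

`chillsuit` implements an end-to-end agroclimatic advisory chain for stone
fruit: station-record quality control, winter-chill accounting under three
models, climate zoning, frost risk, and varietal suitability. This vignette
records the models, the assumptions behind them, and the design choices made
where the underlying methodology is conventionally under-specified.

## The dormancy problem

Deciduous fruit trees pass through endodormancy, broken by accumulated
winter cold, and then ecodormancy, broken by accumulated warmth. Only the
first stage is modelled here. A variety planted where winters no longer
supply its chilling requirement flowers poorly and erratically; a low-chill
variety planted in a traditionally cold area flowers early, into the frost
season. Both failure modes are driven by hourly temperature, which is why
every computation in the package runs on hourly mean temperature series in
local standard time (daylight-saving shifts would fabricate duplicate or
missing hours in the thermal day, so timestamps are treated as DST-free).

## Chill models

All three models consume an `hourly_series` in which each clock hour covers
the half-open interval [h, h+1) and carries a coverage fraction; hours below
the minimum coverage (default 0.8, i.e. at least 5 of 6 ten-minute or 2 of 2
half-hour slots) are gap-masked. Masked hours contribute no chill, are
counted as missing, and are never interpolated by the models themselves.

* **Chilling Hours** counts hours with temperature in the closed band
  0–7 °C. The band endpoints are inclusive — a boundary reading is a chill
  hour — and the common 7.2 °C variant is available through
  `chill_params(ch_bounds = )`.
* **Utah Cold Units** applies the standard Richardson weight table
  (full chill +1 CU/h at 2.5–9.1 °C, half-weights on the shoulders, −0.5
  at 16–18 °C and −1 above 18 °C). The weights partition the real line, so
  every temperature maps to exactly one weight; the cumulative may decrease
  under warm spells. The table is configurable, but the default reproduces
  the published 2.5–12.5 °C effective band.
* **Dynamic (Chill Portions)** runs the two-step kinetic recursion with the
  standard published constants (slp 1.6, tetmlt 277 K, a0 1.395e5, e0
  4153.5, a1 2.567e18, e1 12888.8), converting temperatures to kelvin. An
  intermediate product relaxes each hour towards a temperature-dependent
  equilibrium; on reaching the critical level 1 a temperature-dependent
  fraction is banked irreversibly as Portions, so the cumulative is
  non-decreasing by construction. The recursion state (intermediate level
  plus the previous conversion fraction) is exposed so a split series
  resumed from saved state is bit-exact — this is tested, as is agreement
  to 1e-9 with a literal hour-by-hour transcription of the recursion kept
  independent of the package implementation. Masked hours hold the state:
  no accumulation, no decay. An alternative (short-gap interpolation) was
  considered and rejected as a model-level concern; gap handling belongs to
  QC and resampling.

## Season accounting

**Start of count.** The methodology the package follows names Richardson's
method for the start of chill counting but leaves it unspecified; the
classical reading implemented here is the *cumulative-minimum reset rule*:
run the Utah cumulative from 1 September and start counting the day after
the running cumulative attains its minimum within the September–December
search window (ties resolved to the last minimum, i.e. the last day from
which accumulation is net-positive onward). A series whose cumulative never
dips below its initial level starts at 1 September. Start dates estimated
from windows with more than 20 % masked hours are flagged low-confidence.

**Weekly tables and end of count.** Utah and Portion increments are
aggregated by ISO-8601 week, which makes the season sequence run ~week 36
through 52 and wrap to weeks 1–26 — matching the field convention of
quoting end-of-count weeks like "week 5" or "week 10" after New Year. The
Utah count ends at the first week followed by at least three consecutive
weeks of non-positive weekly sums ("negative or null" is read as applying
to weekly sums, not cumulative values, since a cumulative reading would
almost never terminate); the Dynamic count ends at the last week with a
positive weekly Portion sum. A season with no qualifying terminator returns
the last week with a warning rather than failing.

**Interannual statistics.** Start dates are summarised on day-of-season
integers (days since 1 September); the mode ties break to the earliest
day. Stations whose earliest–latest range exceeds 50 days or whose standard
deviation exceeds 15 days are flagged suspect — flagged, not excluded,
because the methodology asks for them to be *checked*.

The nominal dormancy span is often quoted as "six months until June"; the
package analyses the full start-date → 30 June window and treats the six
months as nominal, since an October start through June is longer than six
months however counted.

## Quality control

The six-level cascade follows the UNE 500540-style real-time validation
sequence. Design points where the standard gives structure but not numbers:

* All limit intervals are **closed**: a value exactly at a bound is valid.
* Default physical limits: temperature −30…50 °C, humidity 0…100 %, wind
  0…60 m/s, precipitation 0…100 mm/interval. Only the humidity ceiling is
  externally prescribed; the rest are conventional Mediterranean station
  ranges, all configurable. Instrumental limits default slightly wider, so
  the rigid limit (their intersection) is physical by default.
* Level 2 (temporal coherence) compares only records one native interval
  apart — a gap suppresses the comparison — and flags *both* members of an
  excessive step as suspect (4 °C/10 min for temperature, 20 %/10 min for
  humidity by default).
* Level 4 implements the low-variance (stuck sensor) test literally: over
  non-overlapping 24 h windows, standard deviation below 0.05 °C or range
  below 0.5 °C makes the whole window suspect. The excessive-variance
  converse is not part of the described cascade and is deliberately
  omitted.
* Level 5 estimates each observation by inverse-distance-squared weighting
  of simultaneous neighbour values (at least 2 neighbours required;
  residual threshold 5 °C). The estimator is a free choice — the source
  only requires *some* estimate from correlated stations — and IDW is the
  simplest defensible one.
* Level 6 (visual inspection) is represented as an exported review report
  of suspect records; by construction it can never invalidate data.

Consolidation: any invalid flag ⇒ invalid, else any suspect ⇒ suspect.
Invalid temperatures are excluded from all downstream indicators; suspect
ones are used but counted. Re-running the cascade on its own output changes
nothing (idempotence is tested).

## Climate zones

Stations are classified A (extremely cold) through E (extremely warm),
mapping to Continental (A, B), Littoral (C, D) and Semi-Arid (E)
Mediterranean types. The verbal classification rule — five or more months
below 10 °C for A/B, exactly three (Dec–Feb) for C, none for D/E — was
formulated from Spain-wide climatologies whose zone means run several
degrees warmer than the Murcia station means that parameterise this
package's synthetic zones. Applied alone to Murcia-like profiles, the
month-count rule misclassifies: an 11.2 °C station with a realistic 8 °C
annual half-amplitude has about five sub-10 °C months, not three.

`classify_zone` therefore applies the month-count rule first and validates
the outcome against annual-mean temperature bands (A < 8.5 ≤ B < 10.2 ≤
C < 12.1 ≤ D < 14 ≤ E, config-exposed); when the rule's class and the band
disagree, the band wins and the result is flagged ambiguous. The A/B
boundary of 8.5 °C sits between the extrapolated zone-A mean (7.5 °C) and
the observed zone-B mean (9.12 °C) — a nominal 10 °C boundary would
contradict the observed zone-B exemplar. B/C and C/D are midpoints of the
observed zone means; D/E uses the conventional 14 °C. Precipitation
patterns (months under 10 mm) are advisory only, because the two printed
descriptions of them conflict. The Gaussen criterion (dry when monthly
precipitation in mm < 2 × mean temperature in °C) drives the ombrothermal
table.

## Extreme events and frost risk

Events are maximal runs — never counted as overlapping sub-windows — of
hours satisfying a threshold-duration rule: frost at T ≤ −0.5 °C for ≥ 3 h
("is −0.5 °C" is read as at-or-below, the only physically coherent
direction); abnormal warmth above 21 °C for ≥ 6 h or above 23 °C for ≥ 3 h;
flowering-phase anomalies above 25 °C for ≥ 3 h in February–March. Masked
hours terminate runs (gaps are never bridged). The warm-anomaly rules are
restricted to the October–March dormancy window by default, with a switch
for year-round scanning, since the source leaves their scope open.

Annual probability is per-year-with-event (the Bernoulli-trial reading that
the binomial risk model requires), not per event count. Trends combine a
least-squares slope (per decade) with the Mann–Kendall test, implemented as
Kendall's tau of counts against year. Haan frost risk takes p = empirical
probability that the sensitive-period minimum reaches T~c~ = −3 °C in a
year and reports the Binomial(n, p) distribution of damage years over a
planning horizon. The sensitive periods per earliness group (I: 1 Feb–15
Mar, II: 20 Feb–5 Apr, III: 10 Mar–20 Apr) are package defaults chosen to
span early-to-late bloom in a Mediterranean spring; no published dates
exist, and they are config-overridable.

## Recommendation

The packaged requirements table quantifies the accumulated cold base per
varietal group in Utah Cold Units (the weekly "UF" metric of the source
system); a configuration switch allows Portion-based requirement tables.
The "heat start" column is preserved and reported verbatim but is not a
suitability criterion — its units are never defined and no heat model is
specified. A site's *safe chill* is the 20th percentile (R type-7
quantile) of seasonal Utah totals, i.e. the chill met or exceeded in
roughly 80 % of observed years; interannual variability otherwise never
enters the advice. Chill classes map to frost earliness groups as Very
Low/Low → I, Medium/Medium-High → II, High → III (low-chill varieties
flower earliest). The suitability rule is a hard conjunction — chill margin
≥ 0 and frost probability ≤ threshold — so no recommended group can ever
exceed the site's safe chill, and the suitable set is monotone in both safe
chill and the frost threshold; both properties are enforced by tests over
randomised profiles.

## The synthetic weather generator

The generator states a world rather than tuning one: per-zone annual means
and precipitation follow the observed zone averages (B 9.12 °C/185 mm,
C 11.21/165, D 13.02/170, E 14.59/155; A extrapolated to 7.5 °C/200 mm);
the annual cycle has half-amplitude 8 °C with its minimum on 15 January,
the diurnal cycle 5 °C peaking at 14:00, and residuals are AR(1) with
autocorrelation 0.8 and stationary SD 1.5 °C — values chosen once so that
cold-zone winters chill effectively and warm-zone winters marginally.
Daily precipitation uses seasonally weighted gamma draws whose expectation
matches the annual total, with the classic dry Mediterranean summer. All
draws derive from the configured seed; per-station seeds in a network are
drawn from the master seed, so fixtures are regenerable bit-identically.

What a green test on this world does and does not establish: it verifies
the *mechanics* — model arithmetic against independent oracles, rule
orderings (colder zones start counting no later, finish no earlier, and
accumulate more chill), QC recall of planted violations — but not
real-world calibration. The generator has no weather fronts, no
cold-air-pooling topography, no humidity–wind microclimate, and its chill
totals run higher than real Murcia seasons because its winters sit long and
steadily in the effective band. Quantities reported from real stations
(exact end-of-count weeks, the CU–CP R² of 0.94) are therefore checked
only as qualitative properties here: ordering of end weeks across zones,
and a seasonal CU–CP regression R² ≥ 0.8 on the synthetic network.

## Numerical and degenerate-input choices

* Duplicate ingestion timestamps keep the last record, with a warning and
  a counter; unparseable rows are skipped and counted.
* Hourly resampling refuses mixed-station input; an hour with zero valid
  slots is a gap with coverage 0.
* Level-4 windows with fewer than two valid records are skipped; spatial
  validation silently skips timestamps with too few neighbours and warns
  when no neighbour station is supplied at all.
* `end_of_count_utah` refuses fewer than four weeks (the rule needs a week
  plus three followers); an all-positive season returns the last week,
  flagged unterminated.
* Binomial masses use `dbinom` directly; the closed form
  1 − (1 − p)^n is asserted against the mass sum to 1e-12.
* Pipeline artifacts fix float formatting at 4 decimals so identical
  inputs and seed yield byte-identical files.

## Known limitations

Ecodormancy (heat) modelling, phenological validation of dormancy break,
spatial interpolation of zones or frost probability, and map rendering are
all out of scope. The start-date rule is one defensible reading of an
under-specified procedure; the classifier's annual-mean bands beyond the
D/E and (adjusted) A/B boundaries are package choices; and the NGSI-LD
parser handles single-entity documents only, as an input format rather
than a broker client.
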