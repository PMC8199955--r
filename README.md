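# chillsuit

Agroclimatic decision support for temperate (stone) fruit growing. Deciduous
fruit trees must accumulate a crop- and variety-specific amount of winter
cold to break endodormancy; planting a variety whose chilling requirement a
site cannot reliably meet — or whose flowering window overlaps the site's
frost season — costs yield. `chillsuit` turns raw weather-station records
into that advice: it validates the records, accumulates chill under the
three standard models, characterises the site's climate zone and frost
regime, and scores each varietal group's suitability.

## What it computes

**Chill models** (per hour, on hourly mean temperature *T*):

- *Chilling Hours* (Weinberger): `CH = Σ 1{0 °C ≤ T ≤ 7 °C}`.
- *Utah Cold Units* (Richardson): `CU = Σ w(T)` with the standard weight
  table — `w = 1` for 2.5–9.1 °C, `0.5` for 1.5–2.4 and 9.2–12.4 °C, `0`
  below 1.5 and at 12.5–15.9 °C, `−0.5` for 16–18 °C, `−1` above 18 °C.
- *Dynamic / Chill Portions* (Fishman–Erez–Couvillon): the two-step kinetic
  recursion in kelvin, `x_s = (a₀/a₁)·e^{(e₁−e₀)/T_K}`,
  `k₁ = a₁·e^{−e₁/T_K}`, intermediate `x ← x_s − (x_s − x)·e^{−k₁}`; when
  `x ≥ 1` the fraction `ξ = s/(1+s)`, `s = e^{slp·tetmlt·(T_K−tetmlt)/T_K}`,
  converts irreversibly to Portions. Constants: `slp = 1.6`,
  `tetmlt = 277 K`, `a₀ = 1.395×10⁵`, `e₀ = 4153.5`, `a₁ = 2.567×10¹⁸`,
  `e₁ = 12888.8`.

**Season accounting**: count start = the day after the running Utah
cumulative (from 1 September) attains its autumn minimum; weekly Utah and
Portion tables; end of count = first week followed by ≥ 3 non-positive Utah
weeks (Richardson) or the last week with positive Portions (Dynamic);
interannual weekly means and suspect-station statistics (range > 50 days,
SD > 15 days).

**QC**: the six-level real-time validation cascade for automatic stations —
rigid physical/instrumental limits, monthly ephemerides, step coherence,
internal consistency (gust ≥ mean wind), stuck-sensor windows, IDW spatial
consistency, and a review report in place of visual inspection.

**Risk and advice**: maximal-run detection of frost (≤ −0.5 °C, ≥ 3 h) and
abnormal-warmth events; Mann–Kendall trends; Haan binomial frost risk
`P(≥1 damage year in n) = 1 − (1−p)ⁿ` with `p` the per-year probability of
reaching the critical temperature `T_c = −3 °C` in an earliness group's
sensitive period; and the recommendation rule *suitable ⇔ safe chill ≥
accumulated cold base ∧ frost p ≤ threshold*, where safe chill is the 20th
percentile of seasonal Utah totals.

## Worked example

Six years of synthetic intermediate-zone (C) weather, seasonal chill,
frost risk and the advisory:

```r
library(chillsuit)

cfg  <- synthetic_zone_config("C", seed = 7)
wx   <- generate_hourly_series(cfg, years = 6, start_year = 2010)
summ <- do.call(rbind, lapply(2010:2014, function(y) {
  win <- season_window(y)
  st  <- estimate_start_date(wx$hourly, win)
  wt  <- weekly_chill_table(wx$hourly, st, win, station_id = "demo")
  season_chill_summary(wt, st)
}))
summ[, c("season_label", "start_date", "end_week_utah", "total_cu_at_end")]
#>   season_label start_date end_week_utah total_cu_at_end
#> 1    2010-2011 2010-09-21            18          2906.5
#> 2    2011-2012 2011-09-19            18          2882.5
#> 3    2012-2013 2012-09-27            18          2837.0
#> 4    2013-2014 2013-10-04            18          2849.5
#> 5    2014-2015 2014-09-26            18          2773.0

risk <- haan_frost_risk(wx$hourly, frost_risk_params(), group = "I",
                        horizon_years = 10)
risk$p               # 1: a damaging frost occurred in the early-group
                     # sensitive period every observed year
prof <- site_profile(summ, frost_p = c(I = risk$p, II = risk$p, III = 0))
prof$safe_cu         # 2824.2 CU (20th percentile of the seasonal totals)

recommend(prof)[, c("crop", "group_label", "suitable", "reasons")]
#>             crop group_label suitable    reasons
#> 1          peach    Very Low    FALSE frost_risk
#> ...
#> 12 japanese_plum        High     TRUE         ok
#> 13  sweet_cherry        High     TRUE         ok
#> 14         peach        High     TRUE         ok
#> 15       apricot        High     TRUE         ok
```

Every varietal group clears the chill criterion at this chill-rich site
(`margin_cu > 1500` throughout), but the yearly early-spring frosts gate
out earliness groups I and II, so only the late, high-chill groups are
advised. The file-based pipeline (`run_pipeline("all", config)`) chains
simulate → qc → season → classify → events → risk → recommend and writes
CSV/JSON/GeoJSON artifacts.

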