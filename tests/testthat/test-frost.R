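test_that("frost runs must reach 3 consecutive hours at or below -0.5", {
  frost <- default_event_definitions()$frost
  ev <- detect_events(mk_series(c(5, -1, -1, -1, 5)), frost)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 3L)
  expect_equal(ev$extreme_temp, -1)

  expect_equal(nrow(detect_events(mk_series(c(5, -1, -1, 5)), frost)), 0L)

  # maximal runs: 5 qualifying hours are one event, not 3 overlapping windows
  ev <- detect_events(mk_series(c(5, rep(-2, 5), 5)), frost)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 5L)

  # boundary: exactly -0.5 qualifies (at-or-below)
  ev <- detect_events(mk_series(rep(-0.5, 3)), frost)
  expect_equal(nrow(ev), 1L)
})

test_that("masked hours and month windows break or restrict runs", {
  temps <- c(-2, -2, NA, -2, -2)
  expect_equal(nrow(detect_events(mk_series(temps),
                                  default_event_definitions()$frost)), 0L)

  flw <- default_event_definitions()$flowering_anomaly
  jan <- mk_series(rep(30, 6), start = "2015-01-10 00:00:00")
  feb <- mk_series(rep(30, 6), start = "2015-02-10 00:00:00")
  expect_equal(nrow(detect_events(jan, flw)), 0L)   # outside Feb-Mar
  expect_equal(nrow(detect_events(feb, flw)), 1L)

  # the Oct-Mar dormancy window wraps across New Year
  warm <- default_event_definitions()$abnormal_warm_3h
  nov <- mk_series(rep(24, 4), start = "2015-11-10 00:00:00")
  jun <- mk_series(rep(24, 4), start = "2015-06-10 00:00:00")
  expect_equal(nrow(detect_events(nov, warm)), 1L)
  expect_equal(nrow(detect_events(jun, warm)), 0L)
})

test_that("detection equals brute-force window enumeration on random hours", {
  set.seed(55)
  n <- 10000
  temps <- 6 - 10 * cos(2 * pi * seq_len(n) / 8760) + rnorm(n, 0, 4)
  temps[sample.int(n, 100)] <- NA
  s <- mk_series(temps, start = "2014-10-01 00:00:00")
  months <- as.integer(format(s$hour, "%m"))
  for (d in default_event_definitions()) {
    got <- detect_events(s, d)
    want <- oracle_events(temps, months, d$threshold, d$direction,
                          d$min_consecutive_hours, d$month_window)
    expect_equal(nrow(got), nrow(want), label = d$name)
    if (nrow(want)) {
      expect_equal(got$start, s$hour[want[, "start"]])
      expect_equal(got$duration, unname(want[, "duration"]))
    }
  }
})

test_that("annual stats: counts, p-hat, critical weeks", {
  ev <- data.frame(name = "frost",
                   start = as.POSIXct(c("2010-01-05", "2010-01-20",
                                        "2012-02-01", "2015-12-30"), tz = "UTC"),
                   duration = 3L, extreme_temp = -2)
  st <- annual_event_stats(ev, 2010:2019)
  expect_equal(st$p_hat, 0.3)     # events in 3 of 10 years
  expect_equal(st$per_year$count[st$per_year$year == 2010], 2L)
  expect_equal(sum(st$weekly$n_events), nrow(ev))
  expect_gte(sum(st$weekly$n_events), sum(st$per_year$count >= 1))

  empty <- annual_event_stats(ev[0, ], 2010:2012)
  expect_equal(empty$p_hat, 0)
})

test_that("event trend: slope per decade and Mann-Kendall decision", {
  up <- data.frame(year = 2001:2010, count = 1:10)
  tr <- event_trend(up)
  expect_equal(tr$slope_per_decade, 10)
  expect_true(tr$trend_detected)
  expect_equal(tr$tau, 1)

  flat <- data.frame(year = 2001:2010, count = rep(3L, 10))
  tr <- event_trend(flat)
  expect_equal(tr$slope_per_decade, 0)
  expect_false(tr$trend_detected)

  expect_error(event_trend(up[1:4, ]), "at least 5")

  # permuting years destroys a strong trend almost always
  set.seed(8)
  detected <- vapply(1:40, function(i) {
    event_trend(data.frame(year = 2001:2010, count = sample(1:10)))$trend_detected
  }, logical(1))
  expect_gte(mean(!detected), 0.95)
})

test_that("Haan binomial risk matches closed forms", {
  # build a 6-year series whose sensitive-period minima are controlled:
  # damage (below tc) in 3 of 6 years -> p = 0.5
  years <- 2010:2015
  series <- do.call(rbind, lapply(seq_along(years), function(i) {
    t <- if (i %% 2 == 0) -5 else 2
    mk_series(rep(t, 24 * 50), start = sprintf("%d-02-01 00:00:00", years[i]))
  }))
  class(series) <- c("hourly_series", "data.frame")
  r <- haan_frost_risk(series, frost_risk_params(), "I", horizon_years = 2)
  expect_equal(r$p, 0.5)
  expect_equal(r$p_at_least_one, 0.75)

  # p = 0 -> no risk at any horizon
  safe <- mk_series(rep(5, 24 * 400), start = "2010-01-01 00:00:00")
  # needs >= 5 years: replicate across years
  safe <- do.call(rbind, lapply(2010:2014, function(y)
    mk_series(rep(5, 24 * 60), start = sprintf("%d-02-01 00:00:00", y))))
  class(safe) <- c("hourly_series", "data.frame")
  r0 <- haan_frost_risk(safe, frost_risk_params(), "I", horizon_years = 7)
  expect_equal(r0$p, 0)
  expect_equal(r0$p_at_least_one, 0)

  # masses sum to 1 within 1e-12 over a (p, n) grid
  for (p in c(0, 0.17, 0.5, 0.93)) {
    for (n in c(1, 10, 50)) {
      expect_lt(abs(sum(stats::dbinom(0:n, n, p)) - 1), 1e-12)
    }
  }
  expect_lt(abs(sum(r$binomial_masses) - 1), 1e-12)

  # P(>=1) is non-decreasing in p and in n
  ps <- seq(0, 1, by = 0.1)
  expect_true(!is.unsorted(1 - (1 - ps)^5))
  expect_true(!is.unsorted(vapply(1:20, function(n) 1 - (1 - 0.3)^n, numeric(1))))
})

test_that("lowering tc never increases the damage probability", {
  set.seed(77)
  cfg <- synthetic_zone_config("C", seed = 77)
  g <- generate_hourly_series(cfg, 6, 2010)
  p_at <- function(tc) haan_frost_risk(g$hourly, frost_risk_params(tc = tc),
                                       "I", 10)$p
  ps <- vapply(c(-0.5, -2, -3, -5, -8), p_at, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("polygon risk banding is total and respects the cut points", {
  polys <- data.frame(id = 1:4, p_I = c(0.05, 0.5, NA, 0.1),
                      p_II = c(0.2, 0.01, 0.9, 0.3))
  out <- classify_polygon_risk(polys)
  expect_equal(out$risk_I, c("low", "high", "unclassified", "medium"))
  expect_equal(out$risk_II, c("medium", "low", "high", "high"))
  expect_true(all(out$risk_I %in% c("low", "medium", "high", "unclassified")))
})
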