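# builds a Sep-Jun hourly series from a day-indexed temperature function
mk_season_series <- function(start_year, temp_of_date, end = "-06-30") {
  from <- as.POSIXct(sprintf("%d-09-01 00:00:00", start_year), tz = "UTC")
  to <- as.POSIXct(sprintf("%d%s 23:00:00", start_year + 1, end), tz = "UTC")
  hours <- seq(from, to, by = 3600)
  mk_series(rep_len(temp_of_date(as.Date(hours, tz = "UTC")), length(hours)),
            start = format(from, "%Y-%m-%d %H:%M:%S"))
}

test_that("start date is the day after the Utah cumulative minimum", {
  win <- season_window(2014)
  # hot (net-negative) through 1 Nov, chill from 2 Nov
  s <- mk_season_series(2014, function(d) ifelse(d <= "2014-11-01", 25, 5))
  expect_equal(as.character(estimate_start_date(s, win)), "2014-11-02")

  # non-decreasing cumulative from the outset -> search start itself
  s <- mk_season_series(2014, function(d) 5)
  expect_equal(as.character(estimate_start_date(s, win)), "2014-09-01")

  # invariant to appending warm-free (chill) weeks past the minimum
  s2 <- mk_season_series(2014, function(d) ifelse(d <= "2014-11-01", 25, 5),
                         end = "-01-31")
  s1 <- mk_season_series(2014, function(d) ifelse(d <= "2014-11-01", 25, 5),
                         end = "-03-31")
  expect_equal(estimate_start_date(s1, win), estimate_start_date(s2, win))
})

test_that("start date is flagged low-confidence above 20% masked hours", {
  win <- season_window(2014)
  s <- mk_season_series(2014, function(d) 5)
  d <- estimate_start_date(s, win)
  expect_false(attr(d, "low_confidence"))
  in_search <- s$hour <= win$search_end
  idx <- which(in_search)
  mask <- idx[seq_len(ceiling(0.25 * length(idx)))]
  s$gap[mask] <- TRUE
  s$temperature[mask] <- NA
  expect_true(attr(estimate_start_date(s, win), "low_confidence"))
})

test_that("start-date statistics set the 50-day and 15-day suspect flags", {
  dates <- list(`2010` = as.Date("2010-10-01"), `2011` = as.Date("2011-11-30"))
  st <- compute_start_date_stats(dates)   # 60-day range
  expect_true(st$suspect_range)

  same <- list(`2010` = as.Date("2010-10-15"), `2011` = as.Date("2011-10-15"),
               `2012` = as.Date("2012-10-15"))
  st <- compute_start_date_stats(same)
  expect_equal(st$std_days, 0)
  expect_false(st$suspect_range)
  expect_false(st$suspect_std)
  expect_equal(st$mean, st$median)
  expect_lte(st$earliest, st$median)
  expect_lte(st$median, st$latest)

  # sd just over 15 days (day-of-season 21 and 44: sd ~16.3)
  wide <- list(`2010` = as.Date("2010-09-22"), `2011` = as.Date("2011-10-15"))
  st <- compute_start_date_stats(wide)
  expect_true(st$std_days > 15 && st$std_days < 17)
  expect_true(st$suspect_std)
  expect_false(st$suspect_range)

  one <- compute_start_date_stats(list(`2010` = as.Date("2010-10-01")))
  expect_false(one$flags_computed)
})

test_that("weekly chill table runs both models from the start date", {
  win <- season_window(2014)
  s <- mk_season_series(2014, function(d) 5)
  # count from a Monday so the first weeks are full
  wt <- weekly_chill_table(s, as.Date("2014-09-08"), win, station_id = "S")
  expect_equal(wt$weekly_uf[1:3], c(168, 168, 168))
  expect_equal(wt$cum_uf[1:3], c(168, 336, 504))
  expect_true(all(diff(wt$cum_portions) >= -1e-12))
  expect_true(all(wt$n_records <= 168))
  # cumulative columns are prefix sums of the weekly columns
  expect_equal(wt$cum_uf, cumsum(wt$weekly_uf))
  expect_equal(wt$cum_portions, cumsum(wt$weekly_portions), tolerance = 1e-12)
})

mk_weekly <- function(uf, portions = rep(0, length(uf))) {
  data.frame(station_id = "S", season_label = "2014-2015",
             year = 2014L, iso_week = seq_along(uf) + 39L,
             week_start = seq(as.POSIXct("2014-09-29", tz = "UTC"),
                              by = 7 * 86400, length.out = length(uf)),
             weekly_uf = uf, weekly_portions = portions,
             cum_uf = cumsum(uf), cum_portions = cumsum(portions),
             n_records = 168L)
}

test_that("Utah end-of-count: first week followed by >=3 non-positive weeks", {
  w <- mk_weekly(c(10, 8, 0, -1, -2, 4, 3))
  e <- end_of_count_utah(w)
  expect_equal(attr(e, "index"), 2L)       # weeks 3-5 are <= 0
  expect_equal(e$iso_week, w$iso_week[2L])
  expect_true(attr(e, "terminated"))

  expect_warning(e <- end_of_count_utah(mk_weekly(rep(5, 6))), "last week")
  expect_equal(attr(e, "index"), 6L)
  expect_false(attr(e, "terminated"))

  e <- end_of_count_utah(mk_weekly(c(5, 0, 0, 0)))
  expect_equal(attr(e, "index"), 1L)

  expect_error(end_of_count_utah(mk_weekly(c(1, 2, 3))), "fewer than 4")
})

test_that("Dynamic end-of-count: last week with positive portions", {
  w <- mk_weekly(rep(1, 5), portions = c(0.2, 0.5, 0.4, 0, 0))
  e <- end_of_count_dynamic(w)
  expect_equal(e$weekly_portions, 0.4)     # the last positive week
  expect_equal(attr(e, "index"), 3L)

  expect_warning(r <- end_of_count_dynamic(mk_weekly(rep(1, 4))), "no week")
  expect_null(r)

  # appending trailing zero-portion weeks never changes the result
  w2 <- mk_weekly(rep(1, 8), portions = c(0.2, 0.5, 0.4, 0, 0, 0, 0, 0))
  expect_equal(end_of_count_dynamic(w2)$iso_week, e$iso_week)
})

test_that("season summary totals equal the cumulative at the end week", {
  win <- season_window(2014)
  set.seed(31)
  s <- mk_season_series(2014, function(d) {
    doy <- as.integer(format(d, "%j"))
    12 - 8 * cos(2 * pi * (doy - 15) / 365) + rnorm(length(d), 0, 2)
  })
  start <- estimate_start_date(s, win)
  wt <- weekly_chill_table(s, start, win, station_id = "S")
  ss <- season_chill_summary(wt, start)
  expect_equal(ss$total_cu_at_end, wt$cum_uf[ss$end_week_utah_index])
  expect_equal(ss$total_portions_at_end,
               wt$cum_portions[ss$end_week_dynamic_index])
  expect_true(ss$end_week_utah %in% wt$iso_week)
})

test_that("interannual weekly means average cumulative values across years", {
  r1 <- mk_weekly(c(50, 50)); r1$cum_uf <- c(50, 100)
  r2 <- mk_weekly(c(100, 100)); r2$season_label <- "2015-2016"
  r2$cum_uf <- c(100, 200)
  m <- interannual_weekly_means(rbind(r1, r2))
  expect_equal(m$mean_cum_uf, c(75, 150))
  expect_equal(m$n_years, c(2L, 2L))

  single <- interannual_weekly_means(r1)
  expect_equal(single$mean_cum_uf, r1$cum_uf)

  # brute-force recomputation for uneven week coverage
  r3 <- mk_weekly(c(10, 20, 30)); r3$season_label <- "2016-2017"
  r3$cum_uf <- cumsum(c(10, 20, 30))
  all_r <- rbind(r1, r2, r3)
  m <- interannual_weekly_means(all_r)
  for (wk in unique(all_r$iso_week)) {
    expect_equal(m$mean_cum_uf[m$iso_week == wk],
                 mean(all_r$cum_uf[all_r$iso_week == wk]))
  }
  # autumn weeks order before winter/spring weeks
  r4 <- mk_weekly(c(1, 1)); r4$iso_week <- c(50L, 2L)
  m <- interannual_weekly_means(r4)
  expect_equal(m$iso_week, c(50L, 2L))
})
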