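#' Dormancy season window
#'
#' A winter season runs from the start-date search window opening on 1
#' September of `start_year` to the analysis end on 30 June of the following
#' year. The start-date search itself is confined to September-December.
#'
#' @param start_year Calendar year in which the season opens.
#' @return List of class `season_window`: `season_label` (e.g. "2015-2016"),
#'   `search_start`, `search_end` (31 Dec), `analysis_end`.
#' @export
season_window <- function(start_year) {
  start_year <- as.integer(start_year)
  structure(list(
    season_label = sprintf("%d-%d", start_year, start_year + 1L),
    start_year = start_year,
    search_start = as.POSIXct(sprintf("%d-09-01 00:00:00", start_year), tz = "UTC"),
    search_end = as.POSIXct(sprintf("%d-12-31 23:00:00", start_year), tz = "UTC"),
    analysis_end = as.POSIXct(sprintf("%d-06-30 23:00:00", start_year + 1L), tz = "UTC")
  ), class = "season_window")
}

.clip_series <- function(series, from, to) {
  series[series$hour >= from & series$hour <= to, , drop = FALSE]
}

#' Estimate the start of chill counting (entry into endodormancy)
#'
#' Richardson-style reset rule: the Utah cumulative is run from 1 September
#' and the start date is the day after the day on which the running cumulative
#' attains its seasonal minimum within the search window (i.e. the last day
#' from which accumulation is net-positive onward; ties resolved to the last
#' minimum). If the cumulative never drops below its initial level, the
#' search start itself is returned.
#'
#' @param series `hourly_series` covering at least September-December.
#' @param window A [season_window()].
#' @param params [chill_params()].
#' @return A `Date`, with attribute `low_confidence` set when more than 20%
#'   of the search-window hours are gap-masked.
#' @export
estimate_start_date <- function(series, window, params = chill_params()) {
  s <- .clip_series(series, window$search_start, window$search_end)
  if (nrow(s) == 0L) stop("series does not cover the start-date search window")
  cu <- utah_units(s, params)
  day <- as.Date(cu$hour, tz = "UTC")
  daily <- tapply(cu$value, day, sum)
  cum <- cumsum(as.numeric(daily))
  days <- as.Date(names(daily))
  # day 0 = state before any accumulation, cumulative 0
  cum_all <- c(0, cum)
  k <- max(which(cum_all == min(cum_all))) - 1L  # 0 => non-decreasing outset
  start <- if (k == 0L) as.Date(window$search_start, tz = "UTC")
           else days[k] + 1L
  masked_frac <- mean(s$gap)
  attr(start, "low_confidence") <- masked_frac > 0.2
  start
}

#' Interannual statistics of start dates, with suspect-station flags
#'
#' Statistics are computed on day-of-season integers (days since 1
#' September). A station is suspect when the earliest-latest range exceeds
#' `range_threshold` (default 50 days) or the standard deviation exceeds
#' `std_threshold` (default 15 days). The mode is the most frequent
#' day-of-season, ties broken by the earliest.
#'
#' @param dates_by_year Named list or vector of `Date` start dates, one per
#'   season (names are season start years).
#' @param range_threshold,std_threshold Day thresholds for the two checks.
#' @return List of class `start_date_stats`.
#' @export
compute_start_date_stats <- function(dates_by_year, range_threshold = 50,
                                     std_threshold = 15) {
  dates <- as.Date(unlist(lapply(dates_by_year, as.character)))
  years <- as.integer(names(dates_by_year))
  if (is.null(years) || any(is.na(years)))
    years <- as.integer(format(dates, "%Y"))
  doy <- as.integer(dates - as.Date(sprintf("%d-09-01", years)))
  n <- length(doy)
  if (n < 2L) {
    return(structure(list(n_years = n, dates = dates, flags_computed = FALSE,
                          suspect_range = FALSE, suspect_std = FALSE),
                     class = "start_date_stats"))
  }
  tab <- table(doy)
  mode_doy <- as.integer(names(tab)[tab == max(tab)])[1L]
  rng <- max(doy) - min(doy)
  sdv <- stats::sd(doy)
  structure(list(
    n_years = n, dates = dates, day_of_season = doy,
    mean = mean(doy), earliest = min(doy), latest = max(doy),
    median = stats::median(doy), mode = mode_doy,
    range_days = rng, std_days = sdv, flags_computed = TRUE,
    suspect_range = rng > range_threshold,
    suspect_std = sdv > std_threshold
  ), class = "start_date_stats")
}

#' Weekly Utah and Portion accumulation table for one season
#'
#' Runs [utah_units()] and [chill_portions()] from the estimated start date to
#' the analysis end and aggregates both by ISO week. Weeks before the start
#' date are absent; cumulative columns are prefix sums since the count start.
#'
#' @param series `hourly_series` covering the season.
#' @param start_date `Date` count start.
#' @param window [season_window()].
#' @param params [chill_params()].
#' @param station_id Optional station label carried into the table.
#' @return `data.frame`: `station_id`, `season_label`, `year`, `iso_week`,
#'   `week_start`, `weekly_uf`, `weekly_portions`, `cum_uf`, `cum_portions`,
#'   `n_records`.
#' @export
weekly_chill_table <- function(series, start_date, window,
                               params = chill_params(),
                               station_id = attr(series, "station_id") %||% "") {
  from <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  stopifnot(from >= window$search_start, from <= window$analysis_end)
  s <- .clip_series(series, from, window$analysis_end)
  cu <- weekly_aggregate(utah_units(s, params))
  cp <- weekly_aggregate(chill_portions(s, params))
  stopifnot(identical(cu$week_start, cp$week_start))
  data.frame(
    station_id = station_id, season_label = window$season_label,
    year = cu$iso_year, iso_week = cu$iso_week, week_start = cu$week_start,
    weekly_uf = cu$weekly_sum, weekly_portions = cp$weekly_sum,
    cum_uf = cu$cumulative, cum_portions = cp$cumulative,
    n_records = cu$n_records, stringsAsFactors = FALSE)
}

#' End of chill counting, Utah (Richardson) rule
#'
#' The first week after which the weekly Utah sums are negative or null for
#' at least three consecutive weeks. If no week qualifies the last week is
#' returned with a warning (attribute `terminated = FALSE`).
#'
#' @param weekly A [weekly_chill_table()] in season order.
#' @return One row of `weekly` (the end week), with attributes `index` and
#'   `terminated`.
#' @export
end_of_count_utah <- function(weekly) {
  n <- nrow(weekly)
  if (n < 4L) stop("end-of-count undefined for fewer than 4 weeks")
  uf <- weekly$weekly_uf
  nonpos <- uf <= 0
  for (i in seq_len(n - 3L)) {
    if (all(nonpos[(i + 1L):(i + 3L)])) {
      out <- weekly[i, , drop = FALSE]
      attr(out, "index") <- i
      attr(out, "terminated") <- TRUE
      return(out)
    }
  }
  warning("no three-week non-positive run; returning last week")
  out <- weekly[n, , drop = FALSE]
  attr(out, "index") <- n
  attr(out, "terminated") <- FALSE
  out
}

#' End of chill counting, Dynamic rule
#'
#' The last week with a positive weekly Portion sum. A season with no
#' positive week returns `NULL` with a warning.
#'
#' @inheritParams end_of_count_utah
#' @export
end_of_count_dynamic <- function(weekly) {
  pos <- which(weekly$weekly_portions > 0)
  if (length(pos) == 0L) {
    warning("no week with positive Portions; end of count undefined")
    return(NULL)
  }
  i <- max(pos)
  out <- weekly[i, , drop = FALSE]
  attr(out, "index") <- i
  attr(out, "terminated") <- TRUE
  out
}

#' Season chill summary
#'
#' Combines the start date, both end-of-count weeks and the cumulative totals
#' at those weeks for one station-season.
#'
#' @param weekly [weekly_chill_table()] output.
#' @param start_date Count start `Date`.
#' @return One-row `data.frame` with `end_week_utah`, `end_week_dynamic`,
#'   `total_cu_at_end`, `total_portions_at_end`.
#' @export
season_chill_summary <- function(weekly, start_date) {
  eu <- end_of_count_utah(weekly)
  ed <- end_of_count_dynamic(weekly)
  data.frame(
    station_id = weekly$station_id[1L], season_label = weekly$season_label[1L],
    start_date = start_date,
    end_week_utah = eu$iso_week, end_week_utah_index = attr(eu, "index"),
    end_week_dynamic = if (is.null(ed)) NA_integer_ else ed$iso_week,
    end_week_dynamic_index = if (is.null(ed)) NA_integer_ else attr(ed, "index"),
    total_cu_at_end = eu$cum_uf,
    total_portions_at_end = if (is.null(ed)) 0 else ed$cum_portions,
    stringsAsFactors = FALSE)
}

#' Interannual weekly means of cumulative chill
#'
#' Arithmetic means of the cumulative Utah and Portion values per (station,
#' ISO week) across seasons; weeks present in only some years are averaged
#' over the available years, with `n_years` recording how many.
#'
#' @param records Row-bound [weekly_chill_table()] outputs across seasons.
#' @return `data.frame(station_id, iso_week, mean_cum_uf, mean_cum_portions,
#'   n_years)` in season-week order (Sep-Dec weeks before Jan-Jun weeks).
#' @export
interannual_weekly_means <- function(records) {
  dt <- data.table::as.data.table(records)
  agg <- dt[, list(mean_cum_uf = mean(cum_uf),
                   mean_cum_portions = mean(cum_portions),
                   n_years = data.table::uniqueN(season_label)),
            by = c("station_id", "iso_week")]
  # season ordering: autumn weeks (>=27) precede winter/spring weeks
  key <- ifelse(agg$iso_week >= 27L, agg$iso_week - 53L, agg$iso_week)
  out <- as.data.frame(agg[order(agg$station_id, key), ])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
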