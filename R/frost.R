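#' Extreme-event definition
#'
#' A threshold-duration rule: an event occurs when the hourly temperature is
#' at-or-below (frost) or above (warm anomalies) a threshold for at least
#' `min_consecutive_hours` consecutive hours, optionally restricted to a
#' month window.
#'
#' @param name Event name.
#' @param threshold Temperature threshold, deg C.
#' @param direction `"at_or_below"` or `"above"`.
#' @param min_consecutive_hours Minimum run length, hours.
#' @param month_window Optional `c(start_month, end_month)` (inclusive; may
#'   wrap across New Year, e.g. `c(10, 3)` for the dormancy window).
#' @return List of class `event_definition`.
#' @export
event_definition <- function(name, threshold,
                             direction = c("at_or_below", "above"),
                             min_consecutive_hours = 3L,
                             month_window = NULL) {
  direction <- match.arg(direction)
  stopifnot(min_consecutive_hours >= 1L)
  if (!is.null(month_window))
    stopifnot(length(month_window) == 2L, all(month_window %in% 1:12))
  structure(list(name = name, threshold = threshold, direction = direction,
                 min_consecutive_hours = as.integer(min_consecutive_hours),
                 month_window = month_window),
            class = "event_definition")
}

#' The three extreme-event types monitored during dormancy
#'
#' Frost: temperature at or below -0.5 deg C for at least 3 consecutive
#' hours. Abnormal warmth: above 21 deg C for at least 6 hours, or above
#' 23 deg C for at least 3 hours (both within the October-March dormancy
#' window by default). Flowering-phase anomaly: above 25 deg C for at least
#' 3 hours between February and March.
#'
#' @param warm_dormancy_only Restrict the abnormal-warmth rules to the
#'   October-March dormancy window (default TRUE).
#' @return Named list of [event_definition()]s.
#' @export
default_event_definitions <- function(warm_dormancy_only = TRUE) {
  warm_win <- if (warm_dormancy_only) c(10L, 3L) else NULL
  list(
    frost = event_definition("frost", -0.5, "at_or_below", 3L),
    abnormal_warm_6h = event_definition("abnormal_warm_6h", 21, "above", 6L, warm_win),
    abnormal_warm_3h = event_definition("abnormal_warm_3h", 23, "above", 3L, warm_win),
    flowering_anomaly = event_definition("flowering_anomaly", 25, "above", 3L, c(2L, 3L))
  )
}

.in_month_window <- function(month, win) {
  if (is.null(win)) return(rep(TRUE, length(month)))
  if (win[1L] <= win[2L]) month >= win[1L] & month <= win[2L]
  else month >= win[1L] | month <= win[2L]
}

#' Detect extreme-temperature events as maximal qualifying runs
#'
#' Scans an hourly series for maximal runs of consecutive hours satisfying
#' the definition; only runs of at least the minimum duration are reported,
#' each once (never as overlapping sub-windows). Gap-masked hours and breaks
#' in hour contiguity terminate runs; the month window is applied before run
#' construction.
#'
#' @param series `hourly_series`.
#' @param definition [event_definition()].
#' @return `data.frame(name, start, duration, extreme_temp)`, one row per
#'   event; `extreme_temp` is the most extreme temperature within the run.
#' @export
detect_events <- function(series, definition) {
  t <- series$temperature
  ok <- !series$gap & !is.na(t)
  hit <- ok & .in_month_window(as.integer(format(series$hour, "%m")),
                               definition$month_window)
  hit[hit] <- if (definition$direction == "at_or_below")
    t[hit] <= definition$threshold else t[hit] > definition$threshold
  # breaks in hour contiguity also split runs
  contig <- c(TRUE, diff(as.numeric(series$hour)) == 3600)
  grp <- cumsum(!contig)
  r <- rle(paste0(grp, "_", hit))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- grepl("_TRUE$", r$values) & r$lengths >= definition$min_consecutive_hours
  rows <- lapply(which(keep), function(i) {
    idx <- starts[i]:ends[i]
    ext <- if (definition$direction == "at_or_below") min(t[idx]) else max(t[idx])
    data.frame(name = definition$name, start = series$hour[starts[i]],
               duration = r$lengths[i], extreme_temp = ext)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(name = character(0),
                  start = as.POSIXct(character(0), tz = "UTC"),
                  duration = integer(0), extreme_temp = numeric(0))
}

#' Annual event counts, empirical probability and critical weeks
#'
#' @param occurrences [detect_events()] output (possibly spanning years).
#' @param years Integer vector of all years observed (so years without
#'   events count as zeros).
#' @return List: `per_year` (`year`, `count`), `p_hat` = share of years with
#'   at least one event, `weekly` per-ISO-week event counts ("critical
#'   weeks").
#' @export
annual_event_stats <- function(occurrences, years) {
  years <- sort(unique(as.integer(years)))
  stopifnot(length(years) >= 1L)
  ev_year <- as.integer(format(occurrences$start, "%Y"))
  counts <- vapply(years, function(y) sum(ev_year == y), integer(1))
  wk <- as.integer(format(occurrences$start, "%V"))
  weekly <- if (length(wk)) as.data.frame(table(iso_week = wk),
                                          stringsAsFactors = FALSE)
            else data.frame(iso_week = character(0), Freq = integer(0))
  names(weekly)[2L] <- "n_events"
  weekly$iso_week <- as.integer(weekly$iso_week)
  list(per_year = data.frame(year = years, count = counts),
       p_hat = mean(counts >= 1L),
       weekly = weekly)
}

#' Trend in annual event counts
#'
#' Least-squares slope of annual counts on year (reported per decade) plus
#' the distribution-free Mann-Kendall monotone-trend test (Kendall's tau of
#' counts against year).
#'
#' @param per_year `data.frame(year, count)` with at least 5 years.
#' @param level Significance level for the trend decision.
#' @return List: `slope_per_decade`, `tau`, `p_value`, `trend_detected`.
#' @export
event_trend <- function(per_year, level = 0.05) {
  if (nrow(per_year) < 5L) stop("trend requires at least 5 years")
  fit <- stats::lm(count ~ year, data = per_year)
  slope <- unname(stats::coef(fit)[2L]) * 10
  if (stats::sd(per_year$count) == 0) {
    return(list(slope_per_decade = 0, tau = 0, p_value = 1,
                trend_detected = FALSE))
  }
  kt <- suppressWarnings(
    stats::cor.test(per_year$year, per_year$count, method = "kendall"))
  list(slope_per_decade = slope, tau = unname(kt$estimate),
       p_value = kt$p.value, trend_detected = kt$p.value < level)
}

#' Frost-risk parameters for the earliness groups
#'
#' `tc` is the critical damage temperature (-3 deg C: at or below it,
#' significant damage occurs within the sensitive period). Earliness groups:
#' I extra-early and early, II mid-season and late, III late; each has a
#' sensitive period given as month-day strings.
#'
#' @param tc Critical damage temperature, deg C (must be negative).
#' @param sensitive_periods Named list of `c(start, end)` `"MM-DD"` pairs.
#' @return List of class `frost_risk_params`.
#' @export
frost_risk_params <- function(
    tc = -3,
    sensitive_periods = list(I = c("02-01", "03-15"),
                             II = c("02-20", "04-05"),
                             III = c("03-10", "04-20"))) {
  stopifnot(tc < 0)
  for (p in sensitive_periods) stopifnot(p[1L] < p[2L])
  structure(list(tc = tc, sensitive_periods = sensitive_periods),
            class = "frost_risk_params")
}

#' Haan binomial frost risk for an earliness group
#'
#' Years are treated as Bernoulli trials: `p` is the empirical probability
#' that the minimum valid temperature within the group's sensitive period
#' reaches the critical temperature `tc` in a year. The number of damage
#' years in a planning horizon of `n` years is Binomial(n, p); the headline
#' risk is P(at least one damage year) = 1 - (1 - p)^n.
#'
#' @param series `hourly_series` spanning several years.
#' @param params [frost_risk_params()].
#' @param group `"I"`, `"II"` or `"III"`.
#' @param horizon_years Planning horizon n.
#' @return List: `p`, `n_years_observed`, `damage_years`, `horizon`,
#'   `p_at_least_one`, `binomial_masses` (P(X = 0..n)).
#' @export
haan_frost_risk <- function(series, params = frost_risk_params(), group = "I",
                            horizon_years = 10L) {
  per <- params$sensitive_periods[[group]]
  if (is.null(per)) stop("unknown earliness group: ", group)
  md <- format(series$hour, "%m-%d")
  inper <- md >= per[1L] & md <= per[2L] & !series$gap & !is.na(series$temperature)
  if (!any(inper)) stop("no data covering the sensitive period")
  yr <- as.integer(format(series$hour, "%Y"))
  years <- sort(unique(yr[inper]))
  if (length(years) < 5L) stop("frost risk requires at least 5 years")
  damage <- vapply(years, function(y) {
    min(series$temperature[inper & yr == y]) <= params$tc
  }, logical(1))
  p <- mean(damage)
  n <- as.integer(horizon_years)
  list(p = p, n_years_observed = length(years), damage_years = sum(damage),
       horizon = n,
       p_at_least_one = 1 - (1 - p)^n,
       binomial_masses = stats::dbinom(0:n, n, p))
}

#' Band per-polygon frost probabilities into risk classes
#'
#' @param polygons `data.frame` with one probability column per earliness
#'   group, named `p_I`, `p_II`, `p_III` (missing groups skipped).
#' @param bands `c(low_cut, high_cut)`: p below the first cut is "low",
#'   between cuts "medium", at or above the second "high".
#' @return `polygons` with added `risk_I` etc.; missing p -> `"unclassified"`.
#' @export
classify_polygon_risk <- function(polygons, bands = c(0.1, 0.3)) {
  stopifnot(length(bands) == 2L, bands[1L] < bands[2L])
  for (g in c("I", "II", "III")) {
    pc <- paste0("p_", g)
    if (!pc %in% names(polygons)) next
    p <- polygons[[pc]]
    cls <- ifelse(is.na(p), "unclassified",
                  ifelse(p < bands[1L], "low",
                         ifelse(p < bands[2L], "medium", "high")))
    polygons[[paste0("risk_", g)]] <- cls
  }
  polygons
}
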