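# Independent brute-force oracles, written before (and kept apart from) the
# package implementations they check.

# hourly series fixture: temps at 1-h steps from `start`
mk_series <- function(temps, start = "2014-11-03 00:00:00", gap = NULL) {
  hours <- seq(as.POSIXct(start, tz = "UTC"), by = 3600,
               length.out = length(temps))
  if (is.null(gap)) gap <- is.na(temps)
  hourly_series(hours, ifelse(gap, NA_real_, temps), gap = gap)
}

# clean sub-hourly observation fixture with all variables
mk_obs <- function(temps, start = "2015-01-01 00:00:00", interval = 10L,
                   humidity = 50, wind_mean = 2, wind_gust = 4, precip = 0) {
  n <- length(temps)
  obs <- data.frame(
    timestamp = seq(as.POSIXct(start, tz = "UTC"), by = interval * 60,
                    length.out = n),
    temperature = temps,
    humidity = rep_len(humidity, n),
    wind_mean = rep_len(wind_mean, n),
    wind_gust = rep_len(wind_gust, n),
    precipitation = rep_len(precip, n))
  attr(obs, "record_interval") <- as.integer(interval)
  obs
}

# fabricated monthly climatology
mk_clim <- function(monthly_temps, monthly_precip = rep(30, 12)) {
  structure(list(
    station_id = "FAKE",
    monthly = data.frame(month = 1:12, mean_temp = monthly_temps,
                         precip = monthly_precip),
    annual_mean_temp = mean(monthly_temps),
    annual_precip = sum(monthly_precip)
  ), class = "monthly_climatology")
}

# 12-month temperature profile with a given annual mean/amplitude (cold in Jan)
mk_profile_acc <- function(mean_t, amp) mean_t - amp * cospi(2 * (0:11 - 0.5) / 12)

# hand-built weekly chill table
mk_weekly_acc <- function(uf, portions = rep(0, length(uf))) {
  data.frame(station_id = "S", season_label = "2014-2015",
             year = 2014L, iso_week = seq_along(uf) + 39L,
             week_start = seq(as.POSIXct("2014-09-29", tz = "UTC"),
                              by = 7 * 86400, length.out = length(uf)),
             weekly_uf = uf, weekly_portions = portions,
             cum_uf = cumsum(uf), cum_portions = cumsum(portions),
             n_records = 168L)
}

# ---- chill-model oracles: literal per-hour recomputation ----

oracle_chilling_hours <- function(temps, low = 0, high = 7) {
  total <- 0
  for (t in temps) if (!is.na(t) && t >= low && t <= high) total <- total + 1
  total
}

oracle_utah_weight <- function(t) {
  if (t <= 1.4) 0
  else if (t <= 2.4) 0.5
  else if (t <= 9.1) 1
  else if (t <= 12.4) 0.5
  else if (t <= 15.9) 0
  else if (t <= 18) -0.5
  else -1
}

oracle_utah_total <- function(temps) {
  total <- 0
  for (t in temps) if (!is.na(t)) total <- total + oracle_utah_weight(t)
  total
}

# literal transcription of the two-step kinetic recursion, scalar per hour
oracle_portions <- function(temps) {
  slp <- 1.6; tetmlt <- 277; a0 <- 139500; e0 <- 4153.5
  a1 <- 2.567e18; e1 <- 12888.8
  inter_prev <- 0; xi_prev <- 0
  portions <- 0
  per_hour <- numeric(length(temps))
  for (i in seq_along(temps)) {
    t <- temps[i]
    if (is.na(t)) next  # state held, no accumulation
    TK <- t + 273
    ftmprt <- slp * tetmlt * (TK - tetmlt) / TK
    sr <- exp(ftmprt)
    xi <- sr / (1 + sr)
    xs <- (a0 / a1) * exp((e1 - e0) / TK)
    ak1 <- a1 * exp(-e1 / TK)
    inter_s <- if (inter_prev < 1) inter_prev else inter_prev * (1 - xi_prev)
    inter_e <- xs - (xs - inter_s) * exp(-ak1)
    delta <- if (inter_e < 1) 0 else xi * inter_e
    portions <- portions + delta
    per_hour[i] <- delta
    inter_prev <- inter_e
    xi_prev <- xi
  }
  list(total = portions, per_hour = per_hour)
}

# ---- event-detection oracle: enumerate qualifying windows, collapse to
# maximal runs ----

oracle_events <- function(temps, months, threshold, direction, min_len,
                          month_window = NULL) {
  qual <- !is.na(temps) &
    (if (direction == "at_or_below") temps <= threshold else temps > threshold)
  if (!is.null(month_window)) {
    inwin <- if (month_window[1] <= month_window[2])
      months >= month_window[1] & months <= month_window[2]
    else months >= month_window[1] | months <= month_window[2]
    qual <- qual & inwin
  }
  runs <- list()
  i <- 1
  n <- length(qual)
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len)
        runs[[length(runs) + 1]] <- c(start = i, duration = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs)) do.call(rbind, runs) else
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "duration")))
}
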