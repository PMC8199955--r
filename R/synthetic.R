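#' Synthetic zone configuration
#'
#' Stated generating conditions for each climate zone. Annual mean
#' temperatures and precipitation follow the observed per-zone station
#' averages (B 9.12 degC / 185 mm, C 11.21 / 165, D 13.02 / 170, E 14.59 /
#' 155); zone A has no observed row and uses an extrapolated 7.5 degC /
#' 200 mm, documented as such. The annual cycle has its minimum on 15
#' January and the diurnal cycle its maximum at 14:00 local; noise is AR(1)
#' in the hourly residuals with stationary standard deviation `noise_sd`.
#'
#' @param zone `"A"`..`"E"`.
#' @param annual_mean_temp,annual_precip Override the zone defaults.
#' @param annual_amplitude,diurnal_amplitude Half-amplitudes, deg C.
#' @param ar1_phi Hour-to-hour autocorrelation, in [0, 1).
#' @param noise_sd Stationary noise standard deviation, deg C.
#' @param seed Integer seed; all generation is reproducible from it.
#' @return List of class `synthetic_zone_config`.
#' @export
synthetic_zone_config <- function(zone, annual_mean_temp = NULL,
                                  annual_precip = NULL,
                                  annual_amplitude = 8, diurnal_amplitude = 5,
                                  ar1_phi = 0.8, noise_sd = 1.5, seed = 1L) {
  zone <- match.arg(zone, c("A", "B", "C", "D", "E"))
  means <- c(A = 7.5, B = 9.12, C = 11.21, D = 13.02, E = 14.59)
  precs <- c(A = 200, B = 185, C = 165, D = 170, E = 155)
  stopifnot(ar1_phi >= 0, ar1_phi < 1,
            annual_amplitude >= 0, diurnal_amplitude >= 0)
  structure(list(
    zone = zone,
    annual_mean_temp = annual_mean_temp %||% unname(means[zone]),
    annual_precip = annual_precip %||% unname(precs[zone]),
    annual_amplitude = annual_amplitude, diurnal_amplitude = diurnal_amplitude,
    ar1_phi = ar1_phi, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_zone_config")
}

# deterministic part of the temperature curve at fractional day-of-year/hour
.temp_curve <- function(config, doy, hour) {
  config$annual_mean_temp -
    config$annual_amplitude * cos(2 * pi * (doy - 15) / 365) +
    config$diurnal_amplitude * cos(2 * pi * (hour - 14) / 24)
}

.ar1_noise <- function(n, phi, sd) {
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

# Mediterranean monthly precipitation weights: spring/autumn wet, summer dry
.precip_weights <- c(2, 2, 3, 3, 3, 1.5, 0.5, 0.5, 3, 3, 2.5, 2)

.gen_daily_precip <- function(dates, annual_precip) {
  month <- as.integer(format(dates, "%m"))
  w <- .precip_weights / sum(.precip_weights)
  p_wet <- pmin(0.5, 0.12 * .precip_weights / mean(.precip_weights))
  shape <- 0.7
  ndays_m <- tabulate(as.integer(format(
    seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day"), "%m")), 12L)
  scale_m <- (annual_precip * w) / (ndays_m * p_wet * shape)
  wet <- stats::runif(length(dates)) < p_wet[month]
  amt <- numeric(length(dates))
  amt[wet] <- stats::rgamma(sum(wet), shape = shape, scale = scale_m[month][wet])
  data.frame(date = dates, precip = amt)
}

#' Generate a multi-year hourly temperature and precipitation series
#'
#' Temperature is an annual cosine (minimum 15 January) plus a diurnal
#' cosine (maximum 14:00) plus AR(1) noise; daily precipitation totals are
#' seasonally weighted gamma draws whose expectation matches the zone's
#' annual total. Fully reproducible from the config seed.
#'
#' @param config [synthetic_zone_config()].
#' @param years Number of calendar years.
#' @param start_year First calendar year.
#' @param station_id Label attached to the series.
#' @return List: `hourly` (an `hourly_series`), `daily_precip`
#'   (`data.frame(date, precip)`).
#' @export
generate_hourly_series <- function(config, years, start_year = 2010L,
                                   station_id = paste0("SYN-", config$zone)) {
  stopifnot(years >= 1)
  from <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  to <- as.POSIXct(sprintf("%d-12-31 23:00:00", start_year + years - 1L), tz = "UTC")
  hours <- seq(from, to, by = 3600)
  doy <- as.integer(format(hours, "%j"))
  hod <- as.integer(format(hours, "%H"))
  set.seed(config$seed)
  temp <- .temp_curve(config, doy, hod) +
    .ar1_noise(length(hours), config$ar1_phi, config$noise_sd)
  dates <- seq(as.Date(from, tz = "UTC"), as.Date(to, tz = "UTC"), by = "day")
  precip <- .gen_daily_precip(dates, config$annual_precip)
  hs <- hourly_series(hours, temp)
  attr(hs, "station_id") <- station_id
  attr(hs, "zone") <- config$zone
  list(hourly = hs, daily_precip = precip)
}

#' Generate sub-hourly weather-station observations
#'
#' Like [generate_hourly_series()] but sampled every `interval` minutes and
#' carrying the full observation record: temperature, relative humidity
#' (anti-correlated with temperature), mean wind and gust (gust always at or
#' above the mean in clean data) and per-interval precipitation. Used to
#' exercise the QC cascade.
#'
#' @inheritParams generate_hourly_series
#' @param interval Minutes between records (must divide 60).
#' @param days Number of days to generate.
#' @param start Start timestamp (POSIXct) or date string.
#' @return Observation `data.frame` with `record_interval` and `station_id`
#'   attributes.
#' @export
generate_observations <- function(config, days = 30,
                                  start = sprintf("%d-01-01", 2015L),
                                  interval = 10L,
                                  station_id = paste0("SYN-", config$zone)) {
  stopifnot(60L %% interval == 0L)
  from <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  ts <- seq(from, by = interval * 60, length.out = days * 24L * (60L / interval))
  doy <- as.integer(format(ts, "%j"))
  hod <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  set.seed(config$seed + 7L)
  phi_sub <- config$ar1_phi^(interval / 60)
  temp <- .temp_curve(config, doy, hod) +
    .ar1_noise(length(ts), phi_sub, config$noise_sd)
  humidity <- pmin(100, pmax(3, 85 - 1.8 * (temp - 10) + stats::rnorm(length(ts), 0, 5)))
  wind_mean <- pmin(30, stats::rlnorm(length(ts), log(1.8), 0.5))
  wind_gust <- wind_mean * (1.3 + abs(stats::rnorm(length(ts), 0, 0.3)))
  obs <- data.frame(timestamp = ts, temperature = temp, humidity = humidity,
                    wind_mean = wind_mean, wind_gust = wind_gust,
                    precipitation = 0)
  attr(obs, "record_interval") <- as.integer(interval)
  attr(obs, "station_id") <- station_id
  obs$station_id <- station_id
  obs
}

#' Generate a synthetic station network across climate zones
#'
#' Derives a distinct seed per station from the master seed, clusters
#' synthetic coordinates per zone (colder zones inland and higher), and
#' returns the ground-truth zone label of every station.
#'
#' @param zones Zone labels to include.
#' @param stations_per_zone Stations per zone.
#' @param years Years of hourly data per station.
#' @param seed Master seed.
#' @param start_year First calendar year.
#' @param ... Passed to [synthetic_zone_config()] (amplitudes, noise).
#' @return List: `stations` (metadata + `true_zone` + per-station `seed`),
#'   `series` (named list of [generate_hourly_series()] results).
#' @export
generate_network <- function(zones = c("B", "C", "D", "E"),
                             stations_per_zone = 3L, years = 10L, seed = 1L,
                             start_year = 2008L, ...) {
  stopifnot(length(zones) >= 1L)
  n <- length(zones) * stations_per_zone
  set.seed(seed)
  station_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  centers <- list(A = c(-2.1, 38.2, 1100), B = c(-1.9, 38.15, 900),
                  C = c(-1.6, 38.0, 600), D = c(-1.3, 37.9, 300),
                  E = c(-0.9, 37.7, 100))
  rows <- list(); series <- list(); k <- 0L
  for (z in zones) {
    for (i in seq_len(stations_per_zone)) {
      k <- k + 1L
      sid <- sprintf("SYN-%s-%02d", z, i)
      cfg <- synthetic_zone_config(z, seed = station_seeds[k], ...)
      ctr <- centers[[z]]
      rows[[k]] <- data.frame(
        station_id = sid, true_zone = z,
        longitude = ctr[1L] + stats::runif(1, -0.1, 0.1),
        latitude = ctr[2L] + stats::runif(1, -0.1, 0.1),
        altitude = ctr[3L] + stats::runif(1, -50, 50),
        record_interval = 60L, seed = station_seeds[k],
        stringsAsFactors = FALSE)
      series[[sid]] <- generate_hourly_series(cfg, years, start_year,
                                              station_id = sid)
    }
  }
  list(stations = do.call(rbind, rows), series = series)
}

#' Injection specification for QC and event ground truth
#'
#' @param physical,internal,step,stuck Counts of planted violations of each
#'   type (level-1 out-of-range humidity, level-3 wind mean above gust,
#'   level-2 temperature step spikes, level-4 stuck-sensor windows).
#' @param frost_runs `data.frame(duration, temp)`: frost episodes to plant
#'   (duration in hours, temp deg C).
#' @param stuck_hours Length of each stuck window, hours.
#' @return List of class `injection_spec`.
#' @export
injection_spec <- function(physical = 0L, internal = 0L, step = 0L,
                           stuck = 0L, frost_runs = NULL, stuck_hours = 24L) {
  structure(list(physical = physical, internal = internal, step = step,
                 stuck = stuck, frost_runs = frost_runs,
                 stuck_hours = stuck_hours),
            class = "injection_spec")
}

#' Plant labelled violations and frost runs into clean observations
#'
#' Positions are random but non-overlapping (with a safety margin so a
#' planted step spike cannot touch another plant); each plant is recorded in
#' the returned label table for recall scoring.
#'
#' @param obs Clean observation data.frame (from [generate_observations()]).
#' @param spec [injection_spec()].
#' @param seed Seed for placement.
#' @return List: `observations` (corrupted), `labels`
#'   (`data.frame(type, index, index_end, timestamp)`).
#' @export
inject_violations <- function(obs, spec, seed = 1L) {
  n <- nrow(obs)
  interval <- attr(obs, "record_interval") %||% 60L
  slots_per_hour <- 60L %/% as.integer(interval)
  n_frost <- if (is.null(spec$frost_runs)) 0L else nrow(spec$frost_runs)
  total <- spec$physical + spec$internal + spec$step + spec$stuck + n_frost
  if (total > n / 10) stop("too many injections for series length")
  set.seed(seed)
  occupied <- rep(FALSE, n)
  margin <- 2L * slots_per_hour
  place <- function(len) {
    for (try in 1:2000) {
      s <- sample.int(n - len - margin, 1L) + margin %/% 2L
      span <- max(1L, s - margin):min(n, s + len - 1L + margin)
      if (!any(occupied[span])) {
        occupied[span] <<- TRUE
        return(s)
      }
    }
    stop("could not place injection without overlap")
  }
  labels <- list()
  mark <- function(type, s, e) labels[[length(labels) + 1L]] <<- data.frame(
    type = type, index = s, index_end = e, timestamp = obs$timestamp[s],
    stringsAsFactors = FALSE)
  for (i in seq_len(spec$physical)) {
    s <- place(1L); obs$humidity[s] <- 105; mark("physical", s, s)
  }
  for (i in seq_len(spec$internal)) {
    s <- place(1L); obs$wind_mean[s] <- obs$wind_gust[s] + 2; mark("internal", s, s)
  }
  for (i in seq_len(spec$step)) {
    s <- place(1L); obs$temperature[s] <- obs$temperature[s] + 15; mark("step", s, s)
  }
  stuck_len <- as.integer(spec$stuck_hours * slots_per_hour)
  for (i in seq_len(spec$stuck)) {
    s <- place(stuck_len); e <- s + stuck_len - 1L
    obs$temperature[s:e] <- obs$temperature[s]
    mark("stuck", s, e)
  }
  if (n_frost > 0L) for (i in seq_len(n_frost)) {
    len <- as.integer(spec$frost_runs$duration[i] * slots_per_hour)
    s <- place(len); e <- s + len - 1L
    obs$temperature[s:e] <- spec$frost_runs$temp[i]
    mark("frost", s, e)
  }
  labels <- if (length(labels)) do.call(rbind, labels)
            else data.frame(type = character(0), index = integer(0),
                            index_end = integer(0),
                            timestamp = as.POSIXct(character(0), tz = "UTC"))
  list(observations = obs, labels = labels)
}
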