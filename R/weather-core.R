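#' Station metadata record
#'
#' Describes an automatic agrometeorological station. Temperature is assumed
#' measured at 150 cm and wind at 200 cm, the convention of the Spanish
#' automatic-station standards; `record_interval` is the native logging step
#' in minutes (10 for the Murcia network, 30 elsewhere).
#'
#' @param station_id Character identifier, unique within a network.
#' @param name,province,network Free-text descriptors.
#' @param latitude,longitude Decimal degrees (WGS84).
#' @param altitude Metres above sea level.
#' @param record_interval Logging interval in minutes; must divide 60.
#' @return A one-row `data.frame` of class `station_metadata`.
#' @export
station_metadata <- function(station_id, latitude, longitude,
                             name = station_id, province = "", altitude = NA_real_,
                             network = "", record_interval = 30L) {
  stopifnot(is.character(station_id), length(station_id) == 1L)
  if (!is.finite(latitude) || latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90]")
  if (!is.finite(longitude) || longitude < -180 || longitude > 180)
    stop("longitude must be in [-180, 180]")
  record_interval <- as.integer(record_interval)
  if (record_interval < 1L || 60L %% record_interval != 0L)
    stop("record_interval must divide 60")
  out <- data.frame(
    station_id = station_id, name = name, province = province,
    latitude = latitude, longitude = longitude, altitude = altitude,
    network = network, record_interval = record_interval,
    stringsAsFactors = FALSE
  )
  class(out) <- c("station_metadata", class(out))
  out
}

# canonical observation columns in file order
.obs_columns <- c("timestamp", "temperature", "humidity",
                  "wind_mean", "wind_gust", "precipitation")

.parse_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  out
}

#' Read a station CSV of sub-hourly weather observations
#'
#' Expects a header with a `timestamp` column (ISO 8601, local standard time)
#' and any subset of `temperature`, `humidity`, `wind_mean`, `wind_gust`,
#' `precipitation`. Rows with unparseable timestamps are skipped and counted;
#' duplicate timestamps are collapsed to the last occurrence with a warning.
#'
#' @param path Path to a CSV file.
#' @param metadata Optional [station_metadata()]; its `station_id` and
#'   `record_interval` are attached to the result.
#' @return A `data.frame` of observations sorted by timestamp, with attributes
#'   `n_skipped` (unparseable rows) and `n_duplicates` (collapsed rows).
#' @export
read_station_csv <- function(path, metadata = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  if (nrow(raw) == 0L) {
    warning("empty observation file: ", path)
    obs <- empty_observations()
  } else {
    if (!"timestamp" %in% names(raw))
      stop("station CSV must have a 'timestamp' column: ", path)
    ts <- suppressWarnings(.parse_timestamp(raw$timestamp))
    bad <- is.na(ts)
    n_skipped <- sum(bad)
    raw <- raw[!bad, , drop = FALSE]
    ts <- ts[!bad]
    obs <- data.frame(timestamp = ts)
    for (v in setdiff(.obs_columns, "timestamp")) {
      obs[[v]] <- if (v %in% names(raw))
        suppressWarnings(as.numeric(raw[[v]])) else NA_real_
    }
    ord <- order(obs$timestamp)
    obs <- obs[ord, , drop = FALSE]
    dup <- duplicated(obs$timestamp, fromLast = TRUE)
    n_dup <- sum(dup)
    if (n_dup > 0L) {
      warning(n_dup, " duplicate timestamp(s) collapsed to last occurrence")
      obs <- obs[!dup, , drop = FALSE]
    }
    rownames(obs) <- NULL
    attr(obs, "n_skipped") <- n_skipped
    attr(obs, "n_duplicates") <- n_dup
  }
  if (!is.null(metadata)) {
    obs$station_id <- if (nrow(obs)) metadata$station_id else character(0)
    attr(obs, "record_interval") <- metadata$record_interval
  }
  obs
}

empty_observations <- function() {
  obs <- data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"))
  for (v in setdiff(.obs_columns, "timestamp")) obs[[v]] <- numeric(0)
  attr(obs, "n_skipped") <- 0L
  attr(obs, "n_duplicates") <- 0L
  obs
}

#' Write observations back to the station CSV layout
#'
#' Inverse of [read_station_csv()]: the written file re-reads to identical
#' timestamps and values.
#'
#' @param obs Observation data.frame.
#' @param path Output path.
#' @export
write_station_csv <- function(obs, path) {
  out <- obs[, intersect(.obs_columns, names(obs)), drop = FALSE]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Resample sub-hourly observations to hourly means
#'
#' Each clock hour `h` covers the half-open interval `[h, h+1)`. The hourly
#' mean temperature is the arithmetic mean of the valid (non-missing)
#' sub-hourly temperatures in the hour; `coverage` is the fraction of expected
#' sub-hourly slots with a valid temperature, and hours with coverage below
#' `min_coverage` are gap-masked (no temperature). Masked hours are never
#' interpolated here.
#'
#' @param obs Observations from a single station, sorted by timestamp.
#' @param min_coverage Minimum fraction of expected slots, in (0, 1].
#' @param record_interval Native interval in minutes; taken from the
#'   `record_interval` attribute when missing, else inferred from the median
#'   time step.
#' @return A `data.frame` of class `hourly_series` with columns `hour`,
#'   `temperature`, `coverage`, `gap`, contiguous at a 1-hour step.
#' @export
resample_to_hourly <- function(obs, min_coverage = 0.8, record_interval = NULL) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  if ("station_id" %in% names(obs) && length(unique(obs$station_id)) > 1L)
    stop("resample_to_hourly expects observations from a single station")
  if (nrow(obs) == 0L) return(hourly_series(as.POSIXct(character(0), tz = "UTC"),
                                            numeric(0), numeric(0)))
  if (is.null(record_interval)) record_interval <- attr(obs, "record_interval")
  if (is.null(record_interval)) {
    steps <- as.numeric(diff(obs$timestamp), units = "mins")
    record_interval <- if (length(steps)) stats::median(steps) else 60
  }
  slots <- 60 / record_interval
  hour <- as.POSIXct(trunc(obs$timestamp, "hours"), tz = "UTC")
  dt <- data.table::data.table(hour = hour, temperature = obs$temperature)
  agg <- dt[, list(mean_temp = mean(temperature[!is.na(temperature)]),
                   n_valid = sum(!is.na(temperature))), by = "hour"]
  full <- data.table::data.table(
    hour = seq(min(agg$hour), max(agg$hour), by = 3600))
  agg <- agg[full, on = "hour"]
  agg[is.na(agg$n_valid), "n_valid"] <- 0L
  coverage <- pmin(agg$n_valid / slots, 1)
  temp <- agg$mean_temp
  temp[!is.finite(temp)] <- NA_real_
  gap <- coverage < min_coverage
  temp[gap] <- NA_real_
  out <- hourly_series(agg$hour, temp, coverage, gap)
  if ("station_id" %in% names(obs)) attr(out, "station_id") <- obs$station_id[1L]
  out
}

#' Construct an hourly series container
#'
#' @param hour POSIXct hour-start timestamps (UTC-encoded local standard time).
#' @param temperature Hourly mean temperature, deg C; NA where gap-masked.
#' @param coverage Fraction of expected sub-hourly records present, in [0, 1].
#' @param gap Logical gap mask; defaults to `coverage < 1` only when
#'   temperature is missing.
#' @return `data.frame` of class `hourly_series`.
#' @export
hourly_series <- function(hour, temperature,
                          coverage = rep(1, length(hour)),
                          gap = is.na(temperature)) {
  stopifnot(length(hour) == length(temperature),
            length(coverage) == length(hour), length(gap) == length(hour))
  out <- data.frame(hour = hour, temperature = temperature,
                    coverage = coverage, gap = gap)
  class(out) <- c("hourly_series", class(out))
  out
}

#' Parse an NGSI-LD-flavoured sensor entity document
#'
#' Accepts one JSON entity (a device or sensor) with `id`, `type`, an optional
#' `location` GeoProperty, and any number of `Property` attributes carrying a
#' numeric `value` and optionally `observedAt`. A property may carry its own
#' `location` whose third (Z) coordinate encodes measurement depth in cm
#' (negative below ground), the convention used for multi-depth soil-moisture
#' probes. Non-numeric property values are skipped with a warning; unknown
#' attributes are preserved in `raw`.
#'
#' @param document JSON text or a path to a JSON file.
#' @return A list with `id`, `type`, `location` (lon, lat and optional `z`),
#'   `measurements` (data.frame: `property`, `value`, `observed_at`, `depth`)
#'   and `raw` (the untouched attribute list).
#' @export
parse_ngsild_entity <- function(document) {
  ent <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  if (is.null(ent$id) || is.null(ent$type))
    stop("NGSI-LD entity must have 'id' and 'type'")
  geo_coords <- function(attr) {
    cc <- tryCatch(attr$value$coordinates, error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    unlist(cc)
  }
  loc <- NULL
  if (!is.null(ent$location)) {
    cc <- geo_coords(ent$location)
    if (!is.null(cc))
      loc <- list(longitude = cc[1L], latitude = cc[2L],
                  z = if (length(cc) >= 3L) cc[3L] else NA_real_)
  }
  reserved <- c("id", "type", "location", "@context")
  props <- ent[setdiff(names(ent), reserved)]
  rows <- list()
  for (nm in names(props)) {
    a <- props[[nm]]
    if (!is.list(a) || is.null(a$type) || !identical(a$type, "Property")) next
    val <- a$value
    if (!(is.numeric(val) && length(val) == 1L && is.finite(val))) {
      warning("non-numeric value for property '", nm, "' skipped")
      next
    }
    depth <- NA_real_
    if (!is.null(a$location)) {
      cc <- geo_coords(a$location)
      if (!is.null(cc) && length(cc) >= 3L) depth <- cc[3L]
    }
    if (is.na(depth) && !is.null(loc)) depth <- loc$z
    rows[[nm]] <- data.frame(
      property = nm, value = as.numeric(val),
      observed_at = if (is.null(a$observedAt)) NA_character_ else a$observedAt,
      depth = depth, stringsAsFactors = FALSE)
  }
  meas <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
          else data.frame(property = character(0), value = numeric(0),
                          observed_at = character(0), depth = numeric(0))
  list(id = ent$id, type = ent$type, location = loc,
       measurements = meas, raw = props)
}
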