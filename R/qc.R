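#' Quality-control thresholds for the six-level validation cascade
#'
#' Configurable limits for the real-time validation of automatic-station
#' records (UNE 500540:2004 style). Levels: (1) rigid physical/instrumental
#' limits plus flexible monthly ephemerides, (2) temporal coherence (maximum
#' step between consecutive native-interval records), (3) internal consistency
#' between co-measured variables, (4) time-series consistency (stuck-sensor
#' low-variance windows), (5) spatial consistency against neighbour stations,
#' (6) visual inspection, represented only as an exported review report.
#'
#' All intervals are closed: a value exactly at a bound is valid. The paper
#' trail behind the defaults: physical limits are standard Mediterranean
#' station ranges (only the 100% humidity bound is prescribed); step limits,
#' low-variance minima and the IDW estimator are conventional choices, all
#' overridable here.
#'
#' @param physical_limits,instrumental_limits Named list of `c(min, max)` per
#'   variable; the intersection (most restrictive) is the rigid limit.
#' @param ephemerides Optional named list: per variable, a 12-row matrix or
#'   list of `c(min, max)` monthly extremes (flexible limits -> suspect).
#' @param max_step Named numeric: maximum absolute change per native interval.
#' @param min_std,min_range Named numeric: minimum acceptable standard
#'   deviation / max pairwise difference over a level-4 window.
#' @param window_length Level-4 window, hours.
#' @param spatial_residual_max Named numeric: maximum |measured - estimated|.
#' @param min_neighbors Minimum simultaneous neighbour records for level 5.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(
    physical_limits = list(temperature = c(-30, 50), humidity = c(0, 100),
                           wind_mean = c(0, 60), wind_gust = c(0, 60),
                           precipitation = c(0, 100)),
    instrumental_limits = list(temperature = c(-40, 60), humidity = c(0, 100),
                               wind_mean = c(0, 75), wind_gust = c(0, 75),
                               precipitation = c(0, 120)),
    ephemerides = NULL,
    max_step = c(temperature = 4, humidity = 20),
    min_std = c(temperature = 0.05),
    min_range = c(temperature = 0.5),
    window_length = 24,
    spatial_residual_max = c(temperature = 5),
    min_neighbors = 2L) {
  chk <- function(lims) for (v in names(lims))
    if (lims[[v]][1L] > lims[[v]][2L]) stop("limits for ", v, " not ordered")
  chk(physical_limits); chk(instrumental_limits)
  stopifnot(all(max_step > 0), window_length >= 1)
  structure(list(
    physical_limits = physical_limits,
    instrumental_limits = instrumental_limits,
    ephemerides = ephemerides,
    max_step = max_step, min_std = min_std, min_range = min_range,
    window_length = window_length,
    spatial_residual_max = spatial_residual_max,
    min_neighbors = as.integer(min_neighbors)
  ), class = "qc_thresholds")
}

.qc_flag_frame <- function(index = integer(0), variable = character(0),
                           level = integer(0), status = character(0),
                           reason = character(0)) {
  data.frame(index = as.integer(index), variable = variable,
             level = as.integer(level), status = status, reason = reason,
             stringsAsFactors = FALSE)
}

.qc_vars <- function(obs) intersect(
  c("temperature", "humidity", "wind_mean", "wind_gust", "precipitation"),
  names(obs))

#' Level 1: rigid and flexible fixed-limit validation
#'
#' Applies the most restrictive of the physical and instrumental bounds:
#' values outside are invalid (reason `physical` or `instrumental`, whichever
#' bound bites). Values inside the rigid limits but outside the monthly
#' ephemeride extremes are suspect (reason `ephemerides`).
#'
#' @param obs Observation data.frame.
#' @param thresholds A [qc_thresholds()] object.
#' @return Flag data.frame (`index`, `variable`, `level`, `status`, `reason`).
#' @export
validate_fixed_limits <- function(obs, thresholds = qc_thresholds()) {
  flags <- list()
  month <- as.integer(format(obs$timestamp, "%m"))
  for (v in .qc_vars(obs)) {
    phys <- thresholds$physical_limits[[v]]
    inst <- thresholds$instrumental_limits[[v]]
    if (is.null(phys) && is.null(inst)) {
      warning("no fixed limits configured for '", v, "'; skipped")
      next
    }
    if (is.null(phys)) phys <- c(-Inf, Inf)
    if (is.null(inst)) inst <- c(-Inf, Inf)
    lo <- max(phys[1L], inst[1L]); hi <- min(phys[2L], inst[2L])
    x <- obs[[v]]
    out <- which(!is.na(x) & (x < lo | x > hi))
    if (length(out)) {
      # name the bound that bites: outside physical -> physical
      phys_hit <- x[out] < phys[1L] | x[out] > phys[2L]
      flags[[length(flags) + 1L]] <- .qc_flag_frame(
        out, v, 1L, "invalid", ifelse(phys_hit, "physical", "instrumental"))
    }
    eph <- thresholds$ephemerides[[v]]
    if (!is.null(eph)) {
      emin <- vapply(month, function(m) eph[[m]][1L], numeric(1))
      emax <- vapply(month, function(m) eph[[m]][2L], numeric(1))
      sus <- which(!is.na(x) & x >= lo & x <= hi & (x < emin | x > emax))
      if (length(sus))
        flags[[length(flags) + 1L]] <- .qc_flag_frame(
          sus, v, 1L, "suspect", "ephemerides")
    }
  }
  if (length(flags)) do.call(rbind, flags) else .qc_flag_frame()
}

#' Level 2: temporal coherence between consecutive records
#'
#' Compares each pair of records one native interval apart; if the absolute
#' change exceeds the per-variable `max_step`, both records become suspect
#' (reason `step`). Pairs separated by more than the native interval (gaps)
#' are not compared.
#'
#' @inheritParams validate_fixed_limits
#' @param record_interval Native interval in minutes; inferred as in
#'   [resample_to_hourly()] when missing.
#' @export
validate_temporal_coherence <- function(obs, thresholds = qc_thresholds(),
                                        record_interval = NULL) {
  if (nrow(obs) < 2L) return(.qc_flag_frame())
  if (is.null(record_interval)) record_interval <- attr(obs, "record_interval")
  if (is.null(record_interval))
    record_interval <- stats::median(as.numeric(diff(obs$timestamp), units = "mins"))
  gap_ok <- as.numeric(diff(obs$timestamp), units = "mins") <= record_interval + 1e-6
  flags <- list()
  for (v in intersect(names(thresholds$max_step), .qc_vars(obs))) {
    x <- obs[[v]]
    d <- abs(diff(x))
    hit <- which(gap_ok & !is.na(d) & d > thresholds$max_step[[v]])
    if (length(hit))
      flags[[length(flags) + 1L]] <- .qc_flag_frame(
        sort(unique(c(hit, hit + 1L))), v, 2L, "suspect", "step")
  }
  if (length(flags)) do.call(rbind, flags) else .qc_flag_frame()
}

#' Level 3: internal consistency between co-measured variables
#'
#' The mean wind speed cannot exceed the gust (equality allowed). Records
#' violating a rule are invalid (reason `internal`); rules whose operands are
#' missing are skipped for that record.
#'
#' @inheritParams validate_fixed_limits
#' @export
validate_internal_consistency <- function(obs) {
  if (!all(c("wind_mean", "wind_gust") %in% names(obs))) return(.qc_flag_frame())
  bad <- which(!is.na(obs$wind_mean) & !is.na(obs$wind_gust) &
                 obs$wind_mean > obs$wind_gust)
  if (length(bad)) .qc_flag_frame(bad, "wind_mean", 3L, "invalid", "internal")
  else .qc_flag_frame()
}

#' Level 4: time-series consistency (stuck-sensor windows)
#'
#' Over non-overlapping windows of `window_length` hours, every record in a
#' window becomes suspect when the standard deviation of a variable is below
#' `min_std` (reason `low_std`) or the largest pairwise difference is below
#' `min_range` (reason `low_range`). Windows with fewer than two valid values
#' are skipped. Only the low-variance direction is tested; an
#' excessive-variance converse is not part of the cascade.
#'
#' @inheritParams validate_fixed_limits
#' @export
validate_series_consistency <- function(obs, thresholds = qc_thresholds()) {
  if (nrow(obs) < 2L) return(.qc_flag_frame())
  t0 <- obs$timestamp[1L]
  win <- floor(as.numeric(difftime(obs$timestamp, t0, units = "hours")) /
                 thresholds$window_length)
  flags <- list()
  vars <- union(names(thresholds$min_std), names(thresholds$min_range))
  for (v in intersect(vars, .qc_vars(obs))) {
    x <- obs[[v]]
    for (w in unique(win)) {
      idx <- which(win == w & !is.na(x))
      if (length(idx) < 2L) next
      reason <- NULL
      ms <- thresholds$min_std[[v]]
      if (!is.null(ms) && stats::sd(x[idx]) < ms) reason <- "low_std"
      mr <- thresholds$min_range[[v]]
      if (is.null(reason) && !is.null(mr) && diff(range(x[idx])) < mr)
        reason <- "low_range"
      if (!is.null(reason))
        flags[[length(flags) + 1L]] <- .qc_flag_frame(
          which(win == w), v, 4L, "suspect", reason)
    }
  }
  if (length(flags)) do.call(rbind, flags) else .qc_flag_frame()
}

# great-circle distance in km (haversine)
.haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Level 5: spatial consistency against neighbour stations
#'
#' For each timestamp with at least `min_neighbors` simultaneous valid
#' neighbour values, an estimate is formed by inverse-distance-squared
#' weighting of the neighbours; records whose residual |measured - estimate|
#' exceeds `spatial_residual_max` become suspect (reason `spatial`).
#' Timestamps with too few neighbours are not tested.
#'
#' @param obs Target-station observations.
#' @param target_meta [station_metadata()] for the target.
#' @param neighbors List of `list(metadata = , obs = )` neighbour stations.
#' @param thresholds A [qc_thresholds()] object.
#' @export
validate_spatial_consistency <- function(obs, target_meta, neighbors,
                                         thresholds = qc_thresholds()) {
  if (length(neighbors) == 0L) {
    warning("no neighbour stations supplied; spatial level skipped")
    return(.qc_flag_frame())
  }
  flags <- list()
  for (v in intersect(names(thresholds$spatial_residual_max), .qc_vars(obs))) {
    est_num <- rep(0, nrow(obs)); est_den <- rep(0, nrow(obs))
    n_nb <- rep(0L, nrow(obs))
    for (nb in neighbors) {
      d <- .haversine_km(target_meta$latitude, target_meta$longitude,
                         nb$metadata$latitude, nb$metadata$longitude)
      w <- 1 / max(d, 0.1)^2
      m <- match(obs$timestamp, nb$obs$timestamp)
      val <- nb$obs[[v]][m]
      ok <- !is.na(val)
      est_num[ok] <- est_num[ok] + w * val[ok]
      est_den[ok] <- est_den[ok] + w
      n_nb[ok] <- n_nb[ok] + 1L
    }
    testable <- n_nb >= thresholds$min_neighbors & !is.na(obs[[v]])
    resid <- abs(obs[[v]] - est_num / est_den)
    hit <- which(testable & resid > thresholds$spatial_residual_max[[v]])
    if (length(hit))
      flags[[length(flags) + 1L]] <- .qc_flag_frame(hit, v, 5L, "suspect", "spatial")
  }
  if (length(flags)) do.call(rbind, flags) else .qc_flag_frame()
}

#' Run the full validation cascade and consolidate verdicts
#'
#' Applies levels 1-5 in order (level 5 only when neighbours are supplied) and
#' consolidates per record: any invalid flag makes the record invalid, else
#' any suspect flag makes it suspect, else it is valid. Level 6 (visual
#' inspection) is represented by the `review` report of suspect records for a
#' human; it never invalidates data. Downstream indicator code excludes
#' invalid temperatures and keeps (but counts) suspect ones.
#'
#' @inheritParams validate_spatial_consistency
#' @param record_interval Passed to [validate_temporal_coherence()].
#' @return List of class `qc_result`: `observations` (with `qc_status`
#'   column), `flags`, `review` (suspect records, the level-6 artifact) and
#'   `summary` (counts by level/status/reason).
#' @export
run_qc <- function(obs, thresholds = qc_thresholds(), target_meta = NULL,
                   neighbors = NULL, record_interval = NULL) {
  flags <- rbind(
    validate_fixed_limits(obs, thresholds),
    validate_temporal_coherence(obs, thresholds, record_interval),
    validate_internal_consistency(obs),
    validate_series_consistency(obs, thresholds),
    if (!is.null(neighbors) && !is.null(target_meta))
      validate_spatial_consistency(obs, target_meta, neighbors, thresholds)
    else .qc_flag_frame()
  )
  status <- rep("valid", nrow(obs))
  status[unique(flags$index[flags$status == "suspect"])] <- "suspect"
  status[unique(flags$index[flags$status == "invalid"])] <- "invalid"
  obs$qc_status <- status
  smry <- if (nrow(flags))
    stats::aggregate(list(n = flags$index),
                     flags[, c("level", "status", "reason")], length)
  else data.frame(level = integer(0), status = character(0),
                  reason = character(0), n = integer(0))
  review <- obs[status == "suspect", , drop = FALSE]
  structure(list(observations = obs, flags = flags,
                 review = review, summary = smry),
            class = "qc_result")
}

#' Drop invalid records' temperature before indicator computation
#'
#' @param qc A `qc_result`.
#' @return The observation data.frame with invalid temperatures set missing.
#' @export
qc_clean_observations <- function(qc) {
  obs <- qc$observations
  obs$temperature[obs$qc_status == "invalid"] <- NA_real_
  obs
}
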