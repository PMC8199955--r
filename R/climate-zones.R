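#' Monthly climatology of a station
#'
#' Monthly mean temperatures are pooled over all valid hours of all years;
#' monthly precipitation is the mean across years of the monthly totals.
#'
#' @param series `hourly_series` spanning at least one full year.
#' @param daily_precip `data.frame(date, precip)` daily totals (mm), same span.
#' @param station_id Optional label.
#' @return List of class `monthly_climatology`: `monthly` (12-row data.frame
#'   `month`, `mean_temp`, `precip`), `annual_mean_temp`, `annual_precip`.
#'   Months with no valid data yield `NA` and make classification refuse.
#' @export
monthly_climatology <- function(series, daily_precip = NULL,
                                station_id = attr(series, "station_id") %||% "") {
  month <- as.integer(format(series$hour, "%m"))
  tmp <- series$temperature
  mean_temp <- vapply(1:12, function(m) {
    x <- tmp[month == m & !is.na(tmp)]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  precip <- rep(NA_real_, 12L)
  if (!is.null(daily_precip)) {
    ym <- format(daily_precip$date, "%Y-%m")
    tot <- tapply(daily_precip$precip, ym, sum)
    mm <- as.integer(substr(names(tot), 6, 7))
    precip <- vapply(1:12, function(m) {
      x <- tot[mm == m]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
  }
  structure(list(
    station_id = station_id,
    monthly = data.frame(month = 1:12, mean_temp = mean_temp, precip = precip),
    annual_mean_temp = mean(mean_temp),
    annual_precip = sum(precip)
  ), class = "monthly_climatology")
}

.zone_descriptors <- c(A = "extremely cold", B = "cold", C = "intermediate",
                       D = "warm", E = "extremely warm")
.zone_koppen <- c(A = "Continental Mediterranean", B = "Continental Mediterranean",
                  C = "Littoral Mediterranean", D = "Littoral Mediterranean",
                  E = "Semi-Arid Mediterranean")

#' Zone boundaries on annual mean temperature
#'
#' Upper bounds (deg C) of zones A-D; zone E is unbounded above. The A/B
#' boundary sits between the extrapolated zone-A mean (7.5) and the observed
#' zone-B station mean (9.12); B/C and C/D are midpoints of the observed
#' zone means; D/E follows the 14 deg C convention.
#'
#' @export
zone_boundaries <- function() c(A = 8.5, B = 10.2, C = 12.1, D = 14)

zone_from_band <- function(annual_mean, boundaries = zone_boundaries()) {
  i <- findInterval(annual_mean, boundaries) + 1L
  c(names(boundaries), "E")[i]
}

#' Classify a station climatology into one of the five climate zones
#'
#' Zones run A (extremely cold) through E (extremely warm). The primary rule
#' counts months with mean temperature strictly below 10 deg C: five or more
#' cold months places the station in the Continental class (A/B, split by
#' annual mean at the A/B boundary); exactly three cold months falling in
#' December-February gives C; no cold months gives the warm class (D/E,
#' split at the D/E boundary). Profiles the month-count rule cannot place,
#' or whose annual mean falls outside the temperature band of the class the
#' rule selected, are assigned by annual-mean bands and flagged ambiguous.
#' A precipitation pattern check (months below 10 mm) is advisory only and
#' recorded in `notes`.
#'
#' @param clim A [monthly_climatology()].
#' @param boundaries Annual-mean boundaries, see [zone_boundaries()].
#' @param cold_month_temp Cold-month threshold, deg C (default 10).
#' @return List of class `climate_zone`: `label`, `descriptor`,
#'   `koppen_type`, `n_cold_months`, `ambiguous`, `notes`.
#' @export
classify_zone <- function(clim, boundaries = zone_boundaries(),
                          cold_month_temp = 10) {
  m <- clim$monthly
  if (any(is.na(m$mean_temp)))
    stop("incomplete climatology: month(s) without valid data")
  cold <- m$mean_temp < cold_month_temp
  ncold <- sum(cold)
  am <- clim$annual_mean_temp
  band <- zone_from_band(am, boundaries)
  notes <- character(0)
  ambiguous <- FALSE
  if (ncold >= 5L) {
    label <- if (am < boundaries[["A"]]) "A" else "B"
    if (!label %in% c("A", "B") || !band %in% c("A", "B")) {
      ambiguous <- TRUE
      notes <- c(notes, sprintf(
        "month-count class A/B conflicts with annual mean %.2f; using band %s",
        am, band))
      label <- band
    }
  } else if (ncold == 3L && all(which(cold) %in% c(12L, 1L, 2L))) {
    label <- "C"
    if (band != "C") {
      ambiguous <- TRUE
      notes <- c(notes, sprintf(
        "month-count class C conflicts with annual mean %.2f; using band %s",
        am, band))
      label <- band
    }
  } else if (ncold == 0L) {
    label <- if (am < boundaries[["D"]]) "D" else "E"
    if (!band %in% c("D", "E")) {
      ambiguous <- TRUE
      notes <- c(notes, sprintf(
        "month-count class D/E conflicts with annual mean %.2f; using band %s",
        am, band))
      label <- band
    }
  } else {
    ambiguous <- TRUE
    notes <- c(notes, sprintf(
      "ambiguous cold-month count %d; nearest band %s by annual mean", ncold, band))
    label <- band
  }
  if (!any(is.na(m$precip))) {
    dry_months <- sum(m$precip < 10, na.rm = TRUE)
    if (label %in% c("A", "B") && dry_months > 0)
      notes <- c(notes, "precipitation check: A/B expected no months < 10 mm")
  }
  structure(list(label = label,
                 descriptor = unname(.zone_descriptors[label]),
                 koppen_type = unname(.zone_koppen[label]),
                 n_cold_months = ncold, annual_mean_temp = am,
                 ambiguous = ambiguous, notes = notes),
            class = "climate_zone")
}

#' Ombrothermal table (Gaussen aridity by month)
#'
#' A month is Gaussen-dry when its precipitation in mm is below twice its
#' mean temperature in deg C; this is the table behind an ombrothermal
#' diagram.
#'
#' @param clim A [monthly_climatology()].
#' @return 12-row `data.frame(month, mean_temp, precip, gaussen_dry)`.
#' @export
ombrothermal_table <- function(clim) {
  m <- clim$monthly
  data.frame(month = m$month, mean_temp = m$mean_temp, precip = m$precip,
             gaussen_dry = m$precip < 2 * m$mean_temp)
}
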