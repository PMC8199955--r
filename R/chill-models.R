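#' Chill-model parameters
#'
#' Bundles the parameters of the three winter-chill accumulation models run
#' on hourly mean temperatures.
#'
#' * **Chilling Hours** (Weinberger): count of hours with temperature in the
#'   closed band `ch_bounds`, default 0-7 deg C (the 7.2 deg C variant is a
#'   config choice).
#' * **Utah Cold Units** (Richardson): a weighted count; the default weight
#'   table is the standard Richardson table, with full chill (+1 CU/h) at
#'   2.5-9.1 deg C, partial chill out to 12.4 deg C, and negative weights
#'   above 15.9 deg C.
#' * **Dynamic / Chill Portions** (Fishman-Erez-Couvillon): a two-step
#'   kinetic recursion in which an intermediate product accumulates towards a
#'   temperature-dependent equilibrium and converts irreversibly to a Chill
#'   Portion once it reaches the critical level 1. `dynamic_constants` are
#'   the standard published values; temperatures are converted to kelvin
#'   inside the recursion.
#'
#' @param ch_bounds Closed `c(low, high)` band for Chilling Hours, deg C.
#' @param utah_weights `data.frame(upper, weight)`: weight applies to
#'   temperatures in `(previous upper, upper]`; the uppers must increase and
#'   end at `Inf`, so the intervals partition the line.
#' @param dynamic_constants Named list `slp`, `tetmlt` (K), `a0`, `e0`, `a1`,
#'   `e1` for the kinetic recursion.
#' @return List of class `chill_params`.
#' @export
chill_params <- function(
    ch_bounds = c(0, 7),
    utah_weights = data.frame(
      upper = c(1.4, 2.4, 9.1, 12.4, 15.9, 18, Inf),
      weight = c(0, 0.5, 1, 0.5, 0, -0.5, -1)),
    dynamic_constants = list(slp = 1.6, tetmlt = 277, a0 = 139500,
                             e0 = 4153.5, a1 = 2.567e18, e1 = 12888.8)) {
  stopifnot(length(ch_bounds) == 2L, ch_bounds[1L] <= ch_bounds[2L],
            all(diff(utah_weights$upper) > 0),
            is.infinite(utah_weights$upper[nrow(utah_weights)]),
            all(unlist(dynamic_constants) > 0))
  structure(list(ch_bounds = ch_bounds, utah_weights = utah_weights,
                 dynamic_constants = dynamic_constants),
            class = "chill_params")
}

.chill_series <- function(series, value, model, n_missing) {
  out <- data.frame(hour = series$hour, temperature = series$temperature,
                    value = value, cumulative = cumsum(value))
  attr(out, "model") <- model
  attr(out, "n_missing") <- n_missing
  class(out) <- c("chill_series", class(out))
  out
}

#' Chilling Hours model
#'
#' One Chilling Hour per hour whose mean temperature lies in the closed band
#' `ch_bounds` (default 0-7 deg C). Gap-masked hours contribute 0 and are
#' counted as missing.
#'
#' @param series An `hourly_series`.
#' @param params [chill_params()].
#' @return A `chill_series` data.frame (`hour`, `temperature`, `value`,
#'   `cumulative`) with attribute `n_missing`.
#' @export
chilling_hours <- function(series, params = chill_params()) {
  t <- series$temperature
  v <- as.numeric(!series$gap & !is.na(t) &
                    t >= params$ch_bounds[1L] & t <= params$ch_bounds[2L])
  .chill_series(series, v, "chilling_hours", sum(series$gap))
}

# per-hour Utah weight lookup; intervals (upper[i-1], upper[i]]
utah_weight <- function(temp, params = chill_params()) {
  uw <- params$utah_weights
  idx <- findInterval(temp, uw$upper, left.open = TRUE) + 1L
  uw$weight[idx]
}

#' Utah Cold Units model
#'
#' Each hour contributes the Richardson weight for its temperature interval;
#' weights may be negative, so the cumulative can decrease. Gap-masked hours
#' contribute 0 and are counted as missing.
#'
#' @inheritParams chilling_hours
#' @export
utah_units <- function(series, params = chill_params()) {
  t <- series$temperature
  v <- numeric(nrow(series))
  ok <- !series$gap & !is.na(t)
  v[ok] <- utah_weight(t[ok], params)
  .chill_series(series, v, "utah", sum(series$gap))
}

#' Dynamic (Chill Portions) model
#'
#' Two-step kinetic recursion: per hour, an intermediate product relaxes
#' towards the temperature-dependent equilibrium `xs = (a0/a1) exp((e1-e0)/TK)`
#' at rate `ak1 = a1 exp(-e1/TK)`; once it reaches 1 it converts irreversibly,
#' the converted fraction `xi = sr/(1+sr)` (with
#' `sr = exp(slp tetmlt (TK - tetmlt)/TK)`) being banked as Chill Portions.
#' The cumulative is therefore non-decreasing. Masked hours advance time with
#' the state held (no accumulation, no decay).
#'
#' @inheritParams chilling_hours
#' @param state Optional saved recursion state (from a previous call's
#'   `state` attribute) to resume a split series exactly.
#' @export
chill_portions <- function(series, params = chill_params(), state = NULL) {
  dc <- params$dynamic_constants
  t <- series$temperature
  ok <- !series$gap & !is.na(t)
  if (any(!is.finite(t[ok]))) stop("non-finite temperature in unmasked hour")
  n <- length(t)
  delta <- numeric(n)
  if (is.null(state)) state <- list(inter = 0, xi = 0)
  inter_prev <- state$inter
  xi_prev <- state$xi
  if (any(ok)) {
    TK <- t[ok] + 273
    sr <- exp(dc$slp * dc$tetmlt * (TK - dc$tetmlt) / TK)
    xi <- sr / (1 + sr)
    xs <- (dc$a0 / dc$a1) * exp((dc$e1 - dc$e0) / TK)
    ek <- exp(-dc$a1 * exp(-dc$e1 / TK))
    idx <- which(ok)
    d <- numeric(length(idx))
    for (i in seq_along(idx)) {
      inter_s <- if (inter_prev < 1) inter_prev else inter_prev * (1 - xi_prev)
      inter_e <- xs[i] - (xs[i] - inter_s) * ek[i]
      d[i] <- if (inter_e < 1) 0 else xi[i] * inter_e
      inter_prev <- inter_e
      xi_prev <- xi[i]
    }
    delta[idx] <- d
  }
  out <- .chill_series(series, delta, "dynamic", sum(series$gap))
  attr(out, "state") <- list(inter = inter_prev, xi = xi_prev)
  out
}

# ISO week id "GGGG-WVV" and week-start date for ordering
.iso_week_key <- function(hour) {
  data.frame(iso_year = as.integer(format(hour, "%G")),
             iso_week = as.integer(format(hour, "%V")))
}

#' Aggregate a chill series to ISO weeks
#'
#' One record per ISO-8601 week intersecting the series, in chronological
#' order (the season sequence runs ~week 36 through 52, then 1 through 26
#' across New Year). `cumulative` is the running total since the start of the
#' series (the count start); `n_records` counts valid (unmasked) hours.
#'
#' @param chill A `chill_series`.
#' @return `data.frame(iso_year, iso_week, week_start, weekly_sum, cumulative,
#'   n_records)`.
#' @export
weekly_aggregate <- function(chill) {
  wk <- .iso_week_key(chill$hour)
  dt <- data.table::data.table(
    iso_year = wk$iso_year, iso_week = wk$iso_week, hour = chill$hour,
    value = chill$value, valid = !is.na(chill$temperature))
  agg <- dt[, list(week_start = min(hour), weekly_sum = sum(value),
                   n_records = sum(valid)),
            by = c("iso_year", "iso_week")]
  agg <- agg[order(agg$week_start), ]
  out <- as.data.frame(agg)
  out$cumulative <- cumsum(out$weekly_sum)
  out[, c("iso_year", "iso_week", "week_start", "weekly_sum",
          "cumulative", "n_records")]
}
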