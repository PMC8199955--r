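#' Load the varietal chilling-requirement table
#'
#' The packaged default quantifies, per stone-fruit crop and varietal group,
#' the accumulated cold base (in Utah Cold Units) a cultivar group must meet
#' before it switches to heat accumulation, plus the group's printed chill
#' range and its "heat start" figure (carried through verbatim; it is
#' reported but not used as a suitability criterion, since no heat model is
#' defined). Crops: peach (5 groups), apricot (4), japanese_plum (3),
#' sweet_cherry (3).
#'
#' @param path CSV with columns `crop`, `accumulated_cold_base`,
#'   `group_label`, `group_range`, `heat_start`; defaults to the packaged
#'   table.
#' @return `data.frame` of class `varietal_requirements`.
#' @export
load_requirements <- function(path = system.file("extdata",
                                                 "varietal_requirements.csv",
                                                 package = "chillsuit")) {
  req <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("crop", "accumulated_cold_base", "group_label", "group_range",
              "heat_start")
  if (!all(needed %in% names(req)))
    stop("requirements table must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(req[, c("crop", "group_label")]))
    stop("duplicate (crop, group_label) rows in requirements table")
  if (any(req$accumulated_cold_base <= 0))
    stop("accumulated_cold_base must be positive")
  class(req) <- c("varietal_requirements", class(req))
  req
}

#' Look up one varietal group's requirement
#'
#' @param requirements [load_requirements()] output.
#' @param crop,group_label Row key.
#' @return The matching one-row data.frame; error if absent.
#' @export
requirement_for <- function(requirements, crop, group_label) {
  row <- requirements[requirements$crop == crop &
                        requirements$group_label == group_label, , drop = FALSE]
  if (nrow(row) == 0L) stop("no requirement for (", crop, ", ", group_label, ")")
  row
}

# chill-class -> frost earliness group: lower-chill groups flower earlier
.earliness_of_group <- function(group_label) {
  switch(group_label,
         "Very Low" = "I", "Low" = "I",
         "Medium" = "II", "Medium-High" = "II",
         "High" = "III",
         stop("unknown varietal group label: ", group_label))
}

#' Build a site profile from seasonal chill and frost risk
#'
#' The safe chill of a site is a lower percentile (default the 20th) of the
#' seasonal Utah totals across years: the chill met or exceeded in about 80%
#' of years. The analogous percentile of seasonal Portions and the per-group
#' frost probabilities complete the profile.
#'
#' @param season_summaries Row-bound [season_chill_summary()] rows (>= 3
#'   seasons for full confidence).
#' @param frost_p Named numeric, probability of a damaging frost year per
#'   earliness group (`I`, `II`, `III`).
#' @param zone Optional [classify_zone()] result.
#' @param percentile Lower percentile (0-100) defining "safe".
#' @param location_id Label.
#' @return List of class `site_profile` with `safe_cu`, `safe_portions`,
#'   `frost_p`, `n_seasons`, `low_confidence`.
#' @export
site_profile <- function(season_summaries, frost_p = c(I = 0, II = 0, III = 0),
                         zone = NULL, percentile = 20, location_id = "") {
  stopifnot(percentile > 0, percentile < 100,
            all(frost_p >= 0), all(frost_p <= 1))
  cu <- season_summaries$total_cu_at_end
  cp <- season_summaries$total_portions_at_end
  n <- nrow(season_summaries)
  structure(list(
    location_id = location_id, zone = zone,
    safe_cu = unname(stats::quantile(cu, percentile / 100)),
    safe_portions = unname(stats::quantile(cp, percentile / 100)),
    frost_p = frost_p, n_seasons = n,
    low_confidence = n < 3L
  ), class = "site_profile")
}

#' Recommend varietal groups for a site
#'
#' One verdict per requirement row: a group is suitable iff the site's safe
#' chill meets its accumulated cold base AND the frost probability for the
#' group's earliness class does not exceed `frost_threshold`. Output is
#' sorted by descending chill margin; `reasons` names each failing
#' criterion.
#'
#' @param site [site_profile()].
#' @param requirements [load_requirements()] output.
#' @param frost_threshold Maximum acceptable frost probability.
#' @return `data.frame` of class `recommendations`: `crop`, `group_label`,
#'   `suitable`, `margin_cu`, `frost_ok`, `earliness`, `heat_start`,
#'   `reasons`.
#' @export
recommend <- function(site, requirements = load_requirements(),
                      frost_threshold = 0.2) {
  earliness <- vapply(requirements$group_label, .earliness_of_group, character(1))
  margin <- site$safe_cu - requirements$accumulated_cold_base
  fp <- site$frost_p[earliness]
  fp[is.na(fp)] <- 0
  frost_ok <- unname(fp <= frost_threshold)
  suitable <- margin >= 0 & frost_ok
  reasons <- mapply(function(m, f) {
    r <- character(0)
    if (m < 0) r <- c(r, "insufficient_chill")
    if (!f) r <- c(r, "frost_risk")
    if (length(r) == 0L) "ok" else paste(r, collapse = ";")
  }, margin, frost_ok)
  out <- data.frame(
    crop = requirements$crop, group_label = requirements$group_label,
    suitable = suitable, margin_cu = margin, frost_ok = frost_ok,
    earliness = unname(earliness), heat_start = requirements$heat_start,
    reasons = unname(reasons), stringsAsFactors = FALSE)
  out <- out[order(-out$margin_cu), ]
  rownames(out) <- NULL
  class(out) <- c("recommendations", class(out))
  out
}
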