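#' Default pipeline configuration
#'
#' Nested list of all tunables with their package defaults. Top-level
#' sections: `paths`, `seed`, `simulate`, `qc`, `chill`, `season`, `events`,
#' `risk`, `recommendation`. Unknown keys are rejected when a user config is
#' merged, so typos fail loudly.
#'
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    paths = list(input_dir = "input", output_dir = "artifacts"),
    seed = 1L,
    simulate = list(zones = c("B", "C", "D", "E"), stations_per_zone = 2L,
                    years = 6L, start_year = 2010L),
    qc = list(min_coverage = 0.8),
    chill = list(ch_upper = 7),
    season = list(start_years = NULL),
    events = list(warm_dormancy_only = TRUE),
    risk = list(tc = -3, horizon_years = 10L),
    recommendation = list(percentile = 20, frost_threshold = 0.2)
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration file
#'
#' Accepts YAML or JSON; values are merged over [default_config()], and
#' unknown keys at any level raise an error.
#'
#' @param path Config file path, or `NULL` for the defaults.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  merge_into <- function(base, upd, where = "config") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown ", where, " key: '", k, "'")
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(where, "$", k))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  out <- merge_into(unclass(cfg), user)
  class(out) <- "pipeline_config"
  out
}

# fixed 4-decimal float formatting so artifacts are byte-identical across runs
.write_artifact_csv <- function(df, path) {
  for (v in names(df)) {
    if (inherits(df[[v]], "POSIXct"))
      df[[v]] <- format(df[[v]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    else if (inherits(df[[v]], "Date"))
      df[[v]] <- format(df[[v]], "%Y-%m-%d")
    else if (is.double(df[[v]]))
      df[[v]] <- formatC(df[[v]], format = "f", digits = 4)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

.seasons_of <- function(series, config) {
  yrs <- config$season$start_years
  if (!is.null(yrs)) return(as.integer(yrs))
  years <- sort(unique(as.integer(format(series$hour, "%Y"))))
  years[-length(years)]  # each season needs the following spring
}

#' Run one pipeline stage (or the whole chain)
#'
#' File-based command surface mirroring the end-to-end flow: `simulate`
#' writes synthetic station CSVs; `qc` validates them; `chill`/`season`
#' compute start dates, weekly chill tables and season summaries; `classify`
#' builds climatologies and zone labels (plus a GeoJSON of stations);
#' `events` detects extreme-temperature episodes; `risk` computes Haan
#' binomial frost risk per earliness group; `recommend` emits the varietal
#' suitability table; `all` chains every stage in order. Artifacts are CSV /
#' JSON / GeoJSON with fixed float formatting, so identical inputs and seed
#' give byte-identical outputs.
#'
#' @param command One of `simulate`, `qc`, `chill`, `season`, `classify`,
#'   `events`, `risk`, `recommend`, `all`.
#' @param config A `pipeline_config` (see [load_config()]).
#' @param out_dir Artifact directory (created if missing).
#' @param seed Overrides `config$seed`.
#' @return Invisibly, a character vector of artifact paths written.
#' @export
run_pipeline <- function(command, config = default_config(),
                         out_dir = config$paths$output_dir,
                         seed = config$seed) {
  commands <- c("simulate", "qc", "chill", "season", "classify", "events",
                "risk", "recommend", "all")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (command == "all") {
    arts <- unlist(lapply(
      c("simulate", "qc", "season", "classify", "events", "risk", "recommend"),
      run_pipeline, config = config, out_dir = out_dir, seed = seed))
    return(invisible(arts))
  }
  arts <- character(0)
  emit <- function(p) arts <<- c(arts, p)

  load_net <- function() {
    sim <- config$simulate
    generate_network(sim$zones, sim$stations_per_zone, sim$years, seed,
                     sim$start_year)
  }

  if (command == "simulate") {
    net <- load_net()
    emit(.write_artifact_csv(net$stations, file.path(out_dir, "stations.csv")))
    for (sid in names(net$series)) {
      hs <- net$series[[sid]]$hourly
      obs <- data.frame(timestamp = hs$hour, temperature = hs$temperature,
                        humidity = NA_real_, wind_mean = NA_real_,
                        wind_gust = NA_real_, precipitation = NA_real_)
      emit(.write_artifact_csv(obs, file.path(out_dir, paste0("obs_", sid, ".csv"))))
      emit(.write_artifact_csv(net$series[[sid]]$daily_precip,
                               file.path(out_dir, paste0("precip_", sid, ".csv"))))
    }
    return(invisible(arts))
  }

  stations <- utils::read.csv(file.path(out_dir, "stations.csv"),
                              stringsAsFactors = FALSE)
  read_obs <- function(sid) {
    md <- stations[stations$station_id == sid, ]
    meta <- station_metadata(sid, md$latitude, md$longitude,
                             record_interval = min(md$record_interval, 30L))
    obs <- read_station_csv(file.path(out_dir, paste0("obs_", sid, ".csv")), meta)
    attr(obs, "record_interval") <- md$record_interval
    obs
  }
  read_hourly <- function(sid) {
    obs <- read_obs(sid)
    resample_to_hourly(obs, config$qc$min_coverage,
                       record_interval = attr(obs, "record_interval"))
  }

  if (command == "qc") {
    thr <- qc_thresholds()
    reports <- list(); summaries <- list()
    for (sid in stations$station_id) {
      qc <- run_qc(read_obs(sid), thr)
      if (nrow(qc$flags)) {
        f <- qc$flags
        f$station_id <- sid
        f$timestamp <- qc$observations$timestamp[f$index]
        reports[[sid]] <- f[, c("station_id", "timestamp", "variable",
                                "level", "status", "reason")]
      }
      summaries[[sid]] <- list(
        n_records = nrow(qc$observations),
        n_valid = sum(qc$observations$qc_status == "valid"),
        n_suspect = sum(qc$observations$qc_status == "suspect"),
        n_invalid = sum(qc$observations$qc_status == "invalid"))
    }
    rep_df <- if (length(reports)) do.call(rbind, c(reports, make.row.names = FALSE))
              else data.frame(station_id = character(0), timestamp = character(0),
                              variable = character(0), level = integer(0),
                              status = character(0), reason = character(0))
    emit(.write_artifact_csv(rep_df, file.path(out_dir, "qc_report.csv")))
    jsonlite::write_json(summaries, file.path(out_dir, "qc_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    emit(file.path(out_dir, "qc_summary.json"))
    return(invisible(arts))
  }

  if (command %in% c("chill", "season")) {
    weekly_all <- list(); summaries <- list(); starts <- list()
    for (sid in stations$station_id) {
      hs <- read_hourly(sid)
      for (y in .seasons_of(hs, config)) {
        win <- season_window(y)
        if (max(hs$hour) < win$analysis_end) next
        sd_ <- estimate_start_date(hs, win)
        wt <- weekly_chill_table(hs, sd_, win, station_id = sid)
        key <- paste(sid, y)
        weekly_all[[key]] <- wt
        summaries[[key]] <- season_chill_summary(wt, sd_)
        starts[[key]] <- data.frame(station_id = sid, season = win$season_label,
                                    start_date = sd_,
                                    low_confidence = isTRUE(attr(sd_, "low_confidence")))
      }
    }
    emit(.write_artifact_csv(do.call(rbind, c(weekly_all, make.row.names = FALSE)),
                             file.path(out_dir, "weekly_chill.csv")))
    emit(.write_artifact_csv(do.call(rbind, c(summaries, make.row.names = FALSE)),
                             file.path(out_dir, "season_summary.csv")))
    emit(.write_artifact_csv(do.call(rbind, c(starts, make.row.names = FALSE)),
                             file.path(out_dir, "start_dates.csv")))
    return(invisible(arts))
  }

  if (command == "classify") {
    rows <- list(); features <- list()
    for (sid in stations$station_id) {
      hs <- read_hourly(sid)
      pr <- utils::read.csv(file.path(out_dir, paste0("precip_", sid, ".csv")),
                            stringsAsFactors = FALSE)
      pr$date <- as.Date(pr$date)
      clim <- monthly_climatology(hs, pr, station_id = sid)
      z <- classify_zone(clim)
      md <- stations[stations$station_id == sid, ]
      rows[[sid]] <- data.frame(
        station_id = sid, zone = z$label, descriptor = z$descriptor,
        koppen_type = z$koppen_type, n_cold_months = z$n_cold_months,
        annual_mean_temp = clim$annual_mean_temp,
        annual_precip = clim$annual_precip, ambiguous = z$ambiguous)
      features[[sid]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(md$longitude, md$latitude)),
        properties = list(station_id = sid, zone = z$label))
    }
    emit(.write_artifact_csv(do.call(rbind, c(rows, make.row.names = FALSE)),
                             file.path(out_dir, "zones.csv")))
    gj <- list(type = "FeatureCollection", features = unname(features))
    jsonlite::write_json(gj, file.path(out_dir, "stations.geojson"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    emit(file.path(out_dir, "stations.geojson"))
    return(invisible(arts))
  }

  if (command == "events") {
    defs <- default_event_definitions(config$events$warm_dormancy_only)
    evs <- list()
    for (sid in stations$station_id) {
      hs <- read_hourly(sid)
      for (d in defs) {
        e <- detect_events(hs, d)
        if (nrow(e)) {
          e$station_id <- sid
          evs[[paste(sid, d$name)]] <- e[, c("station_id", "name", "start",
                                             "duration", "extreme_temp")]
        }
      }
    }
    ev_df <- if (length(evs)) do.call(rbind, c(evs, make.row.names = FALSE))
             else data.frame(station_id = character(0), name = character(0),
                             start = character(0), duration = integer(0),
                             extreme_temp = numeric(0))
    emit(.write_artifact_csv(ev_df, file.path(out_dir, "events.csv")))
    return(invisible(arts))
  }

  if (command == "risk") {
    fp <- frost_risk_params(tc = config$risk$tc)
    out <- list()
    for (sid in stations$station_id) {
      hs <- read_hourly(sid)
      out[[sid]] <- lapply(stats::setNames(nm = c("I", "II", "III")), function(g) {
        r <- haan_frost_risk(hs, fp, g, config$risk$horizon_years)
        r[c("p", "n_years_observed", "damage_years", "horizon", "p_at_least_one")]
      })
    }
    jsonlite::write_json(out, file.path(out_dir, "frost_risk.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    emit(file.path(out_dir, "frost_risk.json"))
    return(invisible(arts))
  }

  if (command == "recommend") {
    summ <- utils::read.csv(file.path(out_dir, "season_summary.csv"),
                            stringsAsFactors = FALSE)
    risk <- jsonlite::read_json(file.path(out_dir, "frost_risk.json"))
    req <- load_requirements()
    recs <- list()
    for (sid in unique(summ$station_id)) {
      ss <- summ[summ$station_id == sid, ]
      fp <- vapply(c("I", "II", "III"),
                   function(g) risk[[sid]][[g]]$p, numeric(1))
      prof <- site_profile(ss, fp, percentile = config$recommendation$percentile,
                           location_id = sid)
      r <- recommend(prof, req, config$recommendation$frost_threshold)
      r$station_id <- sid
      r$safe_cu <- prof$safe_cu
      recs[[sid]] <- r[, c("station_id", "crop", "group_label", "suitable",
                           "margin_cu", "frost_ok", "earliness", "heat_start",
                           "safe_cu", "reasons")]
    }
    emit(.write_artifact_csv(do.call(rbind, c(recs, make.row.names = FALSE)),
                             file.path(out_dir, "recommendations.csv")))
    return(invisible(arts))
  }
  invisible(arts)
}
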