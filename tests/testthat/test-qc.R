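test_that("level 1: rigid limits invalidate, ephemerides only suspect", {
  obs <- mk_obs(c(5, 5, 5), humidity = c(50, 105, 99))
  fl <- validate_fixed_limits(obs)
  expect_equal(fl$index, 2L)
  expect_equal(fl$status, "invalid")
  expect_equal(fl$reason, "physical")   # humidity cannot exceed 100%

  # value exactly at the physical maximum is valid (closed interval)
  obs <- mk_obs(c(50, 49), humidity = 100)
  expect_equal(nrow(validate_fixed_limits(obs)), 0L)

  # inside rigid limits but above the monthly ephemeride -> suspect
  thr <- qc_thresholds(ephemerides = list(
    temperature = rep(list(c(-10, 25)), 12)))
  obs <- mk_obs(c(30, 20))
  fl <- validate_fixed_limits(obs, thr)
  expect_equal(fl$index, 1L)
  expect_equal(fl$status, "suspect")
  expect_equal(fl$reason, "ephemerides")
})

test_that("level 2: step exceedances flag both records; gaps not compared", {
  obs <- mk_obs(c(10, 25, 25.5))
  fl <- validate_temporal_coherence(obs)   # default max_step 4 degC / 10 min
  expect_equal(sort(fl$index), c(1L, 2L))
  expect_true(all(fl$status == "suspect" & fl$reason == "step"))

  expect_equal(nrow(validate_temporal_coherence(mk_obs(rep(7, 10)))), 0L)

  obs <- mk_obs(c(10, 25))
  obs$timestamp[2] <- obs$timestamp[2] + 3 * 3600  # 3-h gap: non-consecutive
  expect_equal(nrow(validate_temporal_coherence(obs, record_interval = 10)), 0L)
})

test_that("level 3: mean wind cannot exceed gust; equality ok; NA skipped", {
  obs <- mk_obs(c(5, 5, 5), wind_mean = c(5, 3, 2), wind_gust = c(3, 3, NA))
  fl <- validate_internal_consistency(obs)
  expect_equal(fl$index, 1L)
  expect_equal(fl$status, "invalid")
  expect_equal(fl$reason, "internal")
})

test_that("level 4: stuck-sensor windows suspect; lively series clean", {
  obs <- mk_obs(rep(7, 24), interval = 60L)      # 24 h identically 7.00 degC
  fl <- validate_series_consistency(obs)
  expect_equal(sort(unique(fl$index)), 1:24)
  expect_true(all(fl$status == "suspect"))

  hrs <- 0:23
  obs <- mk_obs(10 + 8 * sin(2 * pi * hrs / 24), interval = 60L)
  expect_equal(nrow(validate_series_consistency(obs)), 0L)

  obs <- mk_obs(c(7, NA), interval = 60L)        # window with 1 valid record
  expect_equal(nrow(validate_series_consistency(obs)), 0L)
})

test_that("level 5: IDW residuals against neighbours", {
  meta <- station_metadata("T", 38, -1.2)
  nb <- lapply(c(-1.15, -1.25, -1.2), function(lon) list(
    metadata = station_metadata(paste0("N", lon), 38.05, lon),
    obs = mk_obs(rep(5, 3))))
  obs <- mk_obs(c(20, 5, 5))
  fl <- validate_spatial_consistency(obs, meta, nb)
  expect_equal(fl$index, 1L)      # residual 15 > 5
  expect_equal(fl$reason, "spatial")

  # one neighbour with min_neighbors = 2 -> untested
  fl <- validate_spatial_consistency(obs, meta, nb[1], qc_thresholds())
  expect_equal(nrow(fl), 0L)

  expect_warning(validate_spatial_consistency(obs, meta, list()), "skipped")
})

test_that("run_qc consolidates, is idempotent, and reports for review", {
  obs <- mk_obs(c(5, 8), humidity = c(105, 95),
                wind_mean = c(6, 2), wind_gust = c(3, 4))
  qc <- run_qc(obs)
  # record 1 fails levels 1 and 3: one consolidated status, both reasons kept
  expect_equal(qc$observations$qc_status, c("invalid", "valid"))
  expect_setequal(qc$flags$reason[qc$flags$index == 1L],
                  c("physical", "internal"))

  qc2 <- run_qc(qc$observations)
  expect_equal(qc2$observations$qc_status, qc$observations$qc_status)
  expect_equal(qc2$flags, qc$flags)

  # consolidation is monotone: more levels can only degrade a status
  rank <- c(valid = 0, suspect = 1, invalid = 2)
  partial <- rep("valid", nrow(obs))
  l1 <- validate_fixed_limits(obs)
  partial[unique(l1$index[l1$status == "suspect"])] <- "suspect"
  partial[unique(l1$index[l1$status == "invalid"])] <- "invalid"
  expect_true(all(rank[qc$observations$qc_status] >= rank[partial]))
})

test_that("clean synthetic day is 100% valid at levels 1 and 3", {
  cfg <- synthetic_zone_config("D", seed = 101)
  obs <- generate_observations(cfg, days = 1, interval = 10L)
  qc <- run_qc(obs)
  expect_equal(sum(qc$flags$level %in% c(1L, 3L)), 0L)
})

test_that("injected violations are recalled exactly, with matching reasons", {
  cfg <- synthetic_zone_config("C", seed = 11)
  obs <- generate_observations(cfg, days = 20, interval = 10L)
  inj <- inject_violations(obs, injection_spec(physical = 5, internal = 3,
                                               step = 2), seed = 3)
  expect_equal(nrow(inj$labels), 10L)
  qc <- run_qc(inj$observations, record_interval = 10)
  by_reason <- split(qc$flags$index, qc$flags$reason)
  for (type in c("physical", "internal", "step")) {
    planted <- inj$labels$index[inj$labels$type == type]
    expect_true(all(planted %in% by_reason[[type]]),
                label = paste("recall of", type))
  }
  # levels 1 and 3 fire on exactly the planted records
  expect_setequal(qc$flags$index[qc$flags$level == 1L],
                  inj$labels$index[inj$labels$type == "physical"])
  expect_setequal(qc$flags$index[qc$flags$level == 3L],
                  inj$labels$index[inj$labels$type == "internal"])
})
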