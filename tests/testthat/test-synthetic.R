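test_that("metadata generation: cardinality, ranges, determinism", {
  cfg <- synth_config(n_cities = 120, seed = 7)
  meta <- generate_city_metadata(cfg)
  expect_equal(nrow(meta), 120)
  expect_equal(anyDuplicated(meta$city_id), 0)
  expect_true(all(meta$longitude >= -180 & meta$longitude <= 180))
  expect_true(all(meta$latitude >= -90 & meta$latitude <= 90))
  expect_true(all(meta$population >= cfg$population_range[1] &
                    meta$population <= cfg$population_range[2]))
  expect_true(all(meta$group %in% default_city_groups()$group))

  meta2 <- generate_city_metadata(synth_config(n_cities = 120, seed = 7))
  expect_identical(meta, meta2)

  two <- generate_city_metadata(synth_config(n_cities = 2, seed = 1))
  expect_equal(nrow(two), 2)
  expect_false(isTRUE(all.equal(two$longitude[1], two$longitude[2])) &&
                 isTRUE(all.equal(two$latitude[1], two$latitude[2])))

  expect_error(synth_config(n_cities = 1), "n_cities")
  expect_error(synth_config(missing_rate = 0.7, outlier_rate = 0.4),
               "missing_rate")
  expect_error(synth_config(start_date = "2020-01-01",
                            end_date = "2019-01-01"), "end_date")
})

test_that("degenerate generator reproduces its closed form", {
  g <- default_city_groups()[1]
  g$baseline_pm <- 50; g$baseline_o3 <- 50
  g$trend_pm <- 0; g$trend_o3 <- 0
  cfg <- synth_config(n_cities = 2, seed = 1, groups = g,
                      seasonal_amp_pm = 0, seasonal_amp_o3 = 0,
                      noise_sd = 0, missing_rate = 0, outlier_rate = 0)
  meta <- generate_city_metadata(cfg)
  panel <- generate_daily_series(cfg, meta)
  expect_true(all(panel$value == 50))
  n_days <- as.integer(as.Date("2022-12-31") - as.Date("2019-01-01")) + 1L
  expect_equal(nrow(panel), 2 * 2 * n_days)
})

test_that("planted linear trend appears at its closed-form rate", {
  g <- default_city_groups()[1]
  g$trend_pm <- 5; g$trend_o3 <- 5
  cfg <- synth_config(n_cities = 2, seed = 1, groups = g,
                      seasonal_amp_pm = 0, seasonal_amp_o3 = 0,
                      noise_sd = 0, missing_rate = 0, outlier_rate = 0)
  meta <- generate_city_metadata(cfg)
  panel <- generate_daily_series(cfg, meta)
  pm <- panel[pollutant == "PM25" & city_id == "C001"]
  pm[, year := as.integer(format(date, "%Y"))]
  ann <- pm[, mean(value), by = year][order(year)]$V1
  # +5 ug/m3/yr over midpoints 3 years apart -> last - first = 15
  expect_equal(ann[4] - ann[1], 15, tolerance = 0.01)
})

test_that("outlier injection matches its binomial rate and exceeds 999", {
  cfg <- synth_config(n_cities = 4, seed = 11, outlier_rate = 0.01,
                      missing_rate = 0)
  meta <- generate_city_metadata(cfg)
  panel <- generate_daily_series(cfg, meta)
  n_days <- panel[, .N, by = .(city_id, pollutant)]$N
  expect_true(all(n_days == 1461))
  out <- panel[value > 999]
  expect_true(all(out$value > 999 & out$value <= 2000))
  # exact binomial CI for 8 * 1461 Bernoulli(0.01) draws
  n_trials <- 8 * 1461
  ci <- qbinom(c(0.0005, 0.9995), n_trials, 0.01)
  expect_gte(nrow(out), ci[1])
  expect_lte(nrow(out), ci[2])
})

test_that("panel invariants: nonnegative, deterministic, truth ledger", {
  cfg <- tiny_synth()
  meta <- generate_city_metadata(cfg)
  p1 <- generate_daily_series(cfg, meta)
  p2 <- generate_daily_series(cfg, meta)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_true(all(p1$value >= 0))
  tr <- synth_truth(p1)
  expect_setequal(tr$city_id, meta$city_id)
  expect_true(all(c("true_mean_pm", "true_mean_o3", "trend_pm", "trend_o3",
                    "true_type", "true_combined", "true_quadrant")
                  %in% names(tr)))
  # ledger trend signs match the group table
  g <- default_city_groups()
  expect_equal(sign(tr$trend_pm), sign(g$trend_pm[match(tr$group, g$group)]))
})

test_that("emissions couple to planted means as configured", {
  cfg0 <- tiny_synth(n_cities = 60, seed = 5, emission_coupling = 0)
  meta <- generate_city_metadata(cfg0)
  em0 <- generate_emissions(meta, cfg0)
  tr <- synth_truth(generate_daily_series(cfg0, meta))
  mix <- 0.7 * tr$true_mean_pm + 0.3 * tr$true_mean_o3
  expect_lt(abs(cor(em0$nox_tons[match(tr$city_id, em0$city_id)], mix)), 0.35)

  cfg1 <- tiny_synth(n_cities = 60, seed = 5, emission_coupling = 5000,
                     emission_noise = 0)
  em1 <- generate_emissions(meta, cfg1)
  expect_equal(cor(em1$nox_tons[match(tr$city_id, em1$city_id)], mix), 1)
  expect_true(all(em1$nox_tons >= 0 & em1$voc_tons >= 0))

  cfg <- synth_config(n_cities = 120, seed = 5)
  meta120 <- generate_city_metadata(cfg)
  em <- generate_emissions(meta120, cfg)
  tr120 <- synth_truth(generate_daily_series(cfg, meta120))
  mix120 <- 0.7 * tr120$true_mean_pm + 0.3 * tr120$true_mean_o3
  expect_gt(cor(em$nox_tons[match(tr120$city_id, em$city_id)], mix120), 0.6)
})

test_that("southern-hemisphere cities get a flipped seasonal phase", {
  g <- default_city_groups()[group %in% c("compound", "clean_up")]
  g$n <- c(2L, 2L)
  cfg <- synth_config(n_cities = 4, seed = 3, groups = g, noise_sd = 0,
                      missing_rate = 0, outlier_rate = 0)
  meta <- generate_city_metadata(cfg)
  expect_true(any(meta$latitude < 0) && any(meta$latitude > 0))
  panel <- generate_daily_series(cfg, meta)
  panel[, month := as.integer(format(date, "%m"))]
  jan_jul <- panel[pollutant == "PM25" & month %in% c(1, 7),
                   .(m = mean(value)), by = .(city_id, month)]
  w <- data.table::dcast(jan_jul, city_id ~ month, value.var = "m")
  north <- meta$city_id[meta$latitude > 0]
  # PM2.5 peaks in the local winter on both hemispheres
  expect_true(all(w[city_id %in% north][["1"]] > w[city_id %in% north][["7"]]))
  expect_true(all(w[!city_id %in% north][["7"]] > w[!city_id %in% north][["1"]]))
})

test_that("write_synthetic_dataset emits rereadable files", {
  dir <- withr::local_tempdir()
  cfg <- tiny_synth(n_cities = 6)
  out <- write_synthetic_dataset(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("series.csv", "cities.csv", "emissions.csv", "truth.json")))))
  series <- data.table::fread(file.path(dir, "series.csv"))
  expect_equal(nrow(series), nrow(out$series))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), 6)
})
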