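## synthetic multi-city pollutant panel generator with a planted-truth ledger

#' Default planted city-group composition
#'
#' Six city groups whose baselines (µg/m³), linear trends (µg/m³ per year)
#' and counts encode the stated world the generator emulates for a 120-city,
#' 4-year network: 57 compound-polluted cities (of which 10 Delhi-like
#' hotspots with rising ozone), 30 PM2.5-dominant cities, 2 ozone-dominant
#' cities and 31 clean cities, 63 of which (52.5%) have both pollutants
#' declining.  Counts are rescaled proportionally when `n_cities != 120`.
#'
#' @return a `data.table` with one row per group.
#' @export
default_city_groups <- function() {
  data.table::data.table(
    group       = c("compound_hotspot", "compound", "pm_dominant",
                    "o3_dominant", "clean_down", "clean_up"),
    n           = c(10L, 47L, 30L, 2L, 16L, 15L),
    baseline_pm = c(150, 60, 45, 20, 15, 16),
    baseline_o3 = c(130, 120, 70, 112, 60, 62),
    trend_pm    = c(-5, -3, -2, 0.5, -0.5, 0.5),
    trend_o3    = c(3, -8, 1, 1.5, -2, 1.5),
    development = c("developing", "developing", "developed", "developed",
                    "developed", "developed"),
    region      = c("South Asia", "East Asia", "Europe", "North America",
                    "North America", "Oceania"),
    centroid_lon = c(77, 115, 10, -100, -90, 150),
    centroid_lat = c(25, 33, 50, 40, 42, -30)
  )
}

#' Configuration for the synthetic data generator
#'
#' @param n_cities number of cities (>= 2).
#' @param start_date,end_date study window (coerced with [as.Date()]).
#' @param seed integer RNG seed; identical configs give identical output.
#' @param groups group table as in [default_city_groups()].
#' @param seasonal_amp_pm,seasonal_amp_o3 seasonal half-amplitudes, µg/m³.
#' @param seasonal_phase_pm,seasonal_phase_o3 month (1-12) of the seasonal
#'   peak in the northern hemisphere; PM2.5 peaks in winter (January),
#'   O3 in summer (July).  Southern-hemisphere cities get the phase
#'   shifted by six months.
#' @param noise_sd daily observational noise sd, µg/m³.
#' @param missing_rate fraction of days dropped at random.
#' @param outlier_rate fraction of days replaced by gross outliers
#'   drawn uniformly in (1000, 2000] µg/m³ (always > the 999 QC cut).
#' @param spatial_corr_range km scatter of cities around their group
#'   centroid; controls the spatial autocorrelation range.
#' @param population_range min/max city population, persons.
#' @param emission_coupling slope linking annual precursor emissions
#'   (tons/yr) to planted city mean concentrations (µg/m³).
#' @param emission_noise sdlog of the multiplicative lognormal emission
#'   noise term.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_cities = 120L,
                         start_date = "2019-01-01",
                         end_date = "2022-12-31",
                         seed = 1L,
                         groups = default_city_groups(),
                         seasonal_amp_pm = 8,
                         seasonal_amp_o3 = 12,
                         seasonal_phase_pm = 1L,
                         seasonal_phase_o3 = 7L,
                         noise_sd = 5,
                         missing_rate = 0.003,
                         outlier_rate = 0.001,
                         spatial_corr_range = 1200,
                         population_range = c(5e5, 2e7),
                         emission_coupling = 5000,
                         emission_noise = 0.3) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date <= start_date) {
    stop("invalid config: end_date must be after start_date", call. = FALSE)
  }
  if (n_cities < 2) {
    stop("invalid config: n_cities must be >= 2", call. = FALSE)
  }
  if (missing_rate < 0 || outlier_rate < 0 ||
      missing_rate + outlier_rate >= 1) {
    stop("invalid config: missing_rate + outlier_rate must be in [0, 1)",
         call. = FALSE)
  }
  if (seasonal_amp_pm < 0 || seasonal_amp_o3 < 0 || noise_sd < 0) {
    stop("invalid config: amplitudes and noise_sd must be >= 0",
         call. = FALSE)
  }
  if (emission_coupling < 0) {
    stop("invalid config: emission_coupling must be >= 0", call. = FALSE)
  }
  cfg <- list(
    n_cities = as.integer(n_cities), start_date = start_date,
    end_date = end_date, seed = as.integer(seed),
    groups = data.table::as.data.table(groups),
    seasonal_amp_pm = seasonal_amp_pm, seasonal_amp_o3 = seasonal_amp_o3,
    seasonal_phase_pm = as.integer(seasonal_phase_pm),
    seasonal_phase_o3 = as.integer(seasonal_phase_o3),
    noise_sd = noise_sd, missing_rate = missing_rate,
    outlier_rate = outlier_rate, spatial_corr_range = spatial_corr_range,
    population_range = population_range,
    emission_coupling = emission_coupling, emission_noise = emission_noise
  )
  class(cfg) <- "synth_config"
  cfg
}

## largest-remainder allocation of n_cities over group shares
allocate_groups <- function(groups, n_cities) {
  share <- groups$n / sum(groups$n)
  base <- floor(share * n_cities)
  rem <- n_cities - sum(base)
  if (rem > 0) {
    frac <- share * n_cities - base
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[bump] <- base[bump] + 1L
  }
  as.integer(base)
}

#' Generate the synthetic city metadata table
#'
#' Cities are scattered around continental group centroids (great-circle
#' scatter `spatial_corr_range`), giving the network genuine spatial
#' structure; populations are drawn log-uniformly within
#' `population_range`.
#'
#' @param cfg a [synth_config()].
#' @return `data.table` with columns `city_id`, `name`, `country`, `group`,
#'   `development`, `longitude`, `latitude`, `population`.
#' @export
generate_city_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  groups <- cfg$groups
  counts <- allocate_groups(groups, cfg$n_cities)
  idx <- rep(seq_len(nrow(groups)), counts)
  n <- length(idx)
  sd_deg <- cfg$spatial_corr_range / 111  # ~111 km per degree
  lat <- pmin(85, pmax(-85, groups$centroid_lat[idx] + rnorm(n, 0, sd_deg)))
  lon <- groups$centroid_lon[idx] + rnorm(n, 0, sd_deg)
  lon <- ((lon + 180) %% 360) - 180
  lp <- log(cfg$population_range)
  meta <- data.table::data.table(
    city_id = sprintf("C%03d", seq_len(n)),
    name = sprintf("City %03d", seq_len(n)),
    country = groups$region[idx],
    group = groups$group[idx],
    development = groups$development[idx],
    longitude = lon,
    latitude = lat,
    population = round(exp(runif(n, lp[1], lp[2])))
  )
  meta[]
}

## noiseless signal for one city-pollutant over a date grid
planted_signal <- function(dates, start_date, baseline, trend, amp, phase,
                           southern) {
  tt <- as.numeric(dates - start_date) / 365.25
  month <- as.integer(format(dates, "%m"))
  ph <- if (southern) ((phase - 1 + 6) %% 12) + 1 else phase
  pmax(0, baseline + trend * tt + amp * cospi(2 * (month - ph) / 12))
}

## planted study-period and endpoint annual means (noiseless signal means)
planted_truth <- function(cfg, metadata) {
  dates <- seq(cfg$start_date, cfg$end_date, by = "day")
  yr <- as.integer(format(dates, "%Y"))
  years <- sort(unique(yr))
  g <- cfg$groups[match(metadata$group, cfg$groups$group)]
  out <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    south <- metadata$latitude[i] < 0
    sig_pm <- planted_signal(dates, cfg$start_date, g$baseline_pm[i],
                             g$trend_pm[i], cfg$seasonal_amp_pm,
                             cfg$seasonal_phase_pm, south)
    sig_o3 <- planted_signal(dates, cfg$start_date, g$baseline_o3[i],
                             g$trend_o3[i], cfg$seasonal_amp_o3,
                             cfg$seasonal_phase_o3, south)
    ann_pm <- vapply(years, function(y) mean(sig_pm[yr == y]), numeric(1))
    ann_o3 <- vapply(years, function(y) mean(sig_o3[yr == y]), numeric(1))
    out[[i]] <- data.table::data.table(
      city_id = metadata$city_id[i],
      group = metadata$group[i],
      true_mean_pm = mean(ann_pm),
      true_mean_o3 = mean(ann_o3),
      true_first_pm = ann_pm[1], true_last_pm = ann_pm[length(ann_pm)],
      true_first_o3 = ann_o3[1], true_last_o3 = ann_o3[length(ann_o3)],
      trend_pm = g$trend_pm[i], trend_o3 = g$trend_o3[i]
    )
  }
  truth <- data.table::rbindlist(out)
  ## expected labels, written out independently of the analysis modules so
  ## downstream recovery tests compare against a ledger, not the code under
  ## test
  truth[, true_type := ifelse(
    true_mean_pm > 35 & true_mean_o3 > 100, "P-O",
    ifelse(true_mean_pm > 35, "PM25_dominated",
           ifelse(true_mean_o3 > 100, "O3_dominated", "Clean")))]
  band6 <- function(x, lo, hi) ifelse(x > hi, "extremely_high",
                                      ifelse(x >= lo, "high", "low"))
  risk6 <- function(band, up) {
    m <- c(extremely_high_up = "HR", extremely_high_down = "ST",
           high_up = "R", high_down = "DST",
           low_up = "S", low_down = "HS")
    unname(m[paste0(band, ifelse(up, "_up", "_down"))])
  }
  truth[, true_pm_label := risk6(band6(true_mean_pm, 25, 35), trend_pm > 0)]
  truth[, true_o3_label := risk6(band6(true_mean_o3, 100, 120), trend_o3 > 0)]
  truth[, true_combined := paste(true_pm_label, true_o3_label, sep = " + ")]
  rpm <- truth$true_last_pm / truth$true_first_pm
  ro3 <- truth$true_last_o3 / truth$true_first_o3
  truth[, true_quadrant := ifelse(
    rpm >= 1 & ro3 >= 1, "SynergisticIncrease",
    ifelse(rpm < 1 & ro3 < 1, "SynergisticDecrease",
           ifelse(rpm >= 1, "PM_up_O3_down", "PM_down_O3_up")))]
  truth[]
}

#' Generate the daily pollutant panel
#'
#' Daily concentration = baseline + trend·(t − t0)/365.25 +
#' amp·cos(2π(month − phase)/12) + N(0, noise_sd), truncated at zero.
#' A `missing_rate` fraction of days is dropped at random and an
#' `outlier_rate` fraction replaced by gross outliers in (1000, 2000] µg/m³.
#' The returned panel carries the planted-parameter ledger in attribute
#' `"truth"` (see [synth_truth()]).
#'
#' @param cfg a [synth_config()].
#' @param metadata output of [generate_city_metadata()].
#' @return long `data.table` (`city_id`, `date`, `pollutant`, `value`).
#' @export
generate_daily_series <- function(cfg, metadata) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  dates <- seq(cfg$start_date, cfg$end_date, by = "day")
  g <- cfg$groups[match(metadata$group, cfg$groups$group)]
  pieces <- vector("list", 2L * nrow(metadata))
  k <- 0L
  for (i in seq_len(nrow(metadata))) {
    south <- metadata$latitude[i] < 0
    for (pol in c("PM25", "O3")) {
      base <- if (pol == "PM25") g$baseline_pm[i] else g$baseline_o3[i]
      tr <- if (pol == "PM25") g$trend_pm[i] else g$trend_o3[i]
      amp <- if (pol == "PM25") cfg$seasonal_amp_pm else cfg$seasonal_amp_o3
      ph <- if (pol == "PM25") cfg$seasonal_phase_pm else cfg$seasonal_phase_o3
      v <- planted_signal(dates, cfg$start_date, base, tr, amp, ph, south)
      if (cfg$noise_sd > 0) {
        v <- pmax(0, v + rnorm(length(v), 0, cfg$noise_sd))
      }
      u <- runif(length(v))
      out <- u < cfg$outlier_rate
      if (any(out)) v[out] <- runif(sum(out), 1000, 2000)
      miss <- u >= cfg$outlier_rate &
        u < cfg$outlier_rate + cfg$missing_rate
      k <- k + 1L
      pieces[[k]] <- data.table::data.table(
        city_id = metadata$city_id[i], date = dates[!miss],
        pollutant = pol, value = v[!miss])
    }
  }
  panel <- data.table::rbindlist(pieces)
  data.table::setorder(panel, city_id, pollutant, date)
  data.table::setattr(panel, "truth", planted_truth(cfg, metadata))
  data.table::setattr(panel, "synth_config", cfg)
  panel[]
}

#' Planted-truth ledger of a synthetic panel
#' @param panel output of [generate_daily_series()].
#' @return `data.table` of planted means, trends and implied labels.
#' @export
synth_truth <- function(panel) {
  tr <- attr(panel, "truth", exact = TRUE)
  if (is.null(tr)) stop("panel carries no truth ledger", call. = FALSE)
  tr
}

#' Generate annual precursor (NOx, VOC) emissions coupled to pollution
#'
#' Emissions are an affine function of the planted city mean concentrations
#' plus multiplicative lognormal noise:
#' `E = base + coupling * mix + base * (exp(N(0, sdlog)) - 1)` with a mix of
#' the planted PM2.5 and O3 means.  `emission_coupling = 0` makes emissions
#' independent of concentrations; `emission_noise = 0` with positive
#' coupling makes the Pearson correlation with the planted mix exactly 1.
#'
#' @param metadata city metadata.
#' @param cfg a [synth_config()].
#' @return `data.table` (`city_id`, `nox_tons`, `voc_tons`), nonnegative.
#' @export
generate_emissions <- function(metadata, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- planted_truth(cfg, metadata)
  set.seed(cfg$seed + 2L)
  n <- nrow(truth)
  base <- 5e4
  mix_nox <- 0.7 * truth$true_mean_pm + 0.3 * truth$true_mean_o3
  mix_voc <- 0.3 * truth$true_mean_pm + 0.7 * truth$true_mean_o3
  noise1 <- exp(rnorm(n, 0, cfg$emission_noise)) - 1
  noise2 <- exp(rnorm(n, 0, cfg$emission_noise)) - 1
  em <- data.table::data.table(
    city_id = truth$city_id,
    nox_tons = pmax(0, base + cfg$emission_coupling * mix_nox + base * noise1),
    voc_tons = pmax(0, base + cfg$emission_coupling * mix_voc + base * noise2)
  )
  em[]
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `series.csv` (long format: city_id, date, pollutant, value),
#' `cities.csv`, `emissions.csv` and `truth.json` (planted-parameter
#' ledger) under `dir`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory, created if needed.
#' @return invisibly, a list with the in-memory tables.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- generate_city_metadata(cfg)
  panel <- generate_daily_series(cfg, meta)
  em <- generate_emissions(meta, cfg)
  truth <- synth_truth(panel)
  data.table::fwrite(panel, file.path(dir, "series.csv"))
  data.table::fwrite(meta, file.path(dir, "cities.csv"))
  data.table::fwrite(em, file.path(dir, "emissions.csv"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(list(metadata = meta, series = panel, emissions = em,
                 truth = truth))
}
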