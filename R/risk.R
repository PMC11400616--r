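## six-type exposure-risk typology: concentration band x trend direction

RISK_LABELS <- c("HR", "ST", "R", "DST", "S", "HS")

#' Concentration-band thresholds for the risk typology
#'
#' PM2.5: low < 25, high 25-35, extremely high > 35 µg/m³;
#' O3: low < 100, high 100-120, extremely high > 120 µg/m³.
#' The band edges, written with strict inequalities on both sides in the
#' source classification and hence unassigned, are closed into the middle
#' (`high`) band.
#'
#' @return named list of `c(low_edge, high_edge)` per pollutant.
#' @export
risk_thresholds <- function() {
  list(PM25 = c(25, 35), O3 = c(100, 120))
}

#' Concentration band of a period mean
#'
#' @param pollutant `"PM25"` or `"O3"` (vectorised, recycled).
#' @param period_mean period-mean concentration, µg/m³.
#' @param thresholds see [risk_thresholds()].
#' @return character vector in
#'   `c("low", "high", "extremely_high")`; NA mean gives NA.
#' @export
conc_band <- function(pollutant, period_mean, thresholds = risk_thresholds()) {
  n <- max(length(pollutant), length(period_mean))
  pollutant <- rep_len(pollutant, n)
  period_mean <- rep_len(period_mean, n)
  out <- rep(NA_character_, n)
  for (pol in unique(pollutant)) {
    th <- thresholds[[pol]]
    if (is.null(th)) stop("unknown pollutant: ", pol, call. = FALSE)
    sel <- pollutant == pol & is.finite(period_mean)
    out[sel] <- ifelse(period_mean[sel] > th[2], "extremely_high",
                       ifelse(period_mean[sel] >= th[1], "high", "low"))
  }
  out
}

#' Six-type exposure-risk label from band and trend direction
#'
#' HR / ST: extremely high concentrations with increasing / decreasing
#' trend; R / DST: high band; S / HS: low band.  A flat trend
#' (`direction = "none"`, Z = 0) is mapped to the decreasing side; callers
#' should carry a `flat` flag alongside (see [assess_exposure_risk()]).
#'
#' @param band `"extremely_high"`, `"high"` or `"low"` (vectorised).
#' @param direction `"increasing"`, `"decreasing"` or `"none"`.
#' @return character vector in `c("HR","ST","R","DST","S","HS")`.
#' @export
risk_label <- function(band, direction) {
  n <- max(length(band), length(direction))
  band <- rep_len(band, n)
  direction <- rep_len(direction, n)
  up <- direction == "increasing"
  key <- paste0(band, ifelse(up, "_up", "_down"))
  map <- c(extremely_high_up = "HR", extremely_high_down = "ST",
           high_up = "R", high_down = "DST",
           low_up = "S", low_down = "HS")
  out <- unname(map[key])
  out[is.na(band) | is.na(direction)] <- NA_character_
  out
}

#' Per-city exposure-risk labels and combined "PM2.5 + O3" pair
#'
#' Bands come from the study-period mean of valid annual means; directions
#' from the Mann-Kendall trend table (sign of Z; a significance tier can be
#' required via `require_tier`, in which case non-significant trends count
#' as flat).
#'
#' @param agg output of [aggregate_series()].
#' @param trends output of [mk_trends()].
#' @param thresholds see [risk_thresholds()].
#' @param require_tier 0 (default: sign of Z only) or 90/95/99 to gate
#'   direction on a significance tier.
#' @return `data.table` with per-pollutant `band`, `direction`, `flat`,
#'   `label` and a per-city `combined` "PMlabel + O3label" (PM2.5 first).
#' @export
assess_exposure_risk <- function(agg, trends, thresholds = risk_thresholds(),
                                 require_tier = 0L) {
  st <- agg$study[is_valid == TRUE, .(city_id, pollutant, mean)]
  tr <- data.table::as.data.table(trends)[, .(city_id, pollutant, Z,
                                              direction, sig_tier)]
  x <- st[tr, on = c("city_id", "pollutant"), nomatch = NULL]
  x[, flat := direction == "none" |
      (require_tier > 0 & sig_tier < require_tier)]
  x[, direction := ifelse(flat, "decreasing", direction)]
  x[, band := conc_band(pollutant, mean, thresholds)]
  x[, label := risk_label(band, direction)]
  wide <- data.table::dcast(x, city_id ~ pollutant,
                            value.var = c("label", "band", "direction",
                                          "flat"))
  need <- c("label_PM25", "label_O3")
  if (!all(need %in% names(wide))) {
    return(data.table::data.table())
  }
  wide <- wide[!is.na(label_PM25) & !is.na(label_O3)]
  wide[, combined := paste(label_PM25, label_O3, sep = " + ")]
  wide[]
}

#' Population totals per combined exposure-risk type
#'
#' @param risk output of [assess_exposure_risk()].
#' @param metadata city metadata with `population` and optionally
#'   `country` and `development`.
#' @return list with `by_type` population and city counts per combined
#'   label (totals conserve the grand population of labeled cities),
#'   `by_development`, `by_country`, and `n_excluded` cities lacking a
#'   population.
#' @export
population_by_risk <- function(risk, metadata) {
  md <- data.table::as.data.table(metadata)
  x <- data.table::as.data.table(risk)[md, on = "city_id", nomatch = NULL]
  n_excluded <- sum(!is.finite(x$population))
  x <- x[is.finite(population)]
  by_type <- x[, .(n_cities = .N, population = sum(population)),
               by = combined][order(-population)]
  by_dev <- if ("development" %in% names(x)) {
    x[, .(n_cities = .N, population = sum(population)),
      by = .(development, combined)]
  } else NULL
  by_country <- if ("country" %in% names(x)) {
    x[, .(n_cities = .N, population = sum(population)),
      by = .(country, combined)]
  } else NULL
  list(by_type = by_type, by_development = by_dev, by_country = by_country,
       grand_population = sum(x$population), n_excluded = n_excluded)
}
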