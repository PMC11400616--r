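## four-quadrant synergy classification of endpoint concentration change

SYNERGY_QUADRANTS <- c("SynergisticIncrease", "SynergisticDecrease",
                       "PM_up_O3_down", "PM_down_O3_up")

#' Relative rate of change between two annual means
#'
#' `ROC = C_end / C_start`; the start-year mean must be positive.
#'
#' @param c_start,c_end annual mean concentrations, µg/m³ (vectorised).
#' @return ratio; NA where the start mean is not positive or either mean
#'   is missing.
#' @export
roc_ratio <- function(c_start, c_end) {
  out <- c_end / c_start
  out[!is.finite(c_start) | !is.finite(c_end) | c_start <= 0] <- NA_real_
  out
}

#' Synergy quadrant from the two relative rates of change
#'
#' Both ratios >= 1: synergistic increase; both < 1: synergistic decrease;
#' mixed signs give the two seesaw quadrants.  A ratio of exactly 1 counts
#' as an increase.
#'
#' @param roc_pm,roc_o3 relative rates of change (vectorised).
#' @return character vector of quadrant labels; NA inputs give NA.
#' @export
synergy_quadrant <- function(roc_pm, roc_o3) {
  out <- ifelse(roc_pm >= 1 & roc_o3 >= 1, "SynergisticIncrease",
                ifelse(roc_pm < 1 & roc_o3 < 1, "SynergisticDecrease",
                       ifelse(roc_pm >= 1, "PM_up_O3_down",
                              "PM_down_O3_up")))
  out[!is.finite(roc_pm) | !is.finite(roc_o3)] <- NA_character_
  out
}

#' Per-city synergy classification between two endpoint years
#'
#' @param agg output of [aggregate_series()].
#' @param start_year,end_year endpoint years; default the first and last
#'   study years.
#' @return `data.table` (`city_id`, `roc_pm`, `roc_o3`, `quadrant`,
#'   `pct_change_pm`, `pct_change_o3`); cities lacking a valid annual mean
#'   for either endpoint year and pollutant are excluded.
#' @export
synergy_classify <- function(agg, start_year = NULL, end_year = NULL) {
  ann <- agg$annual[is_valid == TRUE]
  years <- sort(unique(ann$year))
  start_year <- start_year %||% min(years)
  end_year <- end_year %||% max(years)
  w <- data.table::dcast(ann[year %in% c(start_year, end_year)],
                         city_id ~ pollutant + year, value.var = "mean")
  need <- c(paste0("PM25_", start_year), paste0("PM25_", end_year),
            paste0("O3_", start_year), paste0("O3_", end_year))
  if (!all(need %in% names(w))) {
    stop("endpoint annual means unavailable for years ",
         start_year, "/", end_year, call. = FALSE)
  }
  out <- w[, .(
    city_id,
    roc_pm = roc_ratio(get(need[1]), get(need[2])),
    roc_o3 = roc_ratio(get(need[3]), get(need[4]))
  )]
  out <- out[is.finite(roc_pm) & is.finite(roc_o3)]
  out[, quadrant := synergy_quadrant(roc_pm, roc_o3)]
  out[, pct_change_pm := (roc_pm - 1) * 100]
  out[, pct_change_o3 := (roc_o3 - 1) * 100]
  out[]
}

#' Quadrant shares and mean percent changes
#'
#' @param results output of [synergy_classify()].
#' @param metadata optional metadata for a country cross-tab.
#' @return list: `by_quadrant` (`n`, `share` summing to 1,
#'   `mean_pct_change_pm`, `mean_pct_change_o3`), optional `by_country`,
#'   `n_cities`.
#' @export
synergy_summary <- function(results, metadata = NULL) {
  res <- data.table::as.data.table(results)
  res <- res[!is.na(quadrant)]
  if (nrow(res) == 0) stop("no classified cities", call. = FALSE)
  by_q <- res[, .(n = .N,
                  mean_pct_change_pm = mean(pct_change_pm),
                  mean_pct_change_o3 = mean(pct_change_o3)),
              by = quadrant]
  by_q[, share := n / sum(n)]
  full <- data.table::data.table(quadrant = SYNERGY_QUADRANTS)
  by_q <- by_q[full, on = "quadrant"]
  by_q[is.na(n), `:=`(n = 0L, share = 0)]
  by_country <- NULL
  if (!is.null(metadata) && "country" %in% names(metadata)) {
    md <- data.table::as.data.table(metadata)
    by_country <- res[md, on = "city_id", nomatch = NULL][
      , .N, by = .(country, quadrant)]
  }
  list(by_quadrant = by_q[], by_country = by_country, n_cities = nrow(res))
}
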