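## dominant-pollution typology: P-O / PM25_dominated / O3_dominated / Clean

POLLUTION_TYPES <- c("P-O", "PM25_dominated", "O3_dominated", "Clean")

#' Classify dominant pollution type from period-mean concentrations
#'
#' A city-period is compound polluted (`P-O`) when its PM2.5 mean exceeds
#' 35 µg/m³ and its O3 mean exceeds 100 µg/m³; exceeding only one threshold
#' gives the corresponding single-pollutant dominance; `Clean` otherwise.
#' Exact threshold equality is assigned to the lower-severity (non
#' exceeding) side.
#'
#' @param pm_mean,o3_mean period-mean concentrations, µg/m³ (vectorised).
#' @param pm_threshold,o3_threshold classification thresholds, µg/m³.
#' @return character vector of labels in
#'   `c("P-O", "PM25_dominated", "O3_dominated", "Clean")`; NA inputs give
#'   NA labels.
#' @export
classify_pollution <- function(pm_mean, o3_mean,
                               pm_threshold = 35, o3_threshold = 100) {
  stopifnot(length(pm_mean) == length(o3_mean))
  pm_ex <- pm_mean > pm_threshold
  o3_ex <- o3_mean > o3_threshold
  out <- ifelse(pm_ex & o3_ex, "P-O",
                ifelse(pm_ex, "PM25_dominated",
                       ifelse(o3_ex, "O3_dominated", "Clean")))
  out[!is.finite(pm_mean) | !is.finite(o3_mean)] <- NA_character_
  out
}

## period-level typing table from aggregate tables; mode "mean" applies the
## rule to period means, mode "exceedance" labels each day and calls a city
## P-O when >= exceedance_frac of its paired valid days are P-O days
#' Pollution type per city and period
#'
#' @param agg output of [aggregate_series()].
#' @param series the QC-filtered daily series (needed for
#'   `mode = "exceedance"`).
#' @param period `"study"` or `"year"`.
#' @param mode `"mean"` (default: rule applied to period means) or
#'   `"exceedance"` (rule applied daily; a type exceeds when its daily
#'   exceedance fraction is at least `exceedance_frac`).
#' @param exceedance_frac daily-exceedance fraction for `"exceedance"`.
#' @param pm_threshold,o3_threshold thresholds, µg/m³.
#' @return `data.table` (`city_id`, `period`, `label`, `pm_mean`,
#'   `o3_mean`); cities with an invalid aggregate are excluded.
#' @export
pollution_types <- function(agg, series = NULL, period = c("study", "year"),
                            mode = c("mean", "exceedance"),
                            exceedance_frac = 0.5,
                            pm_threshold = 35, o3_threshold = 100) {
  period <- match.arg(period)
  mode <- match.arg(mode)
  tab <- if (period == "study") {
    x <- data.table::copy(agg$study)
    x[, period := "study"]
    x
  } else {
    x <- data.table::copy(agg$annual)
    x[, period := as.character(year)]
    x
  }
  wide <- data.table::dcast(tab[is_valid == TRUE],
                            city_id + period ~ pollutant,
                            value.var = "mean")
  if (!all(c("PM25", "O3") %in% names(wide))) {
    return(data.table::data.table(city_id = character(), period = character(),
                                  label = character(), pm_mean = numeric(),
                                  o3_mean = numeric()))
  }
  wide <- wide[!is.na(PM25) & !is.na(O3)]
  data.table::setnames(wide, c("PM25", "O3"), c("pm_mean", "o3_mean"))
  if (mode == "mean") {
    wide[, label := classify_pollution(pm_mean, o3_mean,
                                       pm_threshold, o3_threshold)]
  } else {
    if (is.null(series)) {
      stop("mode = 'exceedance' requires the daily series", call. = FALSE)
    }
    dd <- data.table::as.data.table(series)[valid == TRUE]
    dd[, year := as.integer(format(date, "%Y"))]
    dw <- data.table::dcast(dd, city_id + date + year ~ pollutant,
                            value.var = "value")
    dw <- dw[!is.na(PM25) & !is.na(O3)]
    dw[, period := if (period == "study") "study" else as.character(year)]
    frac <- dw[, .(f_pm = mean(PM25 > pm_threshold),
                   f_o3 = mean(O3 > o3_threshold)), by = .(city_id, period)]
    wide[frac, on = c("city_id", "period"),
         label := classify_pollution(
           ifelse(i.f_pm >= exceedance_frac, pm_threshold + 1, 0),
           ifelse(i.f_o3 >= exceedance_frac, o3_threshold + 1, 0),
           pm_threshold, o3_threshold)]
  }
  wide[!is.na(label),
       .(city_id, period, label, pm_mean, o3_mean)]
}

#' Shares of cities per pollution type
#' @param labels character vector of type labels (one period).
#' @return `data.table` (`label`, `n`, `share`); shares sum to 1.
#' @export
type_shares <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stop("no labeled cities", call. = FALSE)
  tab <- data.table::data.table(label = labels)[, .N, by = label]
  data.table::setnames(tab, "N", "n")
  tab[, share := n / sum(n)]
  full <- data.table::data.table(label = POLLUTION_TYPES)
  out <- tab[full, on = "label"]
  out[is.na(n), `:=`(n = 0L, share = 0)]
  out[]
}

#' First-to-last-year pollution type transitions
#'
#' @param labels_by_year `data.table` (`city_id`, `period` = year as
#'   character or integer, `label`).
#' @return list with `pairs` (per-city first/last labels) and `matrix`
#'   (4x4 transition counts, rows = first-year label).  Cities with fewer
#'   than two labeled years are excluded and counted in `n_excluded`.
#' @export
type_transitions <- function(labels_by_year) {
  dt <- data.table::as.data.table(labels_by_year)
  dt[, year := as.integer(period)]
  dt <- dt[!is.na(label) & !is.na(year)]
  pairs <- dt[order(year), .(
    first_label = label[1L], last_label = label[.N], n_years = .N
  ), by = city_id]
  excluded <- pairs[n_years < 2L]
  pairs <- pairs[n_years >= 2L]
  m <- matrix(0L, 4, 4, dimnames = list(POLLUTION_TYPES, POLLUTION_TYPES))
  if (nrow(pairs)) {
    tab <- pairs[, .N, by = .(first_label, last_label)]
    for (r in seq_len(nrow(tab))) {
      m[tab$first_label[r], tab$last_label[r]] <- tab$N[r]
    }
  }
  list(pairs = pairs[], matrix = m, n_excluded = nrow(excluded))
}
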