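## quality control, MDA8 ozone, and quota-aware aggregation

QC_MAX_UGM3 <- 999  # daily concentrations above this are discarded

normalize_pollutant <- function(x) {
  x <- toupper(gsub("[._ ]", "", as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("PM25", "PM2", "PM")] <- "PM25"
  out[x == "O3"] <- "O3"
  out
}

#' Quality-control filter for raw daily series
#'
#' Flags (never alters) implausible records: values above 999 µg/m³,
#' negative values, and non-finite values.  Rows with unparseable dates or
#' unknown pollutant codes are dropped and counted.  Duplicate
#' (city, pollutant, date) records collapse to the mean of their valid
#' values with a warning.  A per-rule accounting is attached as attribute
#' `"qc_report"` (see [qc_report()]).
#'
#' @param raw data.frame with columns `city_id`, `date`, `pollutant`,
#'   `value`.
#' @param max_value discard threshold, µg/m³ (strict: `value > max_value`
#'   is invalid, `value == max_value` is kept).
#' @return `data.table` of class `city_series` with columns `city_id`,
#'   `pollutant`, `date`, `value`, `valid`, `reason`.
#' @export
qc_filter <- function(raw, max_value = QC_MAX_UGM3) {
  dt <- data.table::as.data.table(raw)
  need <- c("city_id", "date", "pollutant", "value")
  if (!all(need %in% names(dt))) {
    stop("raw series must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(dt)
  dt[, date := suppressWarnings(as.Date(as.character(date)))]
  bad_date <- is.na(dt$date)
  dt[, pollutant := normalize_pollutant(pollutant)]
  bad_pol <- is.na(dt$pollutant) & !bad_date
  dropped <- bad_date | bad_pol
  dt <- dt[!dropped]
  dt[, value := suppressWarnings(as.numeric(value))]
  dt[, reason := "none"]
  dt[!is.finite(value), reason := "nonfinite"]
  dt[is.finite(value) & value < 0, reason := "negative"]
  dt[is.finite(value) & value > max_value, reason := "outlier_gt_threshold"]
  dt[, valid := reason == "none"]
  flagged <- table(dt$reason[dt$reason != "none"])
  ## collapse duplicates to the mean of valid values
  n_dup <- 0L
  if (anyDuplicated(dt, by = c("city_id", "pollutant", "date"))) {
    n_before <- nrow(dt)
    dt <- dt[, {
      if (.N == 1L) {
        list(value = value, valid = valid, reason = reason)
      } else if (any(valid)) {
        list(value = mean(value[valid]), valid = TRUE, reason = "none")
      } else {
        list(value = value[1L], valid = FALSE, reason = reason[1L])
      }
    }, by = .(city_id, pollutant, date)]
    n_dup <- n_before - nrow(dt)
    warning(sprintf("collapsed %d duplicate (city, pollutant, date) records",
                    n_dup), call. = FALSE)
  }
  data.table::setorder(dt, city_id, pollutant, date)
  data.table::setcolorder(dt, c("city_id", "pollutant", "date", "value",
                                "valid", "reason"))
  report <- list(
    n_input = n_input,
    n_dropped_bad_date = sum(bad_date),
    n_dropped_unknown_pollutant = sum(bad_pol),
    n_flagged = as.list(flagged),
    n_duplicates_collapsed = n_dup,
    n_output = nrow(dt),
    n_valid = sum(dt$valid)
  )
  data.table::setattr(dt, "qc_report", report)
  data.table::setattr(dt, "class", c("city_series", class(dt)))
  dt[]
}

#' QC accounting of a filtered series
#' @param x output of [qc_filter()].
#' @return list of row counts per QC rule.
#' @export
qc_report <- function(x) {
  r <- attr(x, "qc_report", exact = TRUE)
  if (is.null(r)) stop("no qc_report attribute found", call. = FALSE)
  r
}

#' Maximum daily 8-hour average (MDA8) ozone
#'
#' Computes the maximum over the 24 rolling 8-hour windows that end in the
#' calendar day (the first seven windows begin in the trailing hours of the
#' previous day).  Each window requires at least `min_valid_hours` of its 8
#' hours to be non-missing and averages its available hours.  The day is
#' valid when at least 18 of the 24 windows are computable; when no
#' previous-day tail is supplied only the 17 fully in-day windows exist and
#' the 75% quota is applied pro rata (>= 13 of 17).
#'
#' @param hourly numeric vector of the day's 24 hourly values (NA allowed).
#' @param prev_hours optional numeric vector of up to the last 7 hourly
#'   values of the previous day.
#' @param min_valid_hours minimum non-missing hours per window (default 6).
#' @param min_windows computable-window quota out of 24 (default 18).
#' @return list with `value` (µg/m³, NA if no window computable),
#'   `n_windows` computable, and `valid` flag.
#' @export
mda8 <- function(hourly, prev_hours = NULL, min_valid_hours = 6L,
                 min_windows = 18L) {
  if (length(hourly) == 0) {
    return(list(value = NA_real_, n_windows = 0L, valid = FALSE))
  }
  if (length(hourly) != 24) {
    stop("hourly must have 24 values (use NA for missing hours)",
         call. = FALSE)
  }
  if (!is.null(prev_hours) && length(prev_hours) > 7) {
    prev_hours <- tail(prev_hours, 7)
  }
  n_prev <- length(prev_hours)
  frame <- c(prev_hours, hourly)         # n_prev + 24 slots
  ## windows end at day hours 1..24, i.e. start at frame position
  ## (end + n_prev - 7); only windows fully inside the frame exist
  starts <- seq_len(24) + n_prev - 7L
  starts <- starts[starts >= 1L]
  means <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    w <- frame[starts[i]:(starts[i] + 7L)]
    if (sum(!is.na(w)) >= min_valid_hours) means[i] <- mean(w, na.rm = TRUE)
  }
  n_comp <- sum(!is.na(means))
  quota <- ceiling(min_windows / 24 * length(starts))
  list(
    value = if (n_comp > 0) max(means, na.rm = TRUE) else NA_real_,
    n_windows = n_comp,
    valid = n_comp >= quota
  )
}

## month -> meteorological season, hemisphere aware.
## northern: DJF winter (Dec counted into the following year's winter),
## MAM spring, JJA summer, SON autumn; southern shifts labels by 6 months.
season_of <- function(month, southern = FALSE) {
  north <- c("winter", "winter", "spring", "spring", "spring",
             "summer", "summer", "summer", "autumn", "autumn",
             "autumn", "winter")
  south <- c("summer", "summer", "autumn", "autumn", "autumn",
             "winter", "winter", "winter", "spring", "spring",
             "spring", "summer")
  ifelse(southern, south[month], north[month])
}

#' Aggregate a QC-filtered series with valid-day quotas
#'
#' Means are computed over valid records only.  A monthly mean is valid
#' with at least `min_month_days` (27) valid days; an annual mean with at
#' least `min_year_days` (360) valid days; a seasonal mean when all three
#' member months are valid; the study-period mean is the mean of the valid
#' annual means and is valid only when every study year is valid.  Invalid
#' aggregates are carried with `is_valid = FALSE`, never imputed.
#'
#' Seasons are meteorological three-month blocks, hemisphere-aware when
#' `metadata` (with `latitude`) is given and `hemisphere_aware = TRUE`;
#' December belongs to the following year's winter (southern: summer).
#'
#' @param series a `city_series` from [qc_filter()].
#' @param metadata optional city metadata with `city_id`, `latitude`.
#' @param min_month_days,min_year_days valid-day quotas.
#' @param hemisphere_aware flip season labels south of the equator.
#' @return list of class `aggregate_tables` with `data.table`s `monthly`,
#'   `seasonal`, `annual`, `study`, each carrying `mean`, `n_valid_days`,
#'   `is_valid`.
#' @export
aggregate_series <- function(series, metadata = NULL,
                             min_month_days = 27L, min_year_days = 360L,
                             hemisphere_aware = TRUE) {
  dt <- data.table::as.data.table(series)
  dt[, year := as.integer(format(date, "%Y"))]
  dt[, month := as.integer(format(date, "%m"))]
  if (!is.null(metadata) && hemisphere_aware) {
    md <- data.table::as.data.table(metadata)
    dt[, southern := md$latitude[match(city_id, md$city_id)] < 0]
    dt[is.na(southern), southern := FALSE]
  } else {
    dt[, southern := FALSE]
  }
  dt[, season := season_of(month, southern)]
  dt[, season_year := year + as.integer(month == 12L)]

  monthly <- dt[, .(
    mean = if (any(valid)) mean(value[valid]) else NA_real_,
    n_valid_days = sum(valid)
  ), by = .(city_id, pollutant, year, month)]
  monthly[, is_valid := n_valid_days >= min_month_days]

  annual <- dt[, .(
    mean = if (any(valid)) mean(value[valid]) else NA_real_,
    n_valid_days = sum(valid)
  ), by = .(city_id, pollutant, year)]
  annual[, is_valid := n_valid_days >= min_year_days]

  ## seasonal validity requires every member month to meet the monthly quota
  dt[, month_valid_days := sum(valid), by = .(city_id, pollutant, year, month)]
  seasonal <- dt[, .(
    mean = if (any(valid)) mean(value[valid]) else NA_real_,
    n_valid_days = sum(valid),
    n_valid_months = {
      mm <- unique(data.table::data.table(month, month_valid_days))
      sum(mm$month_valid_days >= min_month_days)
    }
  ), by = .(city_id, pollutant, season_year, season)]
  seasonal[, is_valid := n_valid_months == 3L]
  seasonal[, n_valid_months := NULL]

  study_years <- sort(unique(annual$year))
  study <- annual[, .(
    mean = if (any(is_valid)) mean(mean[is_valid]) else NA_real_,
    n_valid_days = sum(n_valid_days),
    is_valid = all(study_years %in% year[is_valid])
  ), by = .(city_id, pollutant)]

  out <- list(monthly = monthly[], seasonal = seasonal[], annual = annual[],
              study = study[], study_years = study_years)
  class(out) <- "aggregate_tables"
  out
}
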