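## end-to-end orchestration: generate -> QC -> aggregate -> classify ->
## trend -> risk -> spatial -> synergy -> report

#' Pipeline configuration
#'
#' All scientific constants (classification thresholds, valid-day quotas,
#' significance tiers) are visible here and overridable; defaults are the
#' values used throughout the package documentation.
#'
#' @param synthetic use the synthetic generator (`TRUE`) or read
#'   `series.csv` / `cities.csv` / `emissions.csv` from `input_dir`.
#' @param input_dir directory with input CSVs when `synthetic = FALSE`.
#' @param synth a [synth_config()] used when `synthetic = TRUE`.
#' @param seed master seed: also seeds the permutation tests.
#' @param pm_type_threshold,o3_type_threshold compound-pollution typing
#'   thresholds, µg/m³ (35 / 100).
#' @param risk_bands see [risk_thresholds()].
#' @param min_month_days,min_year_days valid-day quotas (27 / 360).
#' @param hemisphere_aware hemisphere-aware season labels.
#' @param trend_resolution series fed to the Mann-Kendall test.
#' @param require_tier significance gating for risk direction (0 = none).
#' @param typing_mode `"mean"` or `"exceedance"` city typing.
#' @param exceedance_frac daily-exceedance fraction for `"exceedance"`.
#' @param weights_k k for the kNN spatial weights.
#' @param corr_bandwidth adaptive bandwidth (nearest cities) for the
#'   geographically weighted correlation.
#' @param corr_kernel kernel for the local correlation.
#' @param n_perm permutation draws for Moran inference.
#' @param synergy_years endpoint years, NULL = first/last study years.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, input_dir = NULL,
                            synth = synth_config(), seed = 1L,
                            pm_type_threshold = 35, o3_type_threshold = 100,
                            risk_bands = risk_thresholds(),
                            min_month_days = 27L, min_year_days = 360L,
                            hemisphere_aware = TRUE,
                            trend_resolution = "monthly",
                            require_tier = 0L,
                            typing_mode = "mean", exceedance_frac = 0.5,
                            weights_k = 5L, corr_bandwidth = 20L,
                            corr_kernel = "bisquare", n_perm = 999L,
                            synergy_years = NULL) {
  stopifnot(pm_type_threshold > 0, o3_type_threshold > 0)
  stopifnot(risk_bands$PM25[1] < risk_bands$PM25[2],
            risk_bands$O3[1] < risk_bands$O3[2])
  if (!synthetic && is.null(input_dir)) {
    stop("input_dir required when synthetic = FALSE", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

read_input_dataset <- function(input_dir) {
  series <- data.table::fread(file.path(input_dir, "series.csv"))
  metadata <- data.table::fread(file.path(input_dir, "cities.csv"))
  empath <- file.path(input_dir, "emissions.csv")
  emissions <- if (file.exists(empath)) data.table::fread(empath) else NULL
  list(series = series, metadata = metadata, emissions = emissions,
       truth = NULL)
}

#' Run the full compound-pollution assessment pipeline
#'
#' Executes every stage and, when `out_dir` is given, writes the stage
#' tables (`aggregates_*.csv`, `pollution_types.csv`, `transitions.csv`,
#' `mk_results.csv`, `risk_labels.csv`, `population_by_risk.csv`,
#' `bimoran.csv`, `local_corr.csv`, `synergy.csv`) plus a consolidated
#' `report.json` and a plain-text `qc_report.txt`.  Runs are fully
#' deterministic for a fixed config (same seed gives byte-identical
#' output).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with all stage results and the `report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$synthetic) {
    meta <- generate_city_metadata(config$synth)
    panel <- generate_daily_series(config$synth, meta)
    emissions <- generate_emissions(meta, config$synth)
    truth <- synth_truth(panel)
  } else {
    inp <- read_input_dataset(config$input_dir)
    meta <- inp$metadata
    panel <- inp$series
    emissions <- inp$emissions
    truth <- NULL
  }

  ## stage: QC
  qc <- suppressWarnings(qc_filter(panel))
  qrep <- qc_report(qc)

  ## stage: aggregation with quotas
  agg <- aggregate_series(qc, metadata = meta,
                          min_month_days = config$min_month_days,
                          min_year_days = config$min_year_days,
                          hemisphere_aware = config$hemisphere_aware)

  ## stage: pollution typing (study period + per year) and transitions
  types_study <- pollution_types(agg, series = qc, period = "study",
                                 mode = config$typing_mode,
                                 exceedance_frac = config$exceedance_frac,
                                 pm_threshold = config$pm_type_threshold,
                                 o3_threshold = config$o3_type_threshold)
  types_year <- pollution_types(agg, series = qc, period = "year",
                                mode = config$typing_mode,
                                exceedance_frac = config$exceedance_frac,
                                pm_threshold = config$pm_type_threshold,
                                o3_threshold = config$o3_type_threshold)
  shares <- type_shares(types_study$label)
  transitions <- type_transitions(types_year)

  ## stage: Mann-Kendall trends
  trends <- mk_trends(agg, resolution = config$trend_resolution, series = qc)

  ## stage: exposure risk + population
  risk <- assess_exposure_risk(agg, trends, thresholds = config$risk_bands,
                               require_tier = config$require_tier)
  pop <- population_by_risk(risk, meta)

  ## stage: spatial association, on the cities with valid study means for
  ## both pollutants (the analysed network)
  study_w <- data.table::dcast(agg$study[is_valid == TRUE],
                               city_id ~ pollutant, value.var = "mean")
  if (all(c("PM25", "O3") %in% names(study_w))) {
    study_w <- study_w[!is.na(PM25) & !is.na(O3)]
  } else {
    study_w <- study_w[0]
  }
  meta_sp <- data.table::as.data.table(meta)[city_id %in% study_w$city_id]
  spatial_ok <- nrow(meta_sp) > config$weights_k + 1
  W <- if (spatial_ok) knn_weights(meta_sp, k = config$weights_k) else NULL
  if (spatial_ok) study_w <- study_w[match(W$ids, city_id)]
  moran <- if (spatial_ok) {
    bimoran(study_w$PM25, study_w$O3, W, n_perm = config$n_perm,
            seed = config$seed)
  } else NULL
  ann_w <- data.table::dcast(agg$annual[is_valid == TRUE],
                             city_id + year ~ pollutant, value.var = "mean")
  data.table::setnames(ann_w, c("PM25", "O3"), c("pm", "o3"),
                       skip_absent = TRUE)
  lc <- local_correlation(ann_w, if (spatial_ok) meta_sp else meta,
                          bandwidth = config$corr_bandwidth,
                          kernel = config$corr_kernel)
  curv <- tryCatch(
    correlation_curvature(lc$local_r,
                          study_w$PM25[match(lc$city_id, study_w$city_id)]),
    error = function(e) NULL)
  prec <- if (!is.null(emissions) && spatial_ok) {
    em <- data.table::as.data.table(emissions)[match(W$ids, city_id)]
    list(
      nox_pm = precursor_association(em$nox_tons, study_w$PM25, W,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 1L),
      voc_o3 = precursor_association(em$voc_tons, study_w$O3, W,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 2L))
  } else NULL

  ## stage: synergy
  syn <- synergy_classify(agg, start_year = config$synergy_years[1],
                          end_year = config$synergy_years[2])
  syn_sum <- synergy_summary(syn, meta)

  report <- list(
    n_cities = nrow(meta),
    study_years = agg$study_years,
    qc = qrep,
    type_shares = as.list(stats::setNames(shares$share, shares$label)),
    transitions = transitions$matrix,
    risk_counts = if (nrow(risk)) {
      as.list(table(risk$combined))
    } else list(),
    population_by_risk = if (!is.null(pop$by_type)) pop$by_type else NULL,
    global_moran = if (!is.null(moran)) {
      list(I = moran$global_I, pseudo_p = moran$global_p,
           n_perm = moran$n_perm, seed = moran$seed,
           mean_local_I = mean(moran$local$local_I),
           quadrant_counts = as.list(table(moran$local$quadrant)))
    } else NULL,
    local_correlation = list(
      mean = mean(lc$local_r, na.rm = TRUE),
      min = suppressWarnings(min(lc$local_r, na.rm = TRUE)),
      max = suppressWarnings(max(lc$local_r, na.rm = TRUE)),
      n_defined = sum(is.finite(lc$local_r))),
    correlation_curvature = if (!is.null(curv)) {
      curv[c("coefficients", "r_squared", "peak_pm", "peak_r", "n")]
    } else NULL,
    precursor = if (!is.null(prec)) list(
      nox_pm = list(I = prec$nox_pm$moran$global_I,
                    pseudo_p = prec$nox_pm$moran$global_p,
                    pearson_r = prec$nox_pm$pearson_r),
      voc_o3 = list(I = prec$voc_o3$moran$global_I,
                    pseudo_p = prec$voc_o3$moran$global_p,
                    pearson_r = prec$voc_o3$pearson_r)
    ) else NULL,
    synergy = list(
      by_quadrant = syn_sum$by_quadrant,
      n_cities = syn_sum$n_cities),
    config_echo = list(
      seed = config$seed, typing_mode = config$typing_mode,
      trend_resolution = config$trend_resolution,
      require_tier = config$require_tier,
      weights_k = config$weights_k,
      corr_bandwidth = config$corr_bandwidth,
      corr_kernel = config$corr_kernel, n_perm = config$n_perm,
      pm_type_threshold = config$pm_type_threshold,
      o3_type_threshold = config$o3_type_threshold,
      min_month_days = config$min_month_days,
      min_year_days = config$min_year_days,
      hemisphere_aware = config$hemisphere_aware)
  )

  result <- list(metadata = meta, series = qc, emissions = emissions,
                 truth = truth, aggregates = agg,
                 types_study = types_study, types_year = types_year,
                 type_shares = shares, transitions = transitions,
                 trends = trends, risk = risk, population = pop,
                 weights = W, moran = moran, local_corr = lc,
                 curvature = curv, precursor = prec,
                 synergy = syn, synergy_summary = syn_sum,
                 report = report)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f))
  fw(result$aggregates$monthly, "aggregates_monthly.csv")
  fw(result$aggregates$annual, "aggregates_annual.csv")
  fw(result$aggregates$seasonal, "aggregates_seasonal.csv")
  fw(result$aggregates$study, "aggregates_study.csv")
  fw(rbind(result$types_study, result$types_year), "pollution_types.csv")
  fw(result$transitions$pairs, "transitions.csv")
  fw(result$trends, "mk_results.csv")
  if (nrow(result$risk)) fw(result$risk, "risk_labels.csv")
  if (!is.null(result$population$by_type)) {
    fw(result$population$by_type, "population_by_risk.csv")
  }
  if (!is.null(result$moran)) fw(result$moran$local, "bimoran.csv")
  fw(result$local_corr, "local_corr.csv")
  fw(result$synergy, "synergy.csv")
  qlines <- c("QC report",
              sprintf("  %s: %s", names(unlist(result$report$qc)),
                      unlist(result$report$qc)))
  writeLines(qlines, file.path(out_dir, "qc_report.txt"))
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       matrix = "rowmajor", pretty = TRUE, na = "null")
  invisible(out_dir)
}
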