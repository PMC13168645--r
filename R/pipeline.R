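#' Pipeline configuration
#'
#' Bundles the simulation settings with every stage parameter so that one
#' object (serializable to JSON) reproduces a full run.
#'
#' @param sim a [sim_config()] (or `NULL` when composites are supplied
#'   externally).
#' @param classify run the land-cover stage (default TRUE); with `FALSE`
#'   RSEI is still computed ROI-wide and class-stratified outputs are
#'   absent.
#' @param n_train stable-pixel training locations per class.
#' @param train_fraction training share of the pooled samples.
#' @param n_trees Random Forest ensemble size.
#' @param n_stratified per-class validation subset size.
#' @param n_seed_stats labelled samples per class for the maximum-likelihood
#'   seed stage.
#' @param filter_window temporal majority-filter window (odd).
#' @param coverage_threshold June-window coverage threshold.
#' @param ndbsi_variant `"table_verbatim"` or `"standard_si"`.
#' @param transition_mode `"start_to_end"` or `"pooled_annual"`.
#' @param change_rule,change_k,change_m change-threshold rule, see
#'   [threshold_change()].
#' @param connectivity patch connectivity (4 or 8).
#' @param seed master seed; every stage derives a sub-seed from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), classify = TRUE,
                            n_train = 300, train_fraction = 0.75,
                            n_trees = 200, n_stratified = 1500,
                            n_seed_stats = 200,
                            filter_window = 5, coverage_threshold = 0.8,
                            ndbsi_variant = "table_verbatim",
                            transition_mode = "start_to_end",
                            change_rule = "std_multiple", change_k = 0.02,
                            change_m = 0.5, connectivity = 8, seed = 1L) {
  structure(list(sim = sim, classify = classify, n_train = n_train,
                 train_fraction = train_fraction, n_trees = n_trees,
                 n_stratified = n_stratified, n_seed_stats = n_seed_stats,
                 filter_window = filter_window,
                 coverage_threshold = coverage_threshold,
                 ndbsi_variant = ndbsi_variant,
                 transition_mode = transition_mode,
                 change_rule = change_rule, change_k = change_k,
                 change_m = change_m, connectivity = connectivity,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   restored configuration.
#' @export
save_config <- function(config, path) {
  raw <- unclass(config)
  if (!is.null(raw$sim)) raw$sim <- unclass(raw$sim)
  jsonlite::write_json(raw, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    sim <- sim_config(
      grid_rows = s$grid_rows, grid_cols = s$grid_cols,
      pixel_size_m = s$pixel_size_m, years = s$years,
      class_spectra = matrix(unlist(s$class_spectra), nrow = 3,
                             byrow = FALSE,
                             dimnames = list(c("forest", "bog", "grassland"),
                                             BAND_NAMES)),
      thermal_means = stats::setNames(unlist(s$thermal_means),
                                      c("forest", "bog", "grassland")),
      spectral_noise_sd = s$spectral_noise_sd,
      thermal_noise_sd = s$thermal_noise_sd,
      thermal_anomaly_gain = s$thermal_anomaly_gain,
      encroachment_base_rate = s$encroachment_base_rate,
      deficit_sensitivity = s$deficit_sensitivity,
      grass_encroachment_rate = s$grass_encroachment_rate,
      cloud_fraction = s$cloud_fraction,
      scenes_per_year = s$scenes_per_year,
      initial_shares = stats::setNames(unlist(s$initial_shares),
                                       c("forest", "bog", "grassland")),
      climate = lapply(s$climate, as.list),
      seed = s$seed)
  }
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the full monitoring pipeline on a synthetic world
#'
#' Executes simulate, preprocess (seasonal selection + medoid compositing),
#' per-year RSEI, optional two-stage Random-Forest land-cover
#' classification with temporal filtering / areas / transitions, trend and
#' hydroclimate-correlation statistics, and delta-RSEI change mapping.
#' Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, all tables, the
#'   resolved configuration and a JSON summary are written via
#'   [write_report()].
#' @return a run report (list of stage outputs and key tables).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  climate <- stage("simulate_climate",
                   simulate_climate(cfg, derive_seed(config$seed, 11L)))
  world <- stage("simulate_landscape",
                 simulate_landscape(cfg, climate,
                                    derive_seed(config$seed, 12L)))
  years <- vapply(world, `[[`, numeric(1), "year")
  grid <- attr(world, "grid")

  composites <- stage("preprocess", {
    lapply(world, function(rec) {
      composite_year(rec$scenes, rec$year,
                     coverage_threshold = config$coverage_threshold)
    })
  })
  have <- !vapply(composites, is.null, logical(1))
  if (!any(have)) stop("pipeline stage 'preprocess' failed: no usable years")
  composites <- composites[have]
  world <- world[have]
  years <- years[have]

  rsei <- stage("rsei", lapply(composites, rsei_for_year,
                               variant = config$ndbsi_variant))

  lc <- NULL
  if (isTRUE(config$classify)) {
    lc <- stage("classify", classify_stage(config, world, composites, years,
                                           grid))
  }

  trends <- stage("trends",
                  trends_stage(config, climate, rsei, lc, years))

  first <- which.min(years); last <- which.max(years)
  change <- stage("change",
                  change_analysis(rsei[[last]]$rsei, rsei[[first]]$rsei,
                                  rule = config$change_rule,
                                  k = config$change_k, m = config$change_m,
                                  connectivity = config$connectivity,
                                  pixel_area = pixel_area_ha(grid)))

  report <- list(config = config, years = years, grid = grid,
                 climate = climate, composites = composites, rsei = rsei,
                 landcover = lc, trends = trends, change = change,
                 truth = lapply(world, `[[`, "truth"),
                 n_converted = vapply(world, `[[`, integer(1),
                                      "n_converted_pixels"))
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    report$manifest <- write_report(report, out_dir)
  }
  report
}

# two-stage training + RF classification + filtering + accounting
classify_stage <- function(config, world, composites, years, grid) {
  ref_years <- intersect(seq(years[1], by = 5, length.out = 8), years)
  if (length(ref_years) < 2) ref_years <- years[c(1, length(years))]
  ref_idx <- match(ref_years, years)
  ref_comps <- composites[ref_idx]

  # seed stage: per-class Gaussian stats from labelled samples of the first
  # reference year (in real use these come from user-drawn seed polygons)
  pred1 <- composite_predictors(ref_comps[[1]])
  labels1 <- as.vector(world[[ref_idx[1]]]$truth)
  st <- class_stats_from_samples(pred1, labels1,
                                 n_per_class = config$n_seed_stats,
                                 seed = derive_seed(config$seed, 21L))
  seed_maps <- lapply(ref_comps, function(cmp) {
    matrix(maximum_likelihood_classify(composite_predictors(cmp), st),
           grid$nrow, grid$ncol)
  })
  stable <- stable_pixel_mask(seed_maps)
  training <- sample_balanced_training(stable, config$n_train, ref_years,
                                       ref_comps,
                                       seed = derive_seed(config$seed, 22L))
  split <- split_train_validation(training, config$train_fraction,
                                  seed = derive_seed(config$seed, 23L))
  rf <- train_random_forest(split$train, n_trees = config$n_trees,
                            seed = derive_seed(config$seed, 24L))
  accuracy <- assess_accuracy(rf, split$validation, config$n_stratified,
                              seed = derive_seed(config$seed, 25L))

  maps <- lapply(composites, function(cmp) {
    matrix(predict(rf, composite_predictors(cmp)), grid$nrow, grid$ncol)
  })
  filtered <- temporal_majority_filter(maps, config$filter_window)
  pa <- pixel_area_ha(grid)
  areas <- do.call(rbind, lapply(seq_along(years), function(i) {
    cbind(year = years[i], class_areas(filtered[[i]], pa))
  }))
  tm <- transition_matrix(filtered, mode = config$transition_mode)
  list(reference_years = ref_years, stable = stable, classifier = rf,
       accuracy = accuracy, maps_raw = maps, maps = filtered,
       areas = areas, transition = tm)
}

# trend statistics + hydroclimate anomalies and correlations
trends_stage <- function(config, climate, rsei, lc, years) {
  roi_series <- data.frame(
    year = years,
    value = vapply(rsei, function(r) mean(r$rsei, na.rm = TRUE), numeric(1)))
  roi_trend <- trend_test(roi_series$year, roi_series$value)

  jja <- aggregate_climate(climate, "jja")
  jja <- jja[jja$year %in% years, ]
  anom <- list(tmean = anomalies(jja$year, jja$tmean),
               ppt = anomalies(jja$year, jja$ppt),
               cwb = anomalies(jja$year, jja$cwb))

  class_series <- NULL
  class_trends <- NULL
  correlations <- NULL
  if (!is.null(lc)) {
    class_series <- do.call(rbind, lapply(seq_along(years), function(i) {
      sm <- stratified_mean(rsei[[i]]$rsei, lc$maps[[i]])
      cbind(year = years[i], sm)
    }))
    class_trends <- lapply(stats::setNames(nm = names(CLASS_CODES)),
                           function(cn) {
      cls <- CLASS_CODES[[cn]]
      s <- class_series[class_series$class == cls &
                          !is.na(class_series$mean_rsei), ]
      if (nrow(s) < 5) return(NULL)
      trend_test(s$year, s$mean_rsei)
    })
    correlations <- do.call(rbind, lapply(names(CLASS_CODES), function(cn) {
      cls <- CLASS_CODES[[cn]]
      s <- class_series[class_series$class == cls, ]
      do.call(rbind, lapply(names(anom), function(v) {
        cr <- climate_rsei_correlation(
          data.frame(year = s$year, value = s$mean_rsei), anom[[v]])
        data.frame(class = cn, variable = v, r = cr$r, n = cr$n)
      }))
    }))
  }
  list(roi_series = roi_series, roi_trend = roi_trend, climate_jja = jja,
       anomalies = anom, class_series = class_series,
       class_trends = class_trends, correlations = correlations)
}

#' Write a run report to disk
#'
#' CSV tables, the resolved JSON configuration, a JSON summary and a plain
#' log listing every resolved analysis choice. Optional stages are written
#' as JSON `null` fields rather than omitted.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths (the manifest).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  manifest <- c()
  wcsv <- function(df, f) {
    write.csv(df, p(f), row.names = FALSE)
    manifest[[f]] <<- p(f)
  }
  wcsv(report$climate, "climate_monthly.csv")
  wcsv(report$trends$climate_jja, "climate_jja.csv")
  rsei_tab <- do.call(rbind, lapply(report$rsei, function(r) {
    data.frame(year = r$year, variance_share = r$pc1_variance_share,
               flipped = r$orientation_flipped,
               mean_rsei = mean(r$rsei, na.rm = TRUE),
               t(r$pc1_loadings))
  }))
  wcsv(rsei_tab, "rsei_by_year.csv")
  if (!is.null(report$landcover)) {
    wcsv(report$landcover$areas, "class_areas.csv")
    wcsv(report$landcover$accuracy$per_class, "accuracy_per_class.csv")
    wcsv(as.data.frame(report$landcover$transition), "transition_matrix.csv")
    if (!is.null(report$trends$class_series)) {
      wcsv(report$trends$class_series, "class_rsei_series.csv")
    }
    if (!is.null(report$trends$correlations)) {
      wcsv(report$trends$correlations, "climate_correlations.csv")
    }
  }
  wcsv(report$change$patches$table, "change_patches.csv")

  tr <- report$trends$roi_trend
  summary <- list(
    years = range(report$years),
    roi_trend = unclass(tr),
    overall_accuracy = if (!is.null(report$landcover))
      report$landcover$accuracy$overall_accuracy else NULL,
    kappa = if (!is.null(report$landcover))
      report$landcover$accuracy$kappa else NULL,
    change = report$change$summary,
    change_threshold = report$change$threshold$threshold_value,
    n_patches = report$change$patches$n_patches,
    largest_patch_ha = report$change$patches$largest_patch_ha)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest[["summary.json"]] <- p("summary.json")
  save_config(report$config, p("config.json"))
  manifest[["config.json"]] <- p("config.json")

  log_lines <- c(
    sprintf("ndbsi_variant=%s", report$config$ndbsi_variant),
    sprintf("transition_mode=%s", report$config$transition_mode),
    sprintf("coverage_threshold=%g", report$config$coverage_threshold),
    sprintf("change_rule=%s resolved_threshold=%g", report$config$change_rule,
            report$change$threshold$threshold_value),
    sprintf("connectivity=%d", report$config$connectivity),
    sprintf("filter_window=%d", report$config$filter_window),
    sprintf("seed=%d", report$config$seed))
  writeLines(log_lines, p("run.log"))
  manifest[["run.log"]] <- p("run.log")
  unlist(manifest)
}
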