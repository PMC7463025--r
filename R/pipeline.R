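#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters. The master `seed` drives the whole run:
#' each stochastic stage uses the derived seed `seed + 1000 * stage_counter`
#' (stage counters 1 = study area, 2 = sightings, 3 = model fitting,
#' 4 = randomization test), so stages can be re-run in isolation and two runs
#' with the same configuration are identical.
#'
#' @param synthetic a [study_area_config()] describing the synthetic study
#'   area (the seed inside it is overridden by the derived stage seed).
#' @param design a [transect_design()].
#' @param occurrence an [occurrence_params()] ground-truth model.
#' @param expected_schools Poisson mean number of simulated schools.
#' @param buffer_m effort-corridor half width (m).
#' @param screening a [collinearity_config()].
#' @param algorithms,n_runs,calib_fraction,n_perm ensemble settings, see
#'   [esdm()].
#' @param bands an [occurrence_bands()].
#' @param n_permutations randomization-test permutations.
#' @param include_sst if `TRUE`, krige the station SST measurements and add
#'   the layer to the candidate predictors (off by default; the default
#'   eight-predictor set follows the standard overall-model design).
#' @param seed master seed.
#' @param out_dir optional output directory; when given, all tables, rasters,
#'   geometries and the manifest are written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = study_area_config(),
                            design = transect_design(),
                            occurrence = occurrence_params(),
                            expected_schools = 169,
                            buffer_m = 250,
                            screening = collinearity_config(),
                            algorithms = .esdm_algorithms,
                            n_runs = 10, calib_fraction = 0.75, n_perm = 10,
                            bands = occurrence_bands(),
                            n_permutations = 5000,
                            include_sst = FALSE,
                            seed = 1, out_dir = NULL) {
  structure(list(synthetic = synthetic, design = design,
                 occurrence = occurrence,
                 expected_schools = expected_schools, buffer_m = buffer_m,
                 screening = screening, algorithms = algorithms,
                 n_runs = n_runs, calib_fraction = calib_fraction,
                 n_perm = n_perm, bands = bands,
                 n_permutations = n_permutations, include_sst = include_sst,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# polynomial rolling hash of a string (config fingerprinting without extra
# deps; doubles stay exact well below 2^53)
.fnv1a <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  .fnv1a(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12,
                                       force = TRUE)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic study-area generation, transect layout,
#' sighting simulation, effort gridding and response construction
#' (effort-ranked true absences), predictor-layer derivation (depth, slope,
#' seabed complexity, Euclidean distance to coast, cost distances to reef
#' crest / passages / boat ramps / sanctuary zones, categorical benthic
#' habitat, optional kriged SST), collinearity screening (vifcor then
#' vifstep), ensemble model fitting, grid-wide ensemble prediction, band
#' classification, zone summaries and the sanctuary-overlap randomization
#' test. When `out_dir` is set, writes paper-style tables (survey summary,
#' variable importance, zone summary, band proportions), the AUC ledger, the
#' surface raster and the run manifest.
#'
#' @param config a [pipeline_config()].
#' @return a `sdm_pipeline` list holding every intermediate product
#'   (`area`, `transects`, `sightings`, `coverage`, `effort`, `response`,
#'   `layers`, `features`, `screening`, `fit`, `surface`, `bands`,
#'   `zone_summary`, `band_table`, `rand_test`) plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  log_w <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage_seed <- function(i) config$seed + 1000L * i

  withCallingHandlers({
    syn <- config$synthetic
    syn$seed <- stage_seed(1)
    area <- generate_study_area(syn)
    grid <- area$grid

    tl <- generate_transects(area, config$design)
    sightings <- simulate_sightings(area, tl, config$occurrence,
                                    seed = stage_seed(2),
                                    expected_schools = config$expected_schools,
                                    buffer_m = config$buffer_m)
    coverage <- buffer_tracklines(tl, config$buffer_m)
    effort <- effort_per_cell(tl, grid)
    presence <- assign_presence(sightings, grid, coverage)
    response <- select_absences(effort, presence, grid)

    sc <- slope_complexity_layers(area$depth, grid)
    layers <- list(
      habitat = sample_categorical(area$habitat_polygons, grid),
      depth = predictor_layer("depth", area$depth, "continuous", "m"),
      slope = sc$slope,
      complexity = sc$complexity,
      dist_coast = euclidean_distance_layer(grid, geom_lines(area$coastline)),
      dist_boat_ramp = cost_distance_layer(grid, geom_points(area$boat_ramps)),
      dist_reef_crest = cost_distance_layer(grid, geom_lines(area$reef_crest)),
      dist_sanctuary = cost_distance_layer(grid, grid$marine &
                                             !is.na(grid$zone) &
                                             grid$zone == "SZ"),
      dist_passage = cost_distance_layer(grid, geom_points(area$passages)))
    if (config$include_sst)
      layers$sst <- krige_layer(area$sst_samples, grid,
                                variogram = list(nugget = 0.05, sill = 0.6,
                                                 range_m = 10000),
                                name = "sst")
    features <- assemble_feature_table(grid, layers, response, effort)

    screening <- screen_predictors(features, config$screening)
    fml <- stats::as.formula(paste("response ~",
                                   paste(screening$retained, collapse = " + ")))
    fit <- esdm(fml, features, algorithms = config$algorithms,
                n_runs = config$n_runs,
                calib_fraction = config$calib_fraction,
                seed = stage_seed(3), n_perm = config$n_perm)

    # predict over every marine cell with complete predictor data
    m_idx <- which(grid$marine)
    grid_tab <- data.frame(cell_id = m_idx)
    for (nm in names(layers)) {
      lay <- layers[[nm]]
      vals <- unclass(lay)[m_idx]
      if (attr(lay, "kind") == "categorical")
        vals <- factor(vals, levels = levels(features[[nm]]))
      grid_tab[[nm]] <- vals
    }
    ok <- stats::complete.cases(grid_tab)
    surface_cells <- m_idx[ok]
    surface <- ensemble_predict(fit$runs, grid_tab[ok, , drop = FALSE])

    band <- classify_occurrence(surface, config$bands)
    sz_mask <- grid$zone[surface_cells] == "SZ"
    prob_full <- rep(NA_real_, n_cells(grid))
    prob_full[surface_cells] <- surface$probability

    sub_grid <- grid
    sub_grid$marine <- seq_len(n_cells(grid)) %in% surface_cells
    zs <- zone_summary(prob_full, sub_grid)
    band_table <- data.frame(
      band = levels(band),
      entire_pct = 100 * as.numeric(table(band)) / length(band),
      sanctuary_pct = 100 * as.numeric(table(band[sz_mask])) /
        max(1, sum(sz_mask)))
    rt <- randomization_test(band == "High", sz_mask,
                             n_permutations = config$n_permutations,
                             seed = stage_seed(4))

    out <- list(config = config, area = area, transects = tl,
                sightings = sightings, coverage = coverage, effort = effort,
                response = response, layers = layers, features = features,
                screening = screening, fit = fit, surface = surface,
                surface_cells = surface_cells, probability = prob_full,
                bands = band, zone_summary = zs, band_table = band_table,
                rand_test = rt)
  }, warning = log_w)

  manifest <- list(
    config_hash = .config_hash(config),
    seeds = list(master = config$seed, study_area = stage_seed(1),
                 sightings = stage_seed(2), models = stage_seed(3),
                 randomization = stage_seed(4)),
    versions = list(package = as.character(utils::packageVersion("esdm")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    warnings = warnings_log,
    outputs = character(0))
  if (!is.null(config$out_dir)) {
    manifest$outputs <- c(.write_pipeline_outputs(out, config$out_dir),
                          "manifest.json")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out$manifest <- manifest
  class(out) <- "sdm_pipeline"
  out
}

.write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- res$area$grid
  p <- function(f) file.path(dir, f)
  written <- character(0)
  add <- function(f) written <<- c(written, basename(f))

  survey <- data.frame(
    quantity = c("survey_effort_km", "n_schools", "n_presence_cells",
                 "n_absence_cells", "absence_threshold_m"),
    value = c(trackline_length(res$transects) / 1000, nrow(res$sightings),
              length(res$response$presence), length(res$response$absence),
              res$response$absence_threshold_m))
  utils::write.csv(survey, p("survey_summary.csv"), row.names = FALSE)
  add("survey_summary.csv")

  imp <- cbind(model = rownames(res$fit$importance), res$fit$importance)
  utils::write.csv(imp, p("variable_importance.csv"), row.names = FALSE)
  add("variable_importance.csv")

  aucs <- data.frame(
    algorithm = vapply(res$fit$runs, `[[`, character(1), "algorithm"),
    run = vapply(res$fit$runs, `[[`, numeric(1), "run_index"),
    split_seed = vapply(res$fit$runs, `[[`, numeric(1), "split_seed"),
    auc_test = vapply(res$fit$runs, `[[`, numeric(1), "auc_test"))
  utils::write.csv(aucs, p("model_auc.csv"), row.names = FALSE)
  add("model_auc.csv")

  utils::write.csv(res$zone_summary, p("zone_summary.csv"), row.names = FALSE)
  add("zone_summary.csv")
  utils::write.csv(res$band_table, p("band_proportions.csv"),
                   row.names = FALSE)
  add("band_proportions.csv")

  surf <- data.frame(cell_id = res$surface_cells,
                     probability = res$surface$probability,
                     band = as.character(res$bands))
  utils::write.csv(surf, p("ensemble_surface.csv"), row.names = FALSE)
  add("ensemble_surface.csv")
  write_ascii_grid(res$probability, grid, p("ensemble_surface.asc"))
  add("ensemble_surface.asc")
  write_ascii_grid(res$area$depth, grid, p("depth.asc"))
  add("depth.asc")
  write_ascii_grid(as.numeric(res$effort), grid, p("effort.asc"))
  add("effort.asc")

  resp <- as.data.frame(grid)
  resp$effort_m <- as.numeric(res$effort)
  resp$response <- res$response$response
  utils::write.csv(resp, p("response_grid.csv"), row.names = FALSE)
  add("response_grid.csv")

  write_geojson(lapply(res$transects$lines, function(m)
    list(geometry = m, type = "LineString", properties = list())),
    p("transects.geojson"))
  add("transects.geojson")
  write_geojson(lapply(seq_len(nrow(res$sightings)), function(i)
    list(geometry = c(res$sightings$x[i], res$sightings$y[i]),
         type = "Point",
         properties = list(school_size = res$sightings$school_size[i]))),
    p("sightings.geojson"))
  add("sightings.geojson")
  write_geojson(lapply(res$area$zone_polygons, function(z)
    list(geometry = z$ring, type = "Polygon",
         properties = list(zone = z$zone, name = z$name))),
    p("zones.geojson"))
  add("zones.geojson")
  write_geojson(lapply(res$area$habitat_polygons, function(h)
    list(geometry = h$ring, type = "Polygon",
         properties = list(class = h$class))),
    p("habitat.geojson"))
  add("habitat.geojson")

  jsonlite::write_json(
    list(observed_index = res$rand_test$observed_index,
         p_value = res$rand_test$p_value,
         n_permutations = res$rand_test$n_permutations,
         seed = res$rand_test$seed),
    p("randomization.json"), auto_unbox = TRUE, digits = NA)
  add("randomization.json")

  jsonlite::write_json(
    list(vifcor_removed = res$screening$vifcor$removed,
         vifstep_removed = res$screening$vifstep$removed,
         retained = res$screening$retained),
    p("screening.json"), auto_unbox = TRUE, digits = NA)
  add("screening.json")

  cfg <- res$config; cfg$out_dir <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  add("config.json")
  sort(written)
}

#' @export
print.sdm_pipeline <- function(x, ...) {
  cat("Ensemble SDM pipeline run\n")
  cat(sprintf("  sightings: %d schools -> %d presence / %d absence cells\n",
              nrow(x$sightings), length(x$response$presence),
              length(x$response$absence)))
  cat(sprintf("  screening removed: %s\n",
              if (nrow(x$screening$vifcor$removed) +
                  nrow(x$screening$vifstep$removed) == 0) "none"
              else paste(c(x$screening$vifcor$removed$variable,
                           x$screening$vifstep$removed$variable),
                         collapse = ", ")))
  aucs <- vapply(x$fit$runs, `[[`, numeric(1), "auc_test")
  cat(sprintf("  median single-model AUC %.3f; ensemble AUC %.3f\n",
              stats::median(aucs), x$fit$auc_ensemble))
  cat(sprintf("  high-occurrence cells: %d (%.1f%%); randomization p = %.3f\n",
              x$rand_test$n_high,
              100 * x$rand_test$n_high / x$rand_test$n_cells,
              x$rand_test$p_value))
  invisible(x)
}
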