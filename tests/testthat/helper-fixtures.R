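# Shared fixture builders. Everything is generated in code at test time.

# the eight-variable candidate set mirroring the standard overall-model design
std_predictors <- c("habitat", "depth", "slope", "complexity", "dist_coast",
                    "dist_boat_ramp", "dist_reef_crest", "dist_sanctuary")

# full synthetic survey -> feature table for one seed (default study area,
# default transects, default occurrence model)
build_survey <- function(seed, occurrence = occurrence_params(),
                         with_passage = FALSE) {
  area <- generate_study_area(study_area_config(seed = seed))
  grid <- area$grid
  tl <- generate_transects(area)
  sightings <- simulate_sightings(area, tl, occurrence, seed = seed + 500)
  coverage <- buffer_tracklines(tl)
  effort <- suppressMessages(effort_per_cell(tl, grid))
  presence <- suppressWarnings(assign_presence(sightings, grid, coverage))
  response <- suppressMessages(select_absences(effort, presence, grid))
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
                                           grid$zone == "SZ"))
  if (with_passage)
    layers$dist_passage <- cost_distance_layer(grid,
                                               geom_points(area$passages))
  features <- assemble_feature_table(grid, layers, response, effort)
  list(area = area, grid = grid, transects = tl, sightings = sightings,
       coverage = coverage, effort = effort, presence = presence,
       response = response, layers = layers, features = features)
}

# small balanced presence/absence table with a clean signal, for fast
# model-fitting tests
toy_table <- function(n = 120, seed = 1) {
  set.seed(seed)
  d <- data.frame(depth = runif(n, 1, 40),
                  dist = runif(n, 0, 4000),
                  noise = rnorm(n))
  p <- plogis(1.5 - ((d$depth - 10) / 5)^2 - d$dist / 1500)
  d$response <- rbinom(n, 1, p)
  # force both classes
  if (sum(d$response) < 5) d$response[1:5] <- 1
  if (sum(1 - d$response) < 5) d$response[(n - 4):n] <- 0
  d
}
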