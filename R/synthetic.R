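#' Configuration for the synthetic coastal study area
#'
#' Describes a rectangular strip of coastal water backed by land along its
#' northern edge, emulating a ~150 km2 marine-park study area along ~50 km of
#' coastline, up to ~5 km offshore, with water depths between 1 and 45 m and
#' sanctuary / recreation / general-use zones covering about 26/60/14% of the
#' marine area.
#'
#' @param extent_m (width, height) of the rectangle in metres.
#' @param cell_size_m analysis grid resolution in metres.
#' @param coastline_profile parameters of the sinusoidal coastline
#'   `y_coast(x) = mean_width_m + amplitude_m * sin(2*pi*x/wavelength_m + phase)`;
#'   water lies at `y < y_coast(x)`, land above.
#' @param depth_range_m (min, max) water depth in metres; depth increases
#'   monotonically offshore from `min` at the shoreline towards `max`.
#' @param depth_exponent shape of the depth drop seaward of the reef crest:
#'   the drop follows a smoothstep curve raised to `depth_exponent / 1.5`
#'   (the default 1.5 gives a plain smoothstep, flat at both the crest and
#'   the deep plain).
#' @param lagoon fringing-reef lagoon morphology: a gently sloping shallow
#'   lagoon extends from the shoreline out to the reef crest at offshore
#'   distance `L(x) = width_mean_m + amp1_m*sin(2*pi*x/wavelength1_m + phase1)
#'   + amp2_m*sin(2*pi*x/wavelength2_m + phase2)` (clamped at `min_width_m`),
#'   where depth reaches `min + reef_frac * (max - min)`; beyond the crest
#'   the bottom drops to `max` over `drop_width_m`, then a flat deep plain. The along-shore variation of the crest
#'   position is what keeps water depth from being a deterministic function
#'   of distance to coast, as in real fringing-reef coastlines. Lagoon cells
#'   additionally carry patch-reef ("bommie") roughness: their noise standard
#'   deviation is inflated by up to `bommie_factor` times, with along-shore
#'   patchiness of wavelength `bommie_wavelength_m`, so rugged shallow areas
#'   exist alongside smooth deep slopes.
#' @param depth_noise_sd_m base standard deviation (m) of bathymetric noise;
#'   a lagoon cell at bommie-patch peak has standard deviation
#'   `depth_noise_sd_m * (1 + bommie_factor)`.
#' @param zone_fractions named proportions for SZ (sanctuary), RZ (recreation)
#'   and GUZ (general use) zones; must sum to 1.
#' @param n_sst_stations number of fixed environmental stations at which sea
#'   surface temperature is sampled for kriging.
#' @param seed integer RNG seed; the whole study area is a deterministic
#'   function of the configuration.
#' @return a `study_area_config` list.
#' @export
study_area_config <- function(extent_m = c(50000, 5000),
                              cell_size_m = 500,
                              coastline_profile = list(mean_width_m = 3000,
                                                       amplitude_m = 500,
                                                       wavelength_m = 20000,
                                                       phase = 0),
                              depth_range_m = c(1, 45),
                              depth_exponent = 1.5,
                              lagoon = list(reef_frac = 0.12,
                                            drop_width_m = 1800,
                                            width_mean_m = 1200,
                                            amp1_m = 1000, wavelength1_m = 9000,
                                            phase1 = 0.7,
                                            amp2_m = 600, wavelength2_m = 3700,
                                            phase2 = 2.1,
                                            min_width_m = 300,
                                            bommie_factor = 2.5,
                                            bommie_wavelength_m = 5300,
                                            bommie_phase = 2.9,
                                            plain_mod = 0.35,
                                            plain_wavelength_m = 6700,
                                            plain_phase = 0.4,
                                            drop_amp = 0.3,
                                            drop_wavelength_m = 5600,
                                            drop_phase = 1.9,
                                            crest_jitter_m = 500,
                                            crest_jitter_wavelength_m = 4800,
                                            crest_jitter_phase = 0.9,
                                            plain_rough_factor = 2,
                                            plain_rough_wavelength_m = 4100,
                                            plain_rough_phase = 2.2),
                              depth_noise_sd_m = 1.2,
                              zone_fractions = c(SZ = 0.26, RZ = 0.60, GUZ = 0.14),
                              n_sst_stations = 87,
                              seed = 1) {
  if (cell_size_m <= 0) stop("cell_size_m must be positive")
  if (length(depth_range_m) != 2 || depth_range_m[1] > depth_range_m[2])
    stop("depth_range_m must be (min, max) with min <= max")
  if (abs(sum(zone_fractions) - 1) > 1e-9)
    stop("zone_fractions must sum to 1")
  if (is.null(names(zone_fractions))) names(zone_fractions) <- c("SZ", "RZ", "GUZ")
  structure(list(extent_m = as.numeric(extent_m), cell_size_m = cell_size_m,
                 coastline_profile = coastline_profile,
                 depth_range_m = as.numeric(depth_range_m),
                 depth_exponent = depth_exponent,
                 lagoon = lagoon,
                 depth_noise_sd_m = depth_noise_sd_m,
                 zone_fractions = zone_fractions,
                 n_sst_stations = as.integer(n_sst_stations),
                 seed = as.integer(seed)),
            class = "study_area_config")
}

#' Coastline position
#'
#' The y coordinate of the coastline at along-shore position `x`; water lies
#' below (`y < coast_y`), land above.
#' @param area a `study_area` or `study_area_config`.
#' @param x along-shore coordinates (m).
#' @return y coordinates of the coastline (m).
#' @export
coast_y <- function(area, x) {
  cfg <- if (inherits(area, "study_area")) area$config else area
  p <- cfg$coastline_profile
  p$mean_width_m + p$amplitude_m * sin(2 * pi * x / p$wavelength_m + p$phase)
}

#' Reef-crest offshore distance
#'
#' Along-shore position of the fringing reef crest: the offshore distance at
#' which the shallow lagoon ends and the bottom starts dropping.
#' @inheritParams coast_y
#' @return crest distance from the coastline in metres.
#' @export
lagoon_width <- function(area, x) {
  cfg <- if (inherits(area, "study_area")) area$config else area
  lg <- cfg$lagoon
  p <- cfg$coastline_profile
  w_max <- p$mean_width_m + p$amplitude_m
  L <- lg$width_mean_m +
    lg$amp1_m * sin(2 * pi * x / lg$wavelength1_m + lg$phase1) +
    lg$amp2_m * sin(2 * pi * x / lg$wavelength2_m + lg$phase2)
  # crest stays seaward of the shore and inside the study strip
  pmin(pmax(L, lg$min_width_m), w_max - 800, coast_y(cfg, x) - 200)
}

#' Noise-free water depth at a point
#'
#' The deterministic component of the synthetic bathymetry. Inside the lagoon
#' (offshore distance below the local reef-crest distance, [lagoon_width()])
#' depth rises linearly from the shallow end of `depth_range_m` to the crest
#' depth; seaward of the crest it drops towards the deep end as a power of
#' the scaled distance past the crest. For fixed `x` the surface is strictly
#' increasing in offshore distance.
#' @inheritParams coast_y
#' @param x,y point coordinates (m); must be seaward of the coastline.
#' @return depth in metres (positive down).
#' @export
depth_at <- function(area, x, y) {
  cfg <- if (inherits(area, "study_area")) area$config else area
  p <- cfg$coastline_profile
  w_max <- p$mean_width_m + p$amplitude_m
  d <- pmax(0, coast_y(cfg, x) - y)
  dr <- cfg$depth_range_m
  lg <- cfg$lagoon
  L <- lagoon_width(cfg, x)
  reef_depth <- dr[1] + lg$reef_frac * (dr[2] - dr[1])
  # deep-plain depth varies along shore (shoals and basins), so depth is not
  # linearly reconstructible from the distance layers
  plain <- dr[1] + (dr[2] - dr[1]) *
    (1 - lg$plain_mod * (0.5 + 0.5 * sin(2 * pi * x / lg$plain_wavelength_m +
                                           lg$plain_phase)))
  # smoothstep drop of along-shore-varying width from the crest to the deep
  # plain: flat at the crest shoulder and on the plain, steepest mid-drop,
  # so the high-slope band follows the reef rather than a monotone offshore
  # trend
  dw <- lg$drop_width_m *
    (1 + lg$drop_amp * sin(2 * pi * x / lg$drop_wavelength_m + lg$drop_phase))
  s <- pmin(1, pmax(0, (d - L) / dw))
  ramp <- (s^2 * (3 - 2 * s))^(cfg$depth_exponent / 1.5)
  ifelse(d <= L,
         dr[1] + (reef_depth - dr[1]) * d / L,
         reef_depth + pmax(0, plain - reef_depth) * ramp)
}

# class pools per offshore band, shallowest last (y increases toward land)
.habitat_pools <- list(
  deep = c("subtidal reef (seaward)", "deep water soft bottom",
           "macroalgae (limestone reef)"),
  mid = c("coral reef communities (subtidal)", "subtidal reef (lagoonal)",
          "sand"),
  inshore = c("sand", "shoreline reef", "mangroves"))

#' Generate a synthetic coastal study area
#'
#' Builds the full spatial scaffold for the analysis: the 500 m lattice with
#' land mask and zone labels, a noisy bathymetry layer, a benthic-habitat
#' polygon mosaic, coastline / reef-crest / passage / boat-ramp geometry, zone
#' polygons, and fixed stations with sea-surface-temperature measurements.
#'
#' Zone labels are assigned by along-shore blocks (six sanctuary blocks
#' interleaved with recreation and general-use blocks), sized greedily so the
#' realized marine-area fractions track `zone_fractions`.
#'
#' @param config a [study_area_config()].
#' @return an object of class `study_area`: a list with elements `grid`
#'   ([grid_spec()]), `depth` (per-cell metres, `NA` on land), `habitat_polygons`
#'   (mosaic of class-labelled rings), `coastline`, `reef_crest` (polylines),
#'   `passages`, `boat_ramps` (point matrices), `zone_polygons`, `sst_samples`
#'   (data frame x, y, value), and `config`.
#' @export
generate_study_area <- function(config = study_area_config()) {
  stopifnot(inherits(config, "study_area_config"))
  set.seed(config$seed)
  # randomize the seafloor-morphology phases so each seed yields a distinct
  # landscape; the drawn phases are recorded in the returned config
  ph <- stats::runif(7, 0, 2 * pi)
  config$lagoon$phase1 <- ph[1]
  config$lagoon$phase2 <- ph[2]
  config$lagoon$bommie_phase <- ph[3]
  config$lagoon$plain_phase <- ph[4]
  config$lagoon$drop_phase <- ph[5]
  config$lagoon$crest_jitter_phase <- ph[6]
  config$lagoon$plain_rough_phase <- ph[7]
  ex <- config$extent_m; cs <- config$cell_size_m
  n_cols <- as.integer(floor(ex[1] / cs)); n_rows <- as.integer(floor(ex[2] / cs))
  if (n_cols < 1 || n_rows < 1) stop("invalid-config: extent smaller than one cell")
  grid <- grid_spec(c(0, 0), cs, n_rows, n_cols)
  ctr <- cell_centers(grid)
  marine <- ctr[, "y"] < coast_y(config, ctr[, "x"])
  if (sum(marine) < 100)
    stop("invalid-config: extent too small to hold >= 100 marine cells")

  # bathymetry: deterministic lagoon/drop profile plus seeded noise whose
  # amplitude is inflated inside bommie patches of the lagoon; NA on land
  depth <- rep(NA_real_, n_cells(grid))
  det <- depth_at(config, ctr[marine, "x"], ctr[marine, "y"])
  depth[marine] <- det
  if (config$depth_noise_sd_m > 0) {
    lg <- config$lagoon
    reef_depth <- config$depth_range_m[1] +
      lg$reef_frac * diff(config$depth_range_m)
    patch <- 0.5 + 0.5 * sin(2 * pi * ctr[marine, "x"] /
                               lg$bommie_wavelength_m + lg$bommie_phase)
    # rubble/shoal fields also roughen parts of the deep plain
    patch2 <- 0.5 + 0.5 * sin(2 * pi * ctr[marine, "x"] /
                                lg$plain_rough_wavelength_m +
                                lg$plain_rough_phase)
    dr <- config$depth_range_m
    on_plain <- det >= dr[1] + 0.85 * (max(det) - dr[1])
    sd_vec <- config$depth_noise_sd_m *
      (1 + lg$bommie_factor * patch * (det <= reef_depth) +
         lg$plain_rough_factor * patch2 * on_plain)
    depth[marine] <- pmax(0.3, det + stats::rnorm(sum(marine), 0, sd_vec))
  }

  # zone blocks along shore: 6 SZ blocks interleaved with RZ and GUZ
  zf <- config$zone_fractions
  seg_label <- c("SZ", "RZ", "SZ", "RZ", "SZ", "GUZ",
                 "SZ", "RZ", "SZ", "RZ", "SZ", "GUZ")
  seg_frac <- ifelse(seg_label == "SZ", zf[["SZ"]] / 6,
                     ifelse(seg_label == "RZ", zf[["RZ"]] / 4, zf[["GUZ"]] / 2))
  col_of <- cell_rowcol(grid, seq_len(n_cells(grid)))[, "col"]
  marine_per_col <- tabulate(col_of[marine], nbins = n_cols)
  total_marine <- sum(marine_per_col)
  col_seg <- integer(n_cols)
  target_cum <- cumsum(seg_frac) * total_marine
  cum <- cumsum(marine_per_col)
  seg_i <- 1L
  for (cc in seq_len(n_cols)) {
    while (seg_i < length(seg_label) && cum[cc] > target_cum[seg_i] + 1e-9)
      seg_i <- seg_i + 1L
    col_seg[cc] <- seg_i
  }
  sz_counter <- cumsum(seg_label == "SZ")
  rz_counter <- cumsum(seg_label == "RZ")
  guz_counter <- cumsum(seg_label == "GUZ")
  seg_name <- ifelse(seg_label == "SZ", paste("SZ", sz_counter),
                     ifelse(seg_label == "RZ", paste("RZ", rz_counter),
                            paste("GUZ", guz_counter)))
  zone <- ifelse(marine, seg_label[col_seg[col_of]], NA_character_)
  zone_name <- ifelse(marine, seg_name[col_seg[col_of]], NA_character_)
  grid$zone <- zone
  grid$zone_name <- zone_name
  seg_breaks <- c(0, vapply(seq_along(seg_label), function(s)
    max(which(col_seg == s), 0) * cs, numeric(1)))
  zone_polygons <- list()
  for (s in seq_along(seg_label)) {
    if (seg_breaks[s + 1] <= seg_breaks[s]) next
    ring <- rbind(c(seg_breaks[s], 0), c(seg_breaks[s + 1], 0),
                  c(seg_breaks[s + 1], ex[2]), c(seg_breaks[s], ex[2]),
                  c(seg_breaks[s], 0))
    zone_polygons[[length(zone_polygons) + 1]] <-
      list(ring = ring, zone = seg_label[s], name = seg_name[s])
  }

  # benthic habitat mosaic: random along-shore strips x three depth bands
  xb <- 0
  while (xb[length(xb)] < ex[1])
    xb <- c(xb, xb[length(xb)] + stats::runif(1, 2000, 6000))
  xb[length(xb)] <- ex[1]
  habitat_polygons <- list()
  for (i in seq_len(length(xb) - 1)) {
    y1 <- stats::runif(1, 800, 1500)   # deep | mid boundary
    y2 <- stats::runif(1, 2000, 2800)  # mid | inshore boundary
    yy <- c(0, y1, y2, ex[2])
    bands <- c("deep", "mid", "inshore")
    for (b in 1:3) {
      cls <- sample(.habitat_pools[[bands[b]]], 1)
      ring <- rbind(c(xb[i], yy[b]), c(xb[i + 1], yy[b]),
                    c(xb[i + 1], yy[b + 1]), c(xb[i], yy[b + 1]),
                    c(xb[i], yy[b]))
      habitat_polygons[[length(habitat_polygons) + 1]] <-
        list(ring = ring, class = cls)
    }
  }

  # coastline, reef crest (the lagoon edge), passages, ramps
  xs <- seq(0, ex[1], by = 250)
  coastline <- cbind(x = xs, y = coast_y(config, xs))
  p <- config$coastline_profile
  w_max <- p$mean_width_m + p$amplitude_m
  # the mapped crest line carries an along-shore jitter relative to the
  # bathymetric crest, as a habitat map digitized from imagery would
  lg <- config$lagoon
  crest_off <- function(x) {
    y <- coast_y(config, x) - lagoon_width(config, x) -
      lg$crest_jitter_m * sin(2 * pi * x / lg$crest_jitter_wavelength_m +
                                lg$crest_jitter_phase)
    pmin(pmax(y, 100), ex[2] - 100)
  }
  xs2 <- seq(0, ex[1], by = 500)
  reef_crest <- cbind(x = xs2, y = crest_off(xs2))
  px <- seq(2500, ex[1], by = 5000)  # reef passages along the crest
  passages <- cbind(x = px, y = crest_off(px))
  rx <- c(0.10, 0.55, 0.95) * ex[1]
  boat_ramps <- cbind(x = rx, y = coast_y(config, rx) - 200)

  # fixed environmental stations with SST measurements (degC)
  m_idx <- which(marine)
  st <- sample(m_idx, min(config$n_sst_stations, length(m_idx)))
  st_xy <- cell_centers(grid, st)
  sst <- 24 + 1.5 * st_xy[, "x"] / ex[1] +
    0.8 * (coast_y(config, st_xy[, "x"]) - st_xy[, "y"]) / w_max +
    stats::rnorm(length(st), 0, 0.3)
  sst_samples <- data.frame(x = st_xy[, "x"], y = st_xy[, "y"], value = sst)

  grid$marine <- marine
  structure(list(grid = grid, depth = depth,
                 habitat_polygons = habitat_polygons,
                 coastline = coastline, reef_crest = reef_crest,
                 passages = passages, boat_ramps = boat_ramps,
                 zone_polygons = zone_polygons, sst_samples = sst_samples,
                 config = config),
            class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  g <- x$grid
  cat(sprintf(paste0("study_area: %.0f x %.0f km extent, %d marine cells of ",
                     "%g m\nzones: %s\n"),
              x$config$extent_m[1] / 1000, x$config$extent_m[2] / 1000,
              sum(g$marine), g$cell_size_m,
              paste(sprintf("%s %.0f%%", names(table(g$zone)),
                            100 * table(g$zone) / sum(g$marine)),
                    collapse = ", ")))
  invisible(x)
}

#' Zig-zag transect design
#'
#' Parameters for two opposing, evenly spaced zig-zag transect sets plus an
#' optional single along-shore line, the classic systematic line-transect
#' layout for small-cetacean surveys of a coastal strip.
#'
#' @param spacing_m along-shore distance between successive zig-zag vertices.
#' @param n_sets number of opposing zig-zag sets (0, 1 or 2).
#' @param single_line_km length of an extra single line run mid-lagoon
#'   parallel to shore (0 for none).
#' @param inshore_margin_m,offshore_margin_m distance kept between transect
#'   vertices and the coastline / offshore boundary.
#' @return a `transect_design` list.
#' @export
transect_design <- function(spacing_m = 2500, n_sets = 2, single_line_km = 13,
                            inshore_margin_m = 300, offshore_margin_m = 300) {
  if (spacing_m <= 0) stop("invalid-design: spacing must be positive")
  structure(list(spacing_m = spacing_m, n_sets = as.integer(n_sets),
                 single_line_km = single_line_km,
                 inshore_margin_m = inshore_margin_m,
                 offshore_margin_m = offshore_margin_m),
            class = "transect_design")
}

#' Construct a trackline set from raw polylines
#' @param lines list of two-column coordinate matrices (projected metres).
#' @param design optional [transect_design()] that produced them.
#' @return an object of class `tracklines`.
#' @export
tracklines <- function(lines = list(), design = NULL) {
  lines <- lapply(lines, function(m) matrix(as.numeric(m), ncol = 2))
  structure(list(lines = lines, design = design), class = "tracklines")
}

#' Total trackline length
#' @param tl a `tracklines` object.
#' @return total length in metres.
#' @export
trackline_length <- function(tl) {
  sum(vapply(tl$lines, function(m) {
    if (nrow(m) < 2) return(0)
    sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
  }, numeric(1)))
}

#' @export
print.tracklines <- function(x, ...) {
  cat(sprintf("tracklines: %d lines, total length %.1f km\n",
              length(x$lines), trackline_length(x) / 1000))
  invisible(x)
}

#' Generate zig-zag survey transects
#'
#' Lays out `n_sets` opposing zig-zag polylines between the inshore and
#' offshore margins of the marine strip, plus an optional single along-shore
#' line. Opposing sets interleave: one starts inshore, the other offshore, so
#' their legs cross mid-strip.
#'
#' @param area a [generate_study_area()] result.
#' @param design a [transect_design()].
#' @return a [tracklines()] object; total length is available via
#'   [trackline_length()].
#' @export
generate_transects <- function(area, design = transect_design()) {
  stopifnot(inherits(area, "study_area"))
  ex <- area$config$extent_m
  if (design$spacing_m > ex[1])
    stop("invalid-design: spacing exceeds the study extent")
  lines <- list()
  if (design$n_sets >= 1) {
    xs <- seq(0, ex[1], by = design$spacing_m)
    y_in <- coast_y(area, xs) - design$inshore_margin_m
    y_off <- rep(design$offshore_margin_m, length(xs))
    for (s in seq_len(design$n_sets)) {
      start_in <- s %% 2 == 1  # set 1 starts inshore, set 2 offshore
      ys <- ifelse((seq_along(xs) %% 2 == 1) == start_in, y_in, y_off)
      lines[[length(lines) + 1]] <- cbind(xs, ys)
    }
  }
  if (design$single_line_km > 0) {
    xe <- min(design$single_line_km * 1000, ex[1])
    xs <- seq(0, xe, by = 500)
    lines[[length(lines) + 1]] <- cbind(xs, 0.5 * coast_y(area, xs))
  }
  tl <- tracklines(lines, design)
  for (m in tl$lines) {
    inside <- m[, 1] >= 0 & m[, 1] <= ex[1] & m[, 2] >= 0 & m[, 2] <= ex[2]
    if (!all(inside)) stop("transect vertices fall outside the study extent")
  }
  tl
}

#' Parameters of the synthetic occurrence model
#'
#' The ground-truth probability that a dolphin school occupies a location,
#' built from the two drivers the species is known for: a Gaussian preference
#' for a focal water depth and an exponential decay with distance from the
#' coast, on the logit scale:
#' `logit(p) = baseline - ((depth - center)/width)^2 - dist_coast_km/decay +
#' sum(nuisance)`.
#'
#' @param depth_pref_center_m preferred water depth (m).
#' @param depth_pref_width_m depth tolerance (m); strictly positive.
#' @param coast_decay_km e-folding scale of the distance-to-coast effect (km);
#'   strictly positive.
#' @param baseline_logit intercept on the logit scale.
#' @param nuisance_coefs named numeric vector of coefficients for additional
#'   (non-driver) predictors; defaults to none.
#' @return an `occurrence_params` list.
#' @export
occurrence_params <- function(depth_pref_center_m = 10, depth_pref_width_m = 4.5,
                              coast_decay_km = 0.5, baseline_logit = 1,
                              nuisance_coefs = NULL) {
  if (depth_pref_width_m <= 0) stop("depth_pref_width_m must be strictly positive")
  if (coast_decay_km <= 0) stop("coast_decay_km must be strictly positive")
  structure(list(depth_pref_center_m = depth_pref_center_m,
                 depth_pref_width_m = depth_pref_width_m,
                 coast_decay_km = coast_decay_km,
                 baseline_logit = baseline_logit,
                 nuisance_coefs = nuisance_coefs),
            class = "occurrence_params")
}

#' Ground-truth occurrence probability
#'
#' Evaluates the synthetic occurrence model at given predictor values. The
#' probability is unimodal in depth with its maximum at the preferred depth,
#' and non-increasing in distance to coast.
#'
#' @param predictors data frame or named list holding at least `depth` (m) and
#'   `dist_coast` (m), plus any variables named in `nuisance_coefs`.
#' @param params an [occurrence_params()].
#' @return probabilities in (0, 1).
#' @export
true_occurrence_probability <- function(predictors, params = occurrence_params()) {
  for (f in c("depth", "dist_coast"))
    if (is.null(predictors[[f]]))
      stop(sprintf("predictor '%s' is required by the occurrence model", f))
  lg <- params$baseline_logit -
    ((predictors$depth - params$depth_pref_center_m) / params$depth_pref_width_m)^2 -
    (predictors$dist_coast / 1000) / params$coast_decay_km
  if (!is.null(params$nuisance_coefs)) {
    for (nm in names(params$nuisance_coefs)) {
      if (is.null(predictors[[nm]]))
        stop(sprintf("predictor '%s' is required by the occurrence model", nm))
      lg <- lg + params$nuisance_coefs[[nm]] * predictors[[nm]]
    }
  }
  stats::plogis(lg)
}

#' Simulate dolphin school sightings along surveyed transects
#'
#' Draws sightings from a point process restricted to the on-effort corridor
#' (the transects buffered by `buffer_m` each side, flat caps) with intensity
#' proportional to [true_occurrence_probability()] evaluated on the realized
#' bathymetry of the study area (the cell's depth, i.e. the habitat the
#' animals actually occupy) and the distance to coast. The total count is
#' Poisson with mean
#' `expected_schools`, so the rate is directly controllable; `expected_schools
#' = 0` yields an empty set. One point is one school; a school size is drawn
#' per point but not used downstream.
#'
#' @param area a `study_area`.
#' @param tl a non-empty [tracklines()] object.
#' @param params an [occurrence_params()].
#' @param seed integer RNG seed.
#' @param expected_schools expected number of schools (Poisson mean).
#' @param buffer_m half-width of the effort corridor (m).
#' @return a `sighting_set`: data frame with `x`, `y`, `school_size` and
#'   attribute `buffer_m`.
#' @export
simulate_sightings <- function(area, tl, params = occurrence_params(),
                               seed = 1, expected_schools = 169,
                               buffer_m = 250) {
  stopifnot(inherits(area, "study_area"), inherits(tl, "tracklines"))
  if (length(tl$lines) == 0 || trackline_length(tl) == 0)
    stop("effort corridor has zero area: tracklines are empty")
  set.seed(as.integer(seed))
  n <- stats::rpois(1, expected_schools)
  ex <- area$config$extent_m
  segs <- do.call(rbind, lapply(tl$lines, function(m) {
    if (nrow(m) < 2) return(NULL)
    cbind(m[-nrow(m), , drop = FALSE], m[-1, , drop = FALSE])
  }))
  seg_len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  keep <- seg_len > 0
  segs <- segs[keep, , drop = FALSE]; seg_len <- seg_len[keep]
  pts <- matrix(NA_real_, n, 2)
  i <- 0L; tries <- 0L
  while (i < n) {
    tries <- tries + 1L
    if (tries > 200000L) stop("sighting simulation failed to converge")
    s <- sample.int(nrow(segs), 1, prob = seg_len)
    t <- stats::runif(1)
    ux <- (segs[s, 3] - segs[s, 1]) / seg_len[s]
    uy <- (segs[s, 4] - segs[s, 2]) / seg_len[s]
    off <- stats::runif(1, -buffer_m, buffer_m)
    x <- segs[s, 1] + t * (segs[s, 3] - segs[s, 1]) - uy * off
    y <- segs[s, 2] + t * (segs[s, 4] - segs[s, 2]) + ux * off
    if (x < 0 || x > ex[1] || y < 0 || y >= coast_y(area, x)) next
    cell <- cell_of_point(area$grid, matrix(c(x, y), 1))
    # shoreline slivers whose cell is classed as land carry no predictor
    # data; schools are only generated on surveyable marine cells
    if (is.na(cell) || !area$grid$marine[cell]) next
    z <- area$depth[cell]
    p <- true_occurrence_probability(
      list(depth = z, dist_coast = max(0, coast_y(area, x) - y)), params)
    if (stats::runif(1) < p) { i <- i + 1L; pts[i, ] <- c(x, y) }
  }
  out <- data.frame(x = pts[, 1], y = pts[, 2],
                    school_size = 1L + stats::rpois(n, 2.5))
  attr(out, "buffer_m") <- buffer_m
  class(out) <- c("sighting_set", "data.frame")
  out
}
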