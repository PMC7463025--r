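test_that("configuration invariants are enforced", {
  expect_error(study_area_config(zone_fractions = c(SZ = 0.5, RZ = 0.5,
                                                    GUZ = 0.5)), "sum to 1")
  expect_error(study_area_config(cell_size_m = 0), "positive")
  expect_error(study_area_config(depth_range_m = c(10, 5)), "min <= max")
  expect_error(occurrence_params(depth_pref_width_m = 0), "positive")
  expect_error(occurrence_params(coast_decay_km = -1), "positive")
  expect_error(transect_design(spacing_m = 0), "invalid-design")
})

test_that("zone blocks partition the marine area near the target fractions", {
  area <- generate_study_area(study_area_config())
  g <- area$grid
  marine <- which(g$marine)
  # every marine cell carries exactly one zone label, no land cell does
  expect_false(anyNA(g$zone[marine]))
  expect_true(all(is.na(g$zone[!g$marine])))
  fr <- table(g$zone[marine]) / length(marine)
  expect_gte(fr[["SZ"]], 0.21); expect_lte(fr[["SZ"]], 0.31)
  expect_equal(sum(fr), 1)
  # zone blocks sum to the marine area exactly (cell bookkeeping)
  expect_equal(sum(table(g$zone_name[marine])), length(marine))
})

test_that("too small an extent is an invalid configuration", {
  expect_error(generate_study_area(study_area_config(extent_m = c(3000, 4000))),
               "invalid-config")
})

test_that("depth increases monotonically offshore when noise is zero", {
  cfg <- study_area_config(depth_noise_sd_m = 0)
  area <- generate_study_area(cfg)
  g <- area$grid
  for (col in c(3, 25, 50, 75, 98)) {
    cells <- cell_index(g, seq_len(g$n_rows), rep(col, g$n_rows))
    d <- area$depth[cells]
    d <- d[g$marine[cells]]  # rows above the coast are land
    # row 1 is farthest offshore; depth must not increase shoreward
    expect_true(all(diff(d) <= 1e-9))
  }
  expect_gte(min(area$depth, na.rm = TRUE), cfg$depth_range_m[1] - 1e-9)
  expect_lte(max(area$depth, na.rm = TRUE), cfg$depth_range_m[2] + 1e-9)
})

test_that("degenerate depth range with zero noise gives a constant surface", {
  cfg <- study_area_config(depth_range_m = c(7, 7), depth_noise_sd_m = 0)
  area <- generate_study_area(cfg)
  expect_equal(unique(area$depth[area$grid$marine]), 7)
})

test_that("the study area is byte-identical under a fixed seed", {
  cfg <- study_area_config(seed = 99)
  expect_identical(generate_study_area(cfg), generate_study_area(cfg))
})

test_that("a single leg across a 10 km strip at 45 degrees has length 10*sqrt(2) km", {
  tl <- tracklines(list(rbind(c(0, 0), c(10000, 10000))))
  expect_equal(trackline_length(tl), 10000 * sqrt(2), tolerance = 1e-9)
})

test_that("an empty design yields an empty trackline set", {
  area <- generate_study_area(study_area_config())
  tl <- generate_transects(area, transect_design(n_sets = 0,
                                                 single_line_km = 0))
  expect_length(tl$lines, 0)
  expect_equal(trackline_length(tl), 0)
})

test_that("spacing beyond the study extent is an invalid design", {
  area <- generate_study_area(study_area_config())
  expect_error(generate_transects(area, transect_design(spacing_m = 60000)),
               "invalid-design")
})

test_that("opposing zig-zags at 250 m buffer cover at least 80% of marine cells", {
  area <- generate_study_area(study_area_config())
  g <- area$grid
  cov <- buffer_tracklines(generate_transects(area), 250)
  sub <- (seq_len(10) - 0.5) / 10 * g$cell_size_m  # 50 m subcells
  m_idx <- which(g$marine)
  covered <- vapply(m_idx, function(ci) {
    ll <- cell_centers(g, ci) - g$cell_size_m / 2
    pts <- cbind(rep(ll[1] + sub, each = 10), rep(ll[2] + sub, times = 10))
    any(coverage_contains(cov, pts))
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("transect vertices stay inside the extent and over water", {
  area <- generate_study_area(study_area_config())
  tl <- generate_transects(area)
  for (m in tl$lines) {
    expect_true(all(m[, 2] < coast_y(area, m[, 1])))
    expect_true(all(m[, 1] >= 0 & m[, 1] <= area$config$extent_m[1]))
  }
})

test_that("occurrence probability follows the documented logistic form", {
  # at the preferred depth on the shoreline with zero baseline: exactly 1/2
  p0 <- occurrence_params(baseline_logit = 0)
  expect_equal(true_occurrence_probability(
    list(depth = p0$depth_pref_center_m, dist_coast = 0), p0), 0.5)
  # defaults at depth 10 m on the coast: closed form
  pd <- occurrence_params()
  expect_equal(true_occurrence_probability(list(depth = 10, dist_coast = 0), pd),
               plogis(pd$baseline_logit), tolerance = 1e-12)
  # hand evaluation at an arbitrary point
  expect_equal(
    true_occurrence_probability(list(depth = 17, dist_coast = 1200), pd),
    plogis(pd$baseline_logit - ((17 - 10) / pd$depth_pref_width_m)^2 -
             1.2 / pd$coast_decay_km),
    tolerance = 1e-12)
  # preferred shallow nearshore beats deep offshore
  expect_gt(true_occurrence_probability(list(depth = 10, dist_coast = 500), pd),
            true_occurrence_probability(list(depth = 40, dist_coast = 4000), pd))
  # unimodal in depth, non-increasing in distance
  depths <- seq(1, 45, by = 0.5)
  pp <- true_occurrence_probability(list(depth = depths, dist_coast = 0), pd)
  peak <- which.max(pp)
  expect_equal(depths[peak], pd$depth_pref_center_m)
  expect_true(all(diff(pp[seq_len(peak)]) >= 0))
  expect_true(all(diff(pp[peak:length(pp)]) <= 0))
  dd <- true_occurrence_probability(
    list(depth = 10, dist_coast = seq(0, 5000, by = 100)), pd)
  expect_true(all(diff(dd) <= 0))
  expect_error(true_occurrence_probability(list(depth = 5), pd), "dist_coast")
})

test_that("nuisance coefficients require and use their named predictors", {
  pp <- occurrence_params(nuisance_coefs = c(sst = 0.5))
  expect_error(true_occurrence_probability(list(depth = 10, dist_coast = 0), pp),
               "sst")
  a <- true_occurrence_probability(list(depth = 10, dist_coast = 0, sst = 2), pp)
  b <- true_occurrence_probability(list(depth = 10, dist_coast = 0, sst = 0), pp)
  expect_equal(qlogis(a) - qlogis(b), 1, tolerance = 1e-9)
})

test_that("sightings land in the corridor, over water, reproducibly", {
  area <- generate_study_area(study_area_config())
  tl <- generate_transects(area)
  s1 <- simulate_sightings(area, tl, seed = 11)
  s2 <- simulate_sightings(area, tl, seed = 11)
  expect_identical(s1, s2)
  cov <- buffer_tracklines(tl, 250)
  expect_true(all(coverage_contains(cov, cbind(s1$x, s1$y))))
  expect_true(all(s1$y < coast_y(area, s1$x)))
  expect_true(all(s1$school_size >= 1))
  # rate zero gives an empty set; empty tracklines are an error
  expect_equal(nrow(simulate_sightings(area, tl, seed = 1,
                                       expected_schools = 0)), 0)
  expect_error(simulate_sightings(area, tracklines(), seed = 1),
               "zero area")
})

test_that("the mean school count emulates the survey total", {
  area <- generate_study_area(study_area_config())
  tl <- generate_transects(area)
  counts <- vapply(1:30, function(s)
    nrow(simulate_sightings(area, tl, seed = s)), numeric(1))
  expect_gte(mean(counts), 150)
  expect_lte(mean(counts), 190)
})

test_that("sighting intensity is proportional to occurrence probability", {
  area <- generate_study_area(study_area_config())
  grid <- area$grid
  tl <- generate_transects(area)
  pars <- occurrence_params()
  ctr <- cell_centers(grid)
  m_idx <- which(grid$marine)
  p_cell <- rep(0, length(area$depth))
  p_cell[m_idx] <- true_occurrence_probability(
    list(depth = area$depth[m_idx],
         dist_coast = pmax(0, coast_y(area, ctr[m_idx, 1]) - ctr[m_idx, 2])),
    pars)
  counts <- numeric(length(p_cell))
  for (s in 1:100) {
    sg <- simulate_sightings(area, tl, pars, seed = s)
    cells <- cell_of_point(grid, cbind(sg$x, sg$y))
    tab <- table(cells)
    counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
      as.numeric(tab)
  }
  qs <- quantile(p_cell[m_idx], c(0.1, 0.9))
  top <- m_idx[p_cell[m_idx] >= qs[2]]
  bottom <- m_idx[p_cell[m_idx] <= qs[1]]
  expect_gt(sum(counts[top]), sum(counts[bottom]))
})

test_that("presence cells concentrate in the 5-15 m preferred band", {
  in_band <- total <- 0
  for (s in 1:25) {
    area <- generate_study_area(study_area_config(seed = s))
    tl <- generate_transects(area)
    sg <- simulate_sightings(area, tl, seed = s + 1000)
    pres <- suppressWarnings(assign_presence(sg, area$grid,
                                             buffer_tracklines(tl)))
    d <- area$depth[pres]
    in_band <- in_band + sum(d >= 5 & d <= 15)
    total <- total + length(d)
  }
  expect_gte(in_band / total, 0.6)
})
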