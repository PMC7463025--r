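test_that("euclidean distance to a straight coastline is the perpendicular", {
  g <- grid_spec(c(0, 0), 500, n_rows = 3, n_cols = 1)
  # horizontal line 700 m north of the centroid of cell 2 (centroid y = 750)
  lay <- euclidean_distance_layer(g, geom_lines(rbind(c(-1000, 1450),
                                                      c(1000, 1450))))
  expect_equal(unclass(lay)[2], 700)
  expect_error(geom_lines(list()), "empty")
})

test_that("cells inside or intersected by the target get distance zero", {
  g <- grid_spec(c(0, 0), 500, 2, 2)
  poly <- geom_polygon(rbind(c(0, 0), c(1000, 0), c(1000, 400), c(0, 400)))
  lay <- euclidean_distance_layer(g, poly)
  expect_equal(unclass(lay)[1], 0)  # centroid (250,250) inside
  expect_equal(unclass(lay)[2], 0)
  line <- geom_lines(rbind(c(100, 100), c(400, 400)))
  expect_equal(unclass(euclidean_distance_layer(g, line))[1], 0)
})

test_that("euclidean distance matches a densified-vertex oracle within 1 m", {
  set.seed(5)
  g <- grid_spec(c(0, 0), 500, 20, 20)
  # a wiggly coastline across the top of the grid
  xs <- seq(-500, 10500, by = 500)
  coast <- cbind(xs, 9000 + 600 * sin(xs / 1500) + runif(length(xs), -200, 200))
  lay <- euclidean_distance_layer(g, geom_lines(coast))
  # oracle: minimum distance to the polyline densified at 1 m steps
  dense <- do.call(rbind, lapply(seq_len(nrow(coast) - 1), function(i) {
    a <- coast[i, ]; b <- coast[i + 1, ]
    L <- sqrt(sum((b - a)^2)); t <- seq(0, 1, length.out = ceiling(L) + 1)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  ctr <- cell_centers(g)
  for (ci in sample(400, 40)) {
    o <- min(sqrt((dense[, 1] - ctr[ci, 1])^2 + (dense[, 2] - ctr[ci, 2])^2))
    expect_lt(abs(unclass(lay)[ci] - o), 1)
  }
})

test_that("cost distance equals euclidean in open water up to the lattice bound", {
  g <- grid_spec(c(0, 0), 500, 15, 15)
  target <- cell_index(g, 8, 8)
  cd <- cost_distance_layer(g, target)
  eu <- euclidean_distance_layer(g, geom_points(cell_centers(g, target)))
  expect_equal(unclass(cd)[target], 0)
  ok <- which(g$marine)
  # octile lattice overestimates straight lines by at most ~8.25%
  expect_true(all(unclass(cd)[ok] >= unclass(eu)[ok] - 1e-9))
  expect_true(all(unclass(cd)[ok] <= unclass(eu)[ok] * 1.083 + 1e-6))
  # exact along the target's own row
  row_cells <- cell_index(g, rep(8, 15), 1:15)
  expect_equal(unclass(cd)[row_cells], abs(1:15 - 8) * 500)
})

test_that("cost distance around a peninsula matches an independent Dijkstra", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (case in 1:5) {
    g <- grid_spec(c(0, 0), 500, 20, 20)
    marine <- rep(TRUE, 400)
    # a U-shaped peninsula plus random land speckle
    rc <- cell_rowcol(g, 1:400)
    marine[rc[, "row"] %in% 5:15 & rc[, "col"] == 10] <- FALSE
    marine[rc[, "row"] == 15 & rc[, "col"] %in% 8:12] <- FALSE
    marine[sample(400, 30)] <- FALSE
    target <- sample(which(marine), 1)
    g$marine <- marine
    suppressWarnings(cd <- cost_distance_layer(g, target))
    # oracle: igraph shortest paths over the same weighted lattice
    edges <- NULL; weights <- NULL
    for (cell in which(marine)) {
      r <- rc[cell, "row"]; cc <- rc[cell, "col"]
      for (k in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
        r2 <- r + k[1]; c2 <- cc + k[2]
        if (r2 < 1 || r2 > 20 || c2 < 1 || c2 > 20) next
        nb <- cell_index(g, r2, c2)
        if (!marine[nb]) next
        edges <- c(edges, cell, nb)
        weights <- c(weights, if (all(k != 0)) 500 * sqrt(2) else 500)
      }
    }
    gr <- igraph::make_graph(edges, n = 400, directed = FALSE)
    dmat <- igraph::distances(gr, v = target, weights = weights)
    dmat[is.infinite(dmat)] <- NA
    got <- unclass(cd)[which(marine)]
    want <- as.numeric(dmat)[which(marine)]
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("unreachable marine cells are flagged and excluded", {
  g <- grid_spec(c(0, 0), 500, 1, 5,
                 marine = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_warning(cd <- cost_distance_layer(g, 1L), "unreachable")
  expect_true(all(is.na(unclass(cd)[4:5])))
  expect_equal(attr(cd, "excluded_cells"), c(4L, 5L))
  expect_error(cost_distance_layer(g, integer(0)), "no marine target")
})

test_that("slope and complexity are zero on a constant surface", {
  g <- grid_spec(c(0, 0), 500, 5, 5)
  sc <- slope_complexity_layers(rep(10, 25), g)
  expect_true(all(unclass(sc$slope) == 0))
  expect_true(all(unclass(sc$complexity) == 0))
})

test_that("a planar ramp of 1 m per cell gives the closed-form slope", {
  g <- grid_spec(c(0, 0), 500, 5, 5)
  depth <- cell_rowcol(g, 1:25)[, "col"] * 1.0  # 1 m per 500 m eastward
  sc <- slope_complexity_layers(depth, g)
  interior <- cell_index(g, rep(2:4, each = 3), rep(2:4, times = 3))
  expect_equal(unclass(sc$slope)[interior],
               rep(atan(1 / 500) * 180 / pi, 9), tolerance = 1e-12)
})

test_that("terrain statistics match a direct neighbourhood recomputation", {
  set.seed(21)
  g <- grid_spec(c(0, 0), 500, 8, 9,
                 marine = runif(72) > 0.2)
  depth <- ifelse(g$marine, runif(72, 1, 40), NA)
  sc <- suppressMessages(slope_complexity_layers(depth, g))
  rc <- cell_rowcol(g, 1:72)
  for (cell in which(g$marine)) {
    r <- rc[cell, "row"]; cc <- rc[cell, "col"]
    nb_z <- c(); nb_d <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > 8 || c2 < 1 || c2 > 9) next
      nb <- cell_index(g, r2, c2)
      if (!g$marine[nb]) next
      nb_z <- c(nb_z, depth[nb])
      nb_d <- c(nb_d, 500 * sqrt(dr^2 + dc^2))
    }
    want_slope <- if (length(nb_z)) atan(max(abs(nb_z - depth[cell]) / nb_d)) *
      180 / pi else 0
    want_cplx <- if (length(nb_z)) sd(c(depth[cell], nb_z)) else 0
    expect_equal(unclass(sc$slope)[cell], want_slope, tolerance = 1e-9)
    expect_equal(unclass(sc$complexity)[cell], want_cplx, tolerance = 1e-9)
  }
})

test_that("kriging reproduces constants and interpolates exactly at samples", {
  vg <- list(nugget = 0, sill = 2, range_m = 3000)
  samples <- data.frame(x = c(0, 1000, 2000, 500), y = c(0, 500, 0, 1500),
                        value = 7)
  kp <- krige_points(samples, cbind(c(700, 1300), c(200, 900)), vg)
  expect_equal(kp$pred, c(7, 7))
  samples$value <- c(3, 9, 5, 1)
  at_sample <- krige_points(samples, cbind(1000, 500), vg)
  expect_equal(at_sample$pred, 9, tolerance = 1e-9)
})

test_that("a 3-sample kriging prediction solves the hand-assembled system", {
  vg <- list(nugget = 0.1, sill = 1.5, range_m = 2500)
  s <- data.frame(x = c(0, 1200, 400), y = c(0, 300, 900),
                  value = c(2, 5, 3))
  p0 <- c(600, 400)
  kp <- krige_points(s, rbind(p0), vg)
  sph <- function(h) ifelse(h <= 0, 0, ifelse(h >= vg$range_m, vg$sill,
    vg$nugget + (vg$sill - vg$nugget) *
      (1.5 * h / vg$range_m - 0.5 * (h / vg$range_m)^3)))
  h <- as.matrix(dist(cbind(s$x, s$y)))
  A <- rbind(cbind(sph(h), 1), c(1, 1, 1, 0))
  b <- c(sph(sqrt((s$x - p0[1])^2 + (s$y - p0[2])^2)), 1)
  w <- solve(A, b)[1:3]
  expect_equal(kp$pred, sum(w * s$value), tolerance = 1e-9)
  expect_equal(sum(kp$weights[[1]]), 1, tolerance = 1e-9)
})

test_that("duplicate sample locations are averaged before kriging", {
  vg <- list(nugget = 0, sill = 1, range_m = 1000)
  s <- data.frame(x = c(0, 0, 800), y = c(0, 0, 0), value = c(2, 4, 6))
  expect_message(kp <- krige_points(s, cbind(0, 0), vg), "duplicate")
  expect_equal(kp$pred, 3, tolerance = 1e-9)
})

test_that("kriging validates its variogram", {
  s <- data.frame(x = c(0, 1), y = c(0, 1), value = c(1, 2))
  expect_error(krige_points(s, cbind(0, 0),
                            list(nugget = 0, sill = 1, range_m = 0)),
               "range")
  expect_error(krige_points(s, cbind(0, 0),
                            list(nugget = 2, sill = 1, range_m = 10)),
               "sill")
})

test_that("kriged layers carry unit-sum weights on every marine cell", {
  area <- generate_study_area(study_area_config())
  lay <- krige_layer(area$sst_samples, area$grid,
                     variogram = list(nugget = 0.05, sill = 0.6,
                                      range_m = 10000))
  sums <- vapply(attr(lay, "weights"), sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_true(all(is.finite(unclass(lay)[area$grid$marine])))
})

test_that("majority habitat sampling follows area and the documented tie rule", {
  g <- grid_spec(c(0, 0), 500, 1, 2)
  polys <- list(
    list(ring = rbind(c(0, 0), c(300, 0), c(300, 500), c(0, 500)),
         class = "sand"),
    list(ring = rbind(c(300, 0), c(1000, 0), c(1000, 500), c(300, 500)),
         class = "coral"))
  lay <- sample_categorical(polys, g)
  expect_equal(unclass(lay)[1], "sand")   # 60/40 split
  expect_equal(unclass(lay)[2], "coral")  # fully inside
})

test_that("uncovered cells are unclassified with a warning", {
  g <- grid_spec(c(0, 0), 500, 1, 2)
  polys <- list(list(ring = rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500)),
                     class = "sand"))
  expect_warning(lay <- sample_categorical(polys, g), "unclassified")
  expect_equal(unclass(lay)[2], "unclassified")
  expect_equal(attr(lay, "excluded_cells"), 2L)
})

test_that("habitat majorities agree with a 10 m rasterization oracle", {
  set.seed(31)
  g <- grid_spec(c(0, 0), 500, 6, 6)
  # mosaic breaks on the 100 m lattice: clear majorities in every cell
  xb <- c(0, sort(sample(seq(100, 2900, by = 100), 3)), 3000)
  yb <- c(0, sort(sample(seq(100, 2900, by = 100), 3)), 3000)
  classes <- c("sand", "coral", "reef", "algae")
  polys <- list()
  for (i in 1:4) for (j in 1:4)
    polys[[length(polys) + 1]] <- list(
      ring = rbind(c(xb[i], yb[j]), c(xb[i + 1], yb[j]),
                   c(xb[i + 1], yb[j + 1]), c(xb[i], yb[j + 1])),
      class = sample(classes, 1))
  lay <- sample_categorical(polys, g)
  # oracle: 10 m point grid, first containing polygon, majority count
  agree <- vapply(1:36, function(ci) {
    ll <- cell_centers(g, ci) - 250
    sub <- (seq_len(50) - 0.5) * 10
    pts <- cbind(rep(ll[1] + sub, each = 50), rep(ll[2] + sub, times = 50))
    cls <- rep(NA_character_, nrow(pts))
    for (p in polys) {
      hit <- is.na(cls) & pts[, 1] >= min(p$ring[, 1]) &
        pts[, 1] < max(p$ring[, 1]) & pts[, 2] >= min(p$ring[, 2]) &
        pts[, 2] < max(p$ring[, 2])
      cls[hit] <- p$class
    }
    tab <- table(cls)
    unclass(lay)[ci] == sort(names(tab)[tab == max(tab)])[1]
  }, logical(1))
  expect_gte(mean(agree), 0.99)
})

test_that("the feature table has one row per responding cell, stable columns", {
  g <- grid_spec(c(0, 0), 500, 4, 10)
  set.seed(41)
  eff <- runif(40, 100, 1000)
  rg <- select_absences(eff, sort(sample(40, 10)), g)
  layers <- lapply(1:8, function(i)
    predictor_layer(paste0("v", i), rnorm(40), "continuous"))
  names(layers) <- paste0("v", 1:8)
  ft <- assemble_feature_table(g, layers, rg, eff)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft), c(20, 11))
  expect_equal(names(ft)[1:3], c("cell_id", "response", "effort_m"))
  ft7 <- assemble_feature_table(g, layers[1:7], rg, eff)
  expect_equal(ncol(ft7), 10)
  expect_equal(sum(ft$response), 10)
})

test_that("cells excluded by a layer are dropped with a warning; other NAs error", {
  g <- grid_spec(c(0, 0), 500, 2, 5)
  eff <- rep(100, 10)
  rg <- select_absences(eff, c(1L, 2L), g)
  v <- rnorm(10)
  lay_ok <- predictor_layer("a", v, "continuous")
  v_bad <- v; v_bad[rg$absence[1]] <- NA
  lay_excl <- predictor_layer("b", v_bad, "continuous",
                              excluded_cells = rg$absence[1])
  expect_warning(ft <- assemble_feature_table(g, list(a = lay_ok,
                                                      b = lay_excl), rg, eff),
                 "dropping")
  expect_equal(nrow(ft), 3)
  lay_na <- predictor_layer("c", v_bad, "continuous")
  expect_error(assemble_feature_table(g, list(a = lay_ok, c = lay_na), rg,
                                      eff),
               "missing predictor")
})

test_that("feature tables survive a CSV round trip", {
  sv <- build_survey(1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(sv$features, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sv$features),
               tolerance = 1e-12)
  expect_equal(levels(back$habitat), levels(sv$features$habitat))
})
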