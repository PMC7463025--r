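#' Simple planar geometries for layer targets
#'
#' Lightweight geometry wrappers used as distance targets: a point set, a set
#' of polylines, or a polygon (one or more rings, even-odd rule). Coordinates
#' are projected metres.
#' @param xy two-column coordinate matrix.
#' @return an `sdm_geom` object.
#' @export
geom_points <- function(xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (nrow(xy) == 0) stop("empty geometry")
  structure(list(type = "points", coords = list(xy)), class = "sdm_geom")
}

#' @rdname geom_points
#' @param lines list of two-column vertex matrices.
#' @export
geom_lines <- function(lines) {
  if (is.matrix(lines)) lines <- list(lines)
  lines <- lapply(lines, function(m) matrix(as.numeric(m), ncol = 2))
  if (length(lines) == 0 || all(vapply(lines, nrow, 1L) < 2))
    stop("empty geometry")
  structure(list(type = "lines", coords = lines), class = "sdm_geom")
}

#' @rdname geom_points
#' @param rings list of ring vertex matrices (closure optional).
#' @export
geom_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(m) matrix(as.numeric(m), ncol = 2))
  if (length(rings) == 0) stop("empty geometry")
  structure(list(type = "polygon", coords = rings), class = "sdm_geom")
}

#' Construct a predictor layer
#'
#' A per-cell variable on the analysis lattice: continuous (finite on marine
#' cells) or categorical (labels from a declared class set). Values are `NA`
#' off the marine mask.
#' @param name layer name.
#' @param values per-cell vector (row-major).
#' @param kind `"continuous"` or `"categorical"`.
#' @param units unit string for documentation.
#' @param excluded_cells cells flagged unusable (e.g. unreachable or
#'   unclassified); downstream table assembly drops them with a warning.
#' @return a `predictor_layer` (the values vector with metadata attributes).
#' @export
predictor_layer <- function(name, values, kind = c("continuous", "categorical"),
                            units = NULL, excluded_cells = integer(0)) {
  kind <- match.arg(kind)
  structure(values, layer_name = name, kind = kind, units = units,
            excluded_cells = as.integer(excluded_cells),
            class = "predictor_layer")
}

#' @export
print.predictor_layer <- function(x, ...) {
  cat(sprintf("predictor_layer '%s' (%s%s): %d cells defined\n",
              attr(x, "layer_name"), attr(x, "kind"),
              if (!is.null(attr(x, "units"))) paste0(", ", attr(x, "units")) else "",
              sum(!is.na(unclass(x)))))
  invisible(x)
}

# cells traversed by the segments of a geometry (length > 0 inside the cell)
.cells_touched <- function(grid, geom) {
  lines <- switch(geom$type,
                  points = return(unique(stats::na.omit(
                    cell_of_point(grid, geom$coords[[1]])))),
                  lines = geom$coords,
                  polygon = lapply(geom$coords, function(r) {
                    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
                    r
                  }))
  eff <- effort_per_cell(tracklines(lines), grid)
  which(as.numeric(eff) > 0)
}

#' Euclidean distance layer
#'
#' Shortest straight-line planar distance from each marine cell centroid to
#' the target geometry; cells intersected by the target get distance zero.
#'
#' @param grid a [grid_spec()].
#' @param target an `sdm_geom` (points, lines or polygon).
#' @return a continuous [predictor_layer()] in metres.
#' @export
euclidean_distance_layer <- function(grid, target) {
  stopifnot(inherits(grid, "grid_spec"), inherits(target, "sdm_geom"))
  vals <- rep(NA_real_, n_cells(grid))
  m_idx <- which(grid$marine)
  ctr <- cell_centers(grid, m_idx)
  d <- switch(target$type,
    points = dist_to_points(ctr, target$coords[[1]]),
    lines = {
      best <- rep(Inf, nrow(ctr))
      for (ln in target$coords) best <- pmin(best, dist_to_polyline(ctr, ln))
      best
    },
    polygon = {
      best <- rep(Inf, nrow(ctr))
      inside <- rep(FALSE, nrow(ctr))
      for (r in target$coords) {
        rc <- if (all(r[1, ] == r[nrow(r), ])) r else rbind(r, r[1, ])
        best <- pmin(best, dist_to_polyline(ctr, rc))
        inside <- xor(inside, point_in_polygon(ctr, r))
      }
      best[inside] <- 0
      best
    })
  vals[m_idx] <- d
  touched <- intersect(.cells_touched(grid, target), m_idx)
  vals[touched] <- 0
  predictor_layer("euclidean_distance", vals, "continuous", "m")
}

# multi-source Dijkstra over the marine 8-connected lattice
.lattice_dijkstra <- function(grid, sources) {
  cs <- grid$cell_size_m
  n <- n_cells(grid)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  done <- !grid$marine  # land never enters the queue
  nr <- grid$n_rows; nc <- grid$n_cols
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  step <- ifelse(off_r != 0 & off_c != 0, cs * sqrt(2), cs)
  active <- which(grid$marine)
  repeat {
    open <- active[!done[active] & is.finite(dist[active])]
    if (length(open) == 0) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    ru <- (u - 1L) %/% nc + 1L; cu <- (u - 1L) %% nc + 1L
    for (k in 1:8) {
      r2 <- ru + off_r[k]; c2 <- cu + off_c[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- (r2 - 1L) * nc + c2
      if (done[v] || !grid$marine[v]) next
      nd <- dist[u] + step[k]
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  dist
}

#' Cost (least-cost path) distance layer
#'
#' Shortest-path distance over marine cells only, on the 8-connected lattice
#' with orthogonal steps of one cell size and diagonal steps of cell size
#' times sqrt(2). This is the land-aware analogue of Euclidean distance: where
#' the straight line crosses no land the two agree up to the octile-metric
#' discretization error (at most ~8.3% plus one cell); around a peninsula the
#' cost distance is strictly larger.
#'
#' @param grid a [grid_spec()].
#' @param target an `sdm_geom`, or an integer vector of target cell indices,
#'   or a logical per-cell mask.
#' @return a continuous [predictor_layer()] in metres; marine cells with no
#'   marine path to the target are `NA`, flagged in `excluded_cells`, and
#'   reported with a warning.
#' @export
cost_distance_layer <- function(grid, target) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- if (inherits(target, "sdm_geom")) .cells_touched(grid, target)
           else if (is.logical(target)) which(target)
           else as.integer(target)
  cells <- cells[grid$marine[cells]]
  if (length(cells) == 0) stop("no marine target cells for cost distance")
  d <- .lattice_dijkstra(grid, cells)
  vals <- rep(NA_real_, n_cells(grid))
  m_idx <- which(grid$marine)
  vals[m_idx] <- d[m_idx]
  unreachable <- m_idx[!is.finite(vals[m_idx])]
  if (length(unreachable)) {
    warning(sprintf("cost_distance_layer: %d marine cell(s) unreachable from target",
                    length(unreachable)))
    vals[unreachable] <- NA_real_
  }
  predictor_layer("cost_distance", vals, "continuous", "m",
                  excluded_cells = unreachable)
}

#' Slope and seabed-complexity layers
#'
#' Terrain derivatives of the bathymetry over the 3x3 cell neighbourhood:
#' slope is the maximum gradient magnitude to any marine neighbour, in
#' degrees (`atan(|dz|/step)`); seabed complexity is the standard deviation of
#' depth over the cell and its marine neighbours, in metres. Edge cells use
#' the neighbours available; a cell with no marine neighbour gets slope 0 and
#' complexity 0 (logged).
#'
#' @param depth per-cell depth vector (m, `NA` on land), e.g.
#'   `study_area$depth`.
#' @param grid a [grid_spec()].
#' @return list with elements `slope` (degrees) and `complexity` (m), both
#'   [predictor_layer()]s.
#' @export
slope_complexity_layers <- function(depth, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  nr <- grid$n_rows; nc <- grid$n_cols; cs <- grid$cell_size_m
  z <- matrix(NA_real_, nr, nc)
  z[cbind(cell_rowcol(grid, seq_len(n_cells(grid))))] <- as.numeric(depth)
  shift <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr); cs_ <- seq_len(nc)
    rs2 <- rs - dr; cs2 <- cs_ - dc
    ok_r <- rs2 >= 1 & rs2 <= nr; ok_c <- cs2 >= 1 & cs2 <= nc
    out[rs[ok_r], cs_[ok_c]] <- m[rs2[ok_r], cs2[ok_c]]
    out
  }
  max_grad <- matrix(0, nr, nc)
  ssum <- z; ssum[is.na(ssum)] <- 0
  ssq <- z^2; ssq[is.na(ssq)] <- 0
  cnt <- matrix(as.numeric(!is.na(z)), nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    zn <- shift(z, dr, dc)
    stp <- cs * if (dr != 0 && dc != 0) sqrt(2) else 1
    g <- abs(z - zn) / stp
    max_grad <- pmax(max_grad, ifelse(is.na(g), 0, g))
    ssum <- ssum + ifelse(is.na(zn), 0, zn)
    ssq <- ssq + ifelse(is.na(zn), 0, zn^2)
    cnt <- cnt + !is.na(zn)
  }
  sdev <- matrix(0, nr, nc)
  ok <- cnt >= 2 & !is.na(z)
  sdev[ok] <- sqrt(pmax(0, (ssq[ok] - ssum[ok]^2 / cnt[ok]) / (cnt[ok] - 1)))
  idx <- cell_rowcol(grid, seq_len(n_cells(grid)))
  slope_v <- atan(max_grad[idx]) * 180 / pi
  cplx_v <- sdev[idx]
  isolated <- grid$marine & (cnt[idx] == 1)
  if (any(isolated))
    message(sprintf("slope_complexity_layers: %d isolated marine cell(s) set to 0",
                    sum(isolated)))
  slope_v[!grid$marine] <- NA_real_
  cplx_v[!grid$marine] <- NA_real_
  list(slope = predictor_layer("slope", slope_v, "continuous", "degrees"),
       complexity = predictor_layer("complexity", cplx_v, "continuous", "m"))
}

# spherical semivariogram
.sph_gamma <- function(h, nugget, sill, range_m) {
  g <- ifelse(h <= 0, 0,
              ifelse(h >= range_m, sill,
                     nugget + (sill - nugget) *
                       (1.5 * h / range_m - 0.5 * (h / range_m)^3)))
  g
}

#' Ordinary kriging at arbitrary points
#'
#' Solves the ordinary-kriging system (spherical semivariogram, unbiasedness
#' constraint) per prediction point using the nearest `max_neighbors` samples.
#' Duplicate sample locations are averaged first (logged). Kriging weights sum
#' to one by construction; with zero nugget the predictor interpolates the
#' samples exactly and a constant field is reproduced exactly.
#'
#' @param samples data frame with columns `x`, `y`, `value`.
#' @param newpts two-column matrix of prediction locations.
#' @param variogram list with `nugget`, `sill`, `range_m`
#'   (`sill >= nugget >= 0`, `range_m > 0`).
#' @param max_neighbors number of nearest samples used per prediction.
#' @return list with `pred` (numeric) and `weights` (list of named weight
#'   vectors, one per prediction point).
#' @export
krige_points <- function(samples, newpts, variogram, max_neighbors = 12) {
  stopifnot(nrow(samples) >= 2)
  v <- variogram
  if (is.null(v$nugget)) v$nugget <- 0
  if (v$range_m <= 0) stop("variogram range must be positive")
  if (!(v$sill >= v$nugget && v$nugget >= 0))
    stop("variogram must satisfy sill >= nugget >= 0")
  key <- paste(samples$x, samples$y)
  if (anyDuplicated(key)) {
    message("krige_points: duplicate sample locations averaged")
    agg <- stats::aggregate(value ~ x + y, data = samples, FUN = mean)
    samples <- agg
  }
  newpts <- matrix(as.numeric(newpts), ncol = 2)
  sx <- samples$x; sy <- samples$y; sz <- samples$value
  n_new <- nrow(newpts)
  pred <- numeric(n_new)
  wts <- vector("list", n_new)
  for (i in seq_len(n_new)) {
    d <- sqrt((sx - newpts[i, 1])^2 + (sy - newpts[i, 2])^2)
    nb <- order(d)[seq_len(min(max_neighbors, length(d)))]
    k <- length(nb)
    hmat <- as.matrix(stats::dist(cbind(sx[nb], sy[nb])))
    G <- .sph_gamma(hmat, v$nugget, v$sill, v$range_m)
    A <- rbind(cbind(G, 1), c(rep(1, k), 0))
    b <- c(.sph_gamma(d[nb], v$nugget, v$sill, v$range_m), 1)
    sol <- tryCatch(solve(A, b), error = function(e)
      solve(A + diag(1e-10, k + 1), b))
    w <- sol[seq_len(k)]
    pred[i] <- sum(w * sz[nb])
    wts[[i]] <- stats::setNames(w, nb)
  }
  list(pred = pred, weights = wts)
}

#' Ordinary-kriging interpolation layer
#'
#' Interpolates point measurements (e.g. sea surface temperature at fixed
#' stations) onto the marine cells of the lattice via [krige_points()].
#'
#' @param samples data frame with `x`, `y`, `value`.
#' @param grid a [grid_spec()].
#' @param variogram spherical-variogram parameters, see [krige_points()].
#' @param max_neighbors nearest samples used per cell.
#' @param name layer name.
#' @return a continuous [predictor_layer()].
#' @export
krige_layer <- function(samples, grid, variogram, max_neighbors = 12,
                        name = "kriged") {
  stopifnot(inherits(grid, "grid_spec"))
  m_idx <- which(grid$marine)
  kp <- krige_points(samples, cell_centers(grid, m_idx), variogram,
                     max_neighbors)
  vals <- rep(NA_real_, n_cells(grid))
  vals[m_idx] <- kp$pred
  out <- predictor_layer(name, vals, "continuous")
  attr(out, "weights") <- kp$weights
  out
}

#' Majority benthic-habitat class per cell
#'
#' Samples each marine cell on a regular sub-lattice (`subcells_per_side^2`
#' points) and assigns the habitat class covering the majority of the cell.
#' Polygons are tested in list order (first containing polygon wins, so a
#' mosaic needs no tie rule between polygons); class ties within a cell break
#' lexicographically. Cells covered by no polygon are labelled
#' `"unclassified"`, flagged excluded, and reported with a warning.
#'
#' @param polygons list of `list(ring = <matrix>, class = <chr>)`.
#' @param grid a [grid_spec()].
#' @param subcells_per_side sub-sampling density per cell edge (default 10,
#'   i.e. 50 m for a 500 m cell).
#' @return a categorical [predictor_layer()].
#' @export
sample_categorical <- function(polygons, grid, subcells_per_side = 10) {
  stopifnot(inherits(grid, "grid_spec"), length(polygons) > 0)
  classes <- vapply(polygons, function(p) p$class, character(1))
  m_idx <- which(grid$marine)
  cs <- grid$cell_size_m
  sub <- (seq_len(subcells_per_side) - 0.5) / subcells_per_side * cs
  ll <- cell_centers(grid, m_idx) - cs / 2
  pts_x <- rep(ll[, 1], each = subcells_per_side^2) +
    rep(rep(sub, times = subcells_per_side), length(m_idx))
  pts_y <- rep(ll[, 2], each = subcells_per_side^2) +
    rep(rep(sub, each = subcells_per_side), length(m_idx))
  pts <- cbind(pts_x, pts_y)
  assigned <- rep(NA_character_, nrow(pts))
  todo <- rep(TRUE, nrow(pts))
  for (i in seq_along(polygons)) {
    if (!any(todo)) break
    hit <- point_in_polygon(pts[todo, , drop = FALSE], polygons[[i]]$ring)
    idx <- which(todo)[hit]
    assigned[idx] <- classes[i]
    todo[idx] <- FALSE
  }
  cell_rep <- rep(m_idx, each = subcells_per_side^2)
  vals <- rep(NA_character_, n_cells(grid))
  excluded <- integer(0)
  for (ci in m_idx) {
    a <- assigned[cell_rep == ci]
    a <- a[!is.na(a)]
    if (length(a) == 0) { vals[ci] <- "unclassified"; excluded <- c(excluded, ci); next }
    tab <- table(a)
    vals[ci] <- sort(names(tab)[tab == max(tab)])[1]
  }
  if (length(excluded))
    warning(sprintf("sample_categorical: %d cell(s) covered by no polygon marked unclassified",
                    length(excluded)))
  predictor_layer("habitat", vals, "categorical", excluded_cells = excluded)
}

#' Assemble the model design table
#'
#' One row per responding cell (presence or absence), with its predictor
#' values, survey effort, and 0/1 response. Cells flagged excluded by any
#' layer (unreachable for cost distance, unclassified habitat) are dropped
#' with a warning; any other missing predictor value is an error naming the
#' cells and layers.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of [predictor_layer()]s (the names become the
#'   column names).
#' @param response a [select_absences()] result.
#' @param effort an [effort_per_cell()] map.
#' @return a `feature_table` data frame with columns `cell_id`, `response`,
#'   `effort_m`, then one column per layer. Categorical layers become factors
#'   whose level set is taken from the whole marine grid, so prediction over
#'   unseen cells keeps a consistent coding.
#' @export
assemble_feature_table <- function(grid, layers, response, effort) {
  stopifnot(inherits(grid, "grid_spec"), inherits(response, "response_grid"))
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a named list")
  cells <- sort(c(response$presence, response$absence))
  excluded <- sort(unique(unlist(lapply(layers, attr, "excluded_cells"))))
  drop <- intersect(cells, excluded)
  if (length(drop)) {
    warning(sprintf("assemble_feature_table: dropping %d responding cell(s) excluded by layers: %s",
                    length(drop), paste(utils::head(drop, 10), collapse = ", ")))
    cells <- setdiff(cells, drop)
  }
  out <- data.frame(cell_id = cells,
                    response = response$response[cells],
                    effort_m = as.numeric(effort)[cells])
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    vals <- unclass(lay)[cells]
    if (attr(lay, "kind") == "categorical") {
      lv <- sort(unique(stats::na.omit(unclass(lay)[grid$marine])))
      vals <- factor(vals, levels = lv)
    }
    out[[nm]] <- vals
  }
  bad <- which(!stats::complete.cases(out))
  if (length(bad)) {
    bad_layers <- names(layers)[vapply(names(layers), function(nm)
      anyNA(out[[nm]][bad]), logical(1))]
    stop(sprintf("missing predictor values for cell(s) %s in layer(s) %s",
                 paste(utils::head(out$cell_id[bad], 10), collapse = ", "),
                 paste(bad_layers, collapse = ", ")))
  }
  attr(out, "predictors") <- names(layers)
  attr(out, "categorical") <- names(layers)[vapply(layers, function(l)
    attr(l, "kind") == "categorical", logical(1))]
  class(out) <- c("feature_table", "data.frame")
  out
}
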