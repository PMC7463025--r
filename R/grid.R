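#' Define the analysis lattice
#'
#' A `grid_spec` describes the regular square lattice on which every layer of
#' the analysis lives. Cells are indexed row-major with the origin at the
#' lower-left corner: cell 1 is the bottom-left cell, indices increase along a
#' row (west to east) and then by row (south to north). Each cell is the
#' half-open square `[x, x + cell_size) x [y, y + cell_size)`, so a point on a
#' shared edge belongs to exactly one cell.
#'
#' @param origin numeric length-2, (x, y) of the lower-left corner in metres.
#' @param cell_size_m cell edge length in metres (default 500, the resolution
#'   at which all ecogeographic variables are sampled).
#' @param n_rows,n_cols lattice dimensions.
#' @param marine logical vector, one per cell (row-major); `TRUE` for water.
#'   Defaults to all marine.
#' @param zone optional character vector per cell with management-zone type
#'   (`"SZ"` sanctuary / `"RZ"` recreation / `"GUZ"` general use), `NA` on land.
#' @param zone_name optional character vector per cell naming the individual
#'   zone block (e.g. `"SZ 2"`).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size_m = 500, n_rows, n_cols,
                      marine = NULL, zone = NULL, zone_name = NULL) {
  stopifnot(length(origin) == 2, is.finite(origin))
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0)
    stop("cell_size_m must be a single positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1 || n_cols < 1) stop("grid must have at least one cell")
  n <- n_rows * n_cols
  if (is.null(marine)) marine <- rep(TRUE, n)
  if (length(marine) != n) stop("marine mask length must equal n_rows * n_cols")
  if (!is.null(zone) && length(zone) != n) stop("zone length must equal cell count")
  structure(list(origin = as.numeric(origin), cell_size_m = as.numeric(cell_size_m),
                 n_rows = n_rows, n_cols = n_cols, marine = as.logical(marine),
                 zone = zone, zone_name = zone_name),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m (%d marine)\n",
              x$n_rows, x$n_cols, x$cell_size_m, sum(x$marine)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell index from (row, col)
#'
#' Row-major indexing with row 1 at the bottom (southern) edge.
#' @param grid a `grid_spec`.
#' @param row,col integer vectors of lattice coordinates (1-based).
#' @return integer cell indices.
#' @export
cell_index <- function(grid, row, col) {
  stopifnot(all(row >= 1 & row <= grid$n_rows), all(col >= 1 & col <= grid$n_cols))
  (as.integer(row) - 1L) * grid$n_cols + as.integer(col)
}

#' Inverse of [cell_index()]
#' @inheritParams cell_index
#' @param cell integer cell indices.
#' @return two-column integer matrix (row, col).
#' @export
cell_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  row <- (cell - 1L) %/% grid$n_cols + 1L
  col <- (cell - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}

#' Locate points on the lattice
#'
#' Applies the half-open cell convention: a point on a shared edge belongs to
#' the cell whose half-open interval contains it; points on or beyond the
#' upper/right outer boundary are outside.
#'
#' @param grid a `grid_spec`.
#' @param xy two-column matrix of point coordinates (metres).
#' @return integer vector of cell indices, `NA` for points outside the grid.
#' @export
cell_of_point <- function(grid, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  cs <- grid$cell_size_m
  col <- floor((xy[, 1] - grid$origin[1]) / cs) + 1
  row <- floor((xy[, 2] - grid$origin[2]) / cs) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, nrow(xy))
  out[ok] <- (as.integer(row[ok]) - 1L) * grid$n_cols + as.integer(col[ok])
  out
}

#' Cell centroids
#' @param grid a `grid_spec`.
#' @param cell optional cell indices (default all cells).
#' @return two-column matrix of centroid coordinates (metres).
#' @export
cell_centers <- function(grid, cell = seq_len(n_cells(grid))) {
  rc <- cell_rowcol(grid, cell)
  cs <- grid$cell_size_m
  cbind(x = grid$origin[1] + (rc[, "col"] - 0.5) * cs,
        y = grid$origin[2] + (rc[, "row"] - 0.5) * cs)
}

#' Grid as a data frame
#' @param x a `grid_spec`.
#' @param ... unused.
#' @return data frame with cell_id, row, col, x, y (centroid), marine, zone.
#' @export
as.data.frame.grid_spec <- function(x, ...) {
  idx <- seq_len(n_cells(x))
  rc <- cell_rowcol(x, idx)
  ctr <- cell_centers(x, idx)
  d <- data.frame(cell_id = idx, row = rc[, "row"], col = rc[, "col"],
                  x = ctr[, "x"], y = ctr[, "y"], marine = x$marine)
  if (!is.null(x$zone)) d$zone <- x$zone
  if (!is.null(x$zone_name)) d$zone_name <- x$zone_name
  d
}

# ---- planar geometry primitives (projected metres throughout) ----

# squared distance from points (n x 2) to one segment a-b, plus the clamped
# projection parameter t in [0, 1]
.pt_seg <- function(pts, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    t <- rep(0, nrow(pts))
  } else {
    t <- ((pts[, 1] - a[1]) * dx + (pts[, 2] - a[2]) * dy) / len2
    t <- pmin(1, pmax(0, t))
  }
  px <- a[1] + t * dx; py <- a[2] + t * dy
  list(d2 = (pts[, 1] - px)^2 + (pts[, 2] - py)^2, t = t)
}

# minimum distance from each point to a polyline (matrix of vertices)
dist_to_polyline <- function(pts, line) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(line) - 1)) {
    best <- pmin(best, .pt_seg(pts, line[i, ], line[i + 1, ])$d2)
  }
  sqrt(best)
}

# minimum distance from each point to a set of points (matrix)
dist_to_points <- function(pts, targets) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(targets))) {
    best <- pmin(best,
                 (pts[, 1] - targets[i, 1])^2 + (pts[, 2] - targets[i, 2])^2)
  }
  sqrt(best)
}

# even-odd ray-casting point-in-polygon; ring is a matrix of vertices
# (closure optional); returns logical per point
point_in_polygon <- function(pts, ring) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Liang-Barsky clip of segment a-b to rectangle [xmin,xmax] x [ymin,ymax];
# returns NULL if no overlap, else the clipped endpoints
clip_segment_rect <- function(a, b, xmin, xmax, ymin, ymax) {
  d <- b - a
  p <- c(-d[1], d[1], -d[2], d[2])
  q <- c(a[1] - xmin, xmax - a[1], a[2] - ymin, ymax - a[2])
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(NULL)
    } else {
      r <- q[k] / p[k]
      if (p[k] < 0) { if (r > t1) return(NULL); if (r > t0) t0 <- r }
      else { if (r < t0) return(NULL); if (r < t1) t1 <- r }
    }
  }
  rbind(a + t0 * d, a + t1 * d)
}
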