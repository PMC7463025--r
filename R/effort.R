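#' Buffered survey-effort corridor
#'
#' Represents the survey coverage obtained by buffering each trackline segment
#' by `buffer_m` either side with flat (butt) caps: a point is covered when
#' its perpendicular projection falls within some segment and its distance to
#' that segment is at most the buffer. The corridor is stored analytically
#' (segments + buffer); membership tests are exact and area is obtained by
#' deterministic fine-grid integration.
#'
#' @param tl a [tracklines()] object (may be empty, giving an empty corridor).
#' @param buffer_m buffer half-width in metres (> 0).
#' @return an object of class `survey_coverage`.
#' @export
buffer_tracklines <- function(tl, buffer_m = 250) {
  stopifnot(inherits(tl, "tracklines"))
  if (buffer_m <= 0) stop("buffer_m must be positive")
  segs <- do.call(rbind, c(list(matrix(numeric(0), 0, 4)),
                           lapply(tl$lines, function(m) {
    if (nrow(m) < 2) return(NULL)
    cbind(m[-nrow(m), , drop = FALSE], m[-1, , drop = FALSE])
  })))
  len <- if (nrow(segs)) sqrt((segs[, 3] - segs[, 1])^2 +
                              (segs[, 4] - segs[, 2])^2) else numeric(0)
  segs <- segs[len > 0, , drop = FALSE]
  structure(list(segments = segs, buffer_m = buffer_m,
                 total_length_m = sum(len)),
            class = "survey_coverage")
}

#' Test points for corridor membership
#' @param coverage a [buffer_tracklines()] result.
#' @param xy two-column matrix of point coordinates.
#' @return logical vector.
#' @export
coverage_contains <- function(coverage, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  segs <- coverage$segments
  inside <- rep(FALSE, nrow(xy))
  b <- coverage$buffer_m
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1:2]; e <- segs[i, 3:4]
    d <- e - a; len2 <- sum(d^2)
    t <- ((xy[, 1] - a[1]) * d[1] + (xy[, 2] - a[2]) * d[2]) / len2
    # flat caps: projection must land on the segment itself
    perp2 <- (xy[, 1] - a[1] - t * d[1])^2 + (xy[, 2] - a[2] - t * d[2])^2
    inside <- inside | (t >= 0 & t <= 1 & perp2 <= b^2)
  }
  inside
}

#' Corridor area by fine-grid integration
#'
#' Counts covered cell centres of a `resolution_m` lattice aligned to absolute
#' multiples of the resolution; exact for axis-aligned rectangles whose edges
#' fall on lattice lines. The union of overlapping buffers is counted once.
#'
#' @param coverage a [buffer_tracklines()] result.
#' @param resolution_m integration cell size (m).
#' @return area in square metres.
#' @export
coverage_area <- function(coverage, resolution_m = 10) {
  segs <- coverage$segments
  if (nrow(segs) == 0) return(0)
  b <- coverage$buffer_m
  xr <- range(c(segs[, 1], segs[, 3])) + c(-b, b)
  yr <- range(c(segs[, 2], segs[, 4])) + c(-b, b)
  xs <- seq(floor(xr[1] / resolution_m) * resolution_m + resolution_m / 2,
            xr[2], by = resolution_m)
  ys <- seq(floor(yr[1] / resolution_m) * resolution_m + resolution_m / 2,
            yr[2], by = resolution_m)
  count <- 0
  for (yy in ys) {  # row-by-row keeps memory flat on long corridors
    pts <- cbind(xs, yy)
    count <- count + sum(coverage_contains(coverage, pts))
  }
  count * resolution_m^2
}

#' Survey effort per grid cell
#'
#' Clips every trackline segment to the lattice and accumulates the exact
#' length of track falling in each half-open cell. Track parts outside the
#' grid are clipped off and their total length reported via the `clipped_m`
#' attribute (and a message).
#'
#' @param tl a [tracklines()] object.
#' @param grid a [grid_spec()].
#' @return an `effort_map`: numeric vector of metres per cell (row-major) with
#'   attributes `total_m` (clipped track length, equal to `sum(effort)` up to
#'   1e-6 relative) and `clipped_m` (length removed outside the grid).
#' @export
effort_per_cell <- function(tl, grid) {
  stopifnot(inherits(tl, "tracklines"), inherits(grid, "grid_spec"))
  cs <- grid$cell_size_m
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  xmax <- x0 + grid$n_cols * cs; ymax <- y0 + grid$n_rows * cs
  eff <- numeric(n_cells(grid))
  total_in <- 0; clipped <- 0
  for (m in tl$lines) {
    for (i in seq_len(nrow(m) - 1)) {
      a <- m[i, ]; e <- m[i + 1, ]
      seg_len <- sqrt(sum((e - a)^2))
      if (seg_len == 0) next
      cl <- clip_segment_rect(a, e, x0, xmax, y0, ymax)
      if (is.null(cl)) { clipped <- clipped + seg_len; next }
      a2 <- cl[1, ]; e2 <- cl[2, ]
      in_len <- sqrt(sum((e2 - a2)^2))
      clipped <- clipped + (seg_len - in_len)
      total_in <- total_in + in_len
      if (in_len == 0) next
      d <- e2 - a2
      ts <- c(0, 1)
      if (d[1] != 0) {
        ks <- seq(ceiling(min(a2[1], e2[1]) / cs), floor(max(a2[1], e2[1]) / cs))
        ts <- c(ts, (ks * cs - a2[1]) / d[1])
      }
      if (d[2] != 0) {
        ks <- seq(ceiling(min(a2[2], e2[2]) / cs), floor(max(a2[2], e2[2]) / cs))
        ts <- c(ts, (ks * cs - a2[2]) / d[2])
      }
      ts <- sort(unique(pmin(1, pmax(0, ts))))
      for (j in seq_len(length(ts) - 1)) {
        dt <- ts[j + 1] - ts[j]
        if (dt <= 0) next
        mid <- a2 + (ts[j] + ts[j + 1]) / 2 * d
        # nudge points sitting exactly on the outer boundary into the grid
        mid[1] <- min(mid[1], xmax - 1e-9); mid[2] <- min(mid[2], ymax - 1e-9)
        cell <- cell_of_point(grid, matrix(mid, 1))
        if (!is.na(cell)) eff[cell] <- eff[cell] + dt * in_len
      }
    }
  }
  if (clipped > 1e-9)
    message(sprintf("effort_per_cell: %.1f m of track clipped outside the grid",
                    clipped))
  attr(eff, "total_m") <- total_in
  attr(eff, "clipped_m") <- clipped
  class(eff) <- "effort_map"
  eff
}

#' Presence cells from sighting locations
#'
#' A cell is a presence cell iff at least one sighting falls in it (half-open
#' cell convention; multiple sightings in one cell collapse). Sightings
#' outside the grid are dropped with a warning. If `coverage` is supplied,
#' off-corridor sightings are rejected with a warning (only on-effort
#' sightings enter the response). Sightings over land cells are counted but
#' flagged, since they indicate a land-mask/position mismatch.
#'
#' @param sightings a `sighting_set` or two-column coordinate matrix.
#' @param grid a [grid_spec()].
#' @param coverage optional [buffer_tracklines()] corridor.
#' @return sorted integer vector of presence cell indices.
#' @export
assign_presence <- function(sightings, grid, coverage = NULL) {
  xy <- if (is.data.frame(sightings)) cbind(sightings$x, sightings$y)
        else matrix(as.numeric(sightings), ncol = 2)
  if (nrow(xy) == 0) return(integer(0))
  if (!is.null(coverage)) {
    on_eff <- coverage_contains(coverage, xy)
    if (any(!on_eff)) {
      warning(sprintf("%d off-corridor sighting(s) rejected", sum(!on_eff)))
      xy <- xy[on_eff, , drop = FALSE]
    }
  }
  cells <- cell_of_point(grid, xy)
  if (anyNA(cells)) {
    warning(sprintf("%d sighting(s) outside the grid dropped", sum(is.na(cells))))
    cells <- cells[!is.na(cells)]
  }
  cells <- sort(unique(cells))
  on_land <- !grid$marine[cells]
  if (any(on_land))
    warning(sprintf("%d presence cell(s) fall on land; counted but flagged",
                    sum(on_land)))
  cells
}

#' Effort-ranked true-absence selection
#'
#' Candidate absence cells are surveyed marine cells (effort > 0) with no
#' sightings. Exactly as many absences as presences are selected, in
#' decreasing order of survey effort -- the cells most intensively searched
#' without an encounter are the most defensible true absences. Ties at the
#' selection threshold are broken by increasing cell index (deterministic,
#' logged).
#'
#' @param effort an [effort_per_cell()] map.
#' @param presence_cells integer vector from [assign_presence()].
#' @param grid a [grid_spec()].
#' @return a `response_grid`: list with `presence`, `absence` (cell indices),
#'   `absence_threshold_m` (effort of the weakest selected absence; `NA` when
#'   no presences) and `response` (per-cell 1/0/`NA`).
#' @export
select_absences <- function(effort, presence_cells, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  eff <- as.numeric(effort)
  n_p <- length(presence_cells)
  cand <- which(grid$marine & eff > 0)
  cand <- setdiff(cand, presence_cells)
  response <- rep(NA_real_, n_cells(grid))
  response[presence_cells] <- 1
  if (n_p == 0) {
    out <- list(presence = integer(0), absence = integer(0),
                absence_threshold_m = NA_real_, response = response)
    class(out) <- "response_grid"
    return(out)
  }
  if (length(cand) < n_p)
    stop(sprintf(
      "insufficient absence candidates: need %d, have %d (deficit %d)",
      n_p, length(cand), n_p - length(cand)))
  ord <- cand[order(-eff[cand], cand)]
  absence <- ord[seq_len(n_p)]
  threshold <- eff[absence[n_p]]
  n_at <- sum(abs(eff[cand] - threshold) < 1e-12)
  n_sel_at <- sum(abs(eff[absence] - threshold) < 1e-12)
  if (n_at > n_sel_at)
    message(sprintf(
      "select_absences: %d candidate(s) tied at threshold %.1f m; first %d by cell index kept",
      n_at, threshold, n_sel_at))
  response[absence] <- 0
  out <- list(presence = sort(as.integer(presence_cells)),
              absence = sort(as.integer(absence)),
              absence_threshold_m = threshold, response = response)
  class(out) <- "response_grid"
  out
}

#' @export
print.response_grid <- function(x, ...) {
  cat(sprintf("response_grid: %d presence, %d absence cells (threshold %.0f m)\n",
              length(x$presence), length(x$absence), x$absence_threshold_m))
  invisible(x)
}
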