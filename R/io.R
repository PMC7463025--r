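#' Write a per-cell layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS software.
#' Rows are written north to south; `NA` becomes the NODATA value.
#'
#' @param values per-cell vector (row-major, row 1 south) or a
#'   [predictor_layer()].
#' @param grid a [grid_spec()].
#' @param path output file.
#' @param nodata NODATA sentinel.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  v <- as.numeric(unclass(values))
  stopifnot(length(v) == n_cells(grid))
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g", grid$origin[2]),
               sprintf("cellsize %.10g", grid$cell_size_m),
               sprintf("NODATA_value %g", nodata)), con)
  for (r in grid$n_rows:1) {
    idx <- ((r - 1) * grid$n_cols + 1):(r * grid$n_cols)
    writeLines(paste(format(v[idx], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path input file.
#' @return list with `grid` (a [grid_spec()] with all-marine mask) and
#'   `values` (row-major, row 1 south; NODATA as `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- suppressWarnings(as.numeric(kv[2]))
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop(sprintf("malformed ASCII grid header at line %d of %s", i, path))
  vals <- suppressWarnings(unlist(lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))))
  if (length(vals) != hdr$ncols * hdr$nrows || anyNA(vals))
    stop("malformed ASCII grid body: does not match declared dimensions")
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  # file rows run north to south; flip into row-major south-first order
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[hdr$nrows:1, , drop = FALSE]
  list(grid = grid_spec(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize,
                        hdr$nrows, hdr$ncols),
       values = as.numeric(t(m)))
}

# build one GeoJSON feature
.gj_feature <- function(type, coords, properties) {
  list(type = "Feature",
       geometry = list(type = type, coordinates = coords),
       properties = if (length(properties)) properties else
         stats::setNames(list(), character(0)))
}

#' Write simple geometries to GeoJSON
#'
#' Writes points, polylines or polygons with arbitrary properties. Unknown
#' extra properties survive a read/write round trip untouched.
#'
#' @param features list of `list(geometry = <matrix or list of matrices>,
#'   type = "Point"|"LineString"|"Polygon", properties = <named list>)`.
#' @param path output file.
#' @param crs optional CRS string carried through as a foreign member.
#' @export
write_geojson <- function(features, path, crs = NULL) {
  fl <- lapply(features, function(f) {
    coords <- switch(f$type,
      Point = as.numeric(f$geometry),
      LineString = lapply(seq_len(nrow(f$geometry)), function(i)
        as.numeric(f$geometry[i, ])),
      Polygon = {
        rings <- if (is.matrix(f$geometry)) list(f$geometry) else f$geometry
        lapply(rings, function(r) {
          if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
          lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
        })
      },
      stop(sprintf("unsupported geometry type '%s'", f$type)))
    .gj_feature(f$type, coords, f$properties)
  })
  obj <- list(type = "FeatureCollection", features = fl)
  if (!is.null(crs)) obj$crs <- crs
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GeoJSON file written by [write_geojson()]
#' @param path input file.
#' @return list of features in the same shape accepted by [write_geojson()],
#'   with attribute `crs` if present.
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop(sprintf("malformed GeoJSON in %s: not a FeatureCollection", path))
  feats <- lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    if (is.null(f$geometry))
      stop(sprintf("malformed GeoJSON feature %d in %s", i, path))
    g <- f$geometry
    geometry <- switch(g$type,
      Point = matrix(unlist(g$coordinates), 1, 2),
      LineString = do.call(rbind, lapply(g$coordinates, unlist)),
      Polygon = lapply(g$coordinates, function(r)
        do.call(rbind, lapply(r, unlist))),
      stop(sprintf("unsupported geometry type '%s' in feature %d", g$type, i)))
    list(geometry = geometry, type = g$type, properties = f$properties)
  })
  if (!is.null(obj$crs)) attr(feats, "crs") <- obj$crs
  feats
}

#' Write / read a feature table as CSV
#'
#' Round-trip stable: `read_feature_table(write_feature_table(x))` equals `x`
#' up to floating-point printing (full precision is written).
#' @param x a `feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(predictors = attr(x, "predictors"),
               categorical = attr(x, "categorical"),
               levels = lapply(x[attr(x, "categorical")], levels))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    for (nm in meta$categorical)
      d[[nm]] <- factor(d[[nm]], levels = meta$levels[[nm]])
    attr(d, "predictors") <- meta$predictors
    attr(d, "categorical") <- meta$categorical
  }
  class(d) <- c("feature_table", "data.frame")
  d
}
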