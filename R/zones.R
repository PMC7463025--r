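#' Occurrence probability bands
#'
#' Band boundaries for classifying the ensemble surface. The partition is
#' total via half-open intervals: Low = `[0, low_max]`, Medium =
#' `(low_max, high_min]`, High = `(high_min, 1]` -- so 0.30 is Low and 0.60
#' is Medium, and "High" means strictly above `high_min`.
#'
#' @param low_max upper bound of the Low band (default 0.3).
#' @param high_min lower bound (exclusive) of the High band (default 0.6).
#' @return an `occurrence_bands` list.
#' @export
occurrence_bands <- function(low_max = 0.3, high_min = 0.6) {
  if (!(0 < low_max && low_max < high_min && high_min < 1))
    stop("need 0 < low_max < high_min < 1")
  structure(list(low_max = low_max, high_min = high_min,
                 labels = c("Low", "Medium", "High")),
            class = "occurrence_bands")
}

#' Classify occurrence probabilities into bands
#'
#' @param probability numeric probabilities in `[0, 1]` (per cell), or an
#'   `ensemble_surface`.
#' @param bands an [occurrence_bands()].
#' @return factor with levels Low/Medium/High (`NA` stays `NA`).
#' @export
classify_occurrence <- function(probability, bands = occurrence_bands()) {
  if (inherits(probability, "ensemble_surface"))
    probability <- probability$probability
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  cut(probability, breaks = c(-Inf, bands$low_max, bands$high_min, Inf),
      labels = bands$labels, right = TRUE)
}

#' Summarize occurrence probability by management zone
#'
#' Area, cell count, mean (SD), median and range of occurrence probability
#' for each named zone block, each zone type, all sanctuary zones combined,
#' and everything outside sanctuary zones (recreation + general use).
#'
#' @param probability per-marine-cell probabilities (full-grid vector, `NA`
#'   off-marine) or an `ensemble_surface` aligned to the marine cells of
#'   `grid`.
#' @param grid a [grid_spec()] carrying `zone` (and optionally `zone_name`)
#'   labels.
#' @return data frame with one row per zone block plus `Combined SZ` and
#'   `Outside (RZ & GUZ)` rows; columns `zone`, `zone_type`, `area_km2`,
#'   `n_cells`, `mean`, `sd`, `median`, `min`, `max`.
#' @export
zone_summary <- function(probability, grid) {
  stopifnot(inherits(grid, "grid_spec"), !is.null(grid$zone))
  m_idx <- which(grid$marine)
  p <- if (inherits(probability, "ensemble_surface")) {
    stopifnot(length(probability$probability) == length(m_idx))
    probability$probability
  } else as.numeric(probability)[m_idx]
  if (anyNA(grid$zone[m_idx])) stop("every marine cell must carry a zone label")
  cell_km2 <- (grid$cell_size_m / 1000)^2
  zn <- if (!is.null(grid$zone_name)) grid$zone_name[m_idx] else grid$zone[m_idx]
  zt <- grid$zone[m_idx]
  stat_row <- function(name, type, v) {
    if (length(v) == 0) {
      message(sprintf("zone_summary: zone '%s' has no cells", name))
      return(data.frame(zone = name, zone_type = type, area_km2 = 0,
                        n_cells = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, min = NA_real_, max = NA_real_))
    }
    data.frame(zone = name, zone_type = type,
               area_km2 = length(v) * cell_km2, n_cells = length(v),
               mean = mean(v), sd = stats::sd(v), median = stats::median(v),
               min = min(v), max = max(v))
  }
  rows <- list()
  for (nm in sort(unique(zn[zt == "SZ"])))
    rows[[length(rows) + 1]] <- stat_row(nm, "SZ", p[zn == nm])
  rows[[length(rows) + 1]] <- stat_row("Combined SZ", "SZ", p[zt == "SZ"])
  rows[[length(rows) + 1]] <- stat_row("Outside (RZ & GUZ)", "RZ+GUZ",
                                       p[zt != "SZ"])
  do.call(rbind, rows)
}

#' Sanctuary-zone overlap randomization test
#'
#' Tests whether high-occurrence cells fall within sanctuary (no-take) zones
#' more often than expected if they were randomly scattered across the marine
#' study area. The observed index is the count of high cells inside the
#' sanctuary mask; each permutation relocates the same number of high cells
#' uniformly at random (without replacement) among all marine cells and
#' recounts. The one-sided p-value is the proportion of permuted indices
#' greater than or equal to the observed one, i.e. the upper tail of a
#' hypergeometric null estimated by Monte Carlo.
#'
#' @param high logical vector over marine cells: is the cell a high-occurrence
#'   cell? (Or a band factor from [classify_occurrence()], in which case
#'   `"High"` is used.)
#' @param sanctuary logical vector over the same cells: is the cell inside a
#'   sanctuary zone?
#' @param n_permutations number of random relocations (default 5000).
#' @param seed integer RNG seed.
#' @return a `rand_test` list: `observed_index`, `null_distribution`,
#'   `p_value`, `n_permutations`, `seed`, and the problem sizes `n_cells`,
#'   `n_high`, `n_sanctuary`.
#' @export
randomization_test <- function(high, sanctuary, n_permutations = 5000,
                               seed = 1) {
  if (is.factor(high)) high <- !is.na(high) & high == "High"
  high <- as.logical(high); sanctuary <- as.logical(sanctuary)
  stopifnot(length(high) == length(sanctuary))
  N <- length(high); k <- sum(high); m <- sum(sanctuary)
  if (m == 0) stop("sanctuary mask is empty")
  observed <- sum(high & sanctuary)
  set.seed(as.integer(seed))
  if (k == 0) {
    warning("no high-occurrence cells; p-value is 1 by construction")
    null <- integer(n_permutations)
  } else {
    sz_idx <- which(sanctuary)
    null <- vapply(seq_len(n_permutations), function(i)
      sum(sample.int(N, k) %in% sz_idx), integer(1))
  }
  structure(list(observed_index = observed, null_distribution = null,
                 p_value = mean(null >= observed),
                 n_permutations = n_permutations, seed = seed,
                 n_cells = N, n_high = k, n_sanctuary = m),
            class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf(paste0("randomization test: %d of %d high cells in sanctuary ",
                     "zones\nnull: %d cells, %d sanctuary, %d permutations\n",
                     "P(null index >= observed) = %.4f\n"),
              x$observed_index, x$n_high, x$n_cells, x$n_sanctuary,
              x$n_permutations, x$p_value))
  invisible(x)
}
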