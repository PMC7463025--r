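#' Collinearity screening configuration
#'
#' Thresholds for predictor screening: pairwise Pearson correlation (default
#' 0.7) and variance inflation factor (default 3), the conventional cutoffs
#' for ecological regression modelling.
#'
#' @param r_threshold maximum tolerated absolute pairwise correlation,
#'   in (0, 1).
#' @param vif_threshold maximum tolerated VIF, > 1.
#' @return a `collinearity_config` list.
#' @export
collinearity_config <- function(r_threshold = 0.7, vif_threshold = 3) {
  if (!(r_threshold > 0 && r_threshold < 1))
    stop("r_threshold must be in (0, 1)")
  if (!(vif_threshold > 1)) stop("vif_threshold must exceed 1")
  structure(list(r_threshold = r_threshold, vif_threshold = vif_threshold),
            class = "collinearity_config")
}

# continuous predictor columns of a feature table (categorical predictors are
# excluded from correlation/VIF screening: Pearson r is undefined for
# unordered categories)
.screen_columns <- function(features) {
  pred <- attr(features, "predictors")
  if (inherits(features, "feature_table") && !is.null(pred)) {
    cat_ <- attr(features, "categorical")
    features <- features[, setdiff(pred, cat_), drop = FALSE]
  }
  features <- as.data.frame(features)
  features[vapply(features, is.numeric, logical(1))]
}

#' Pairwise Pearson correlation matrix
#'
#' @param features data frame of continuous predictors (or a `feature_table`,
#'   whose continuous predictor columns are used).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(features) {
  x <- .screen_columns(features)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (ncol(x) < 2) stop("need at least 2 continuous columns")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0))
    stop(sprintf("zero-variance column(s): %s",
                 paste(names(x)[sds == 0], collapse = ", ")))
  stats::cor(as.matrix(x))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of predictor `j` on all other predictors. Exact linear
#' dependence is reported as an infinite VIF rather than an error, so the
#' iterative exclusion procedures can handle it.
#'
#' @inheritParams pearson_matrix
#' @return named numeric vector of VIFs (all `>= 1`, possibly `Inf`).
#' @export
vif <- function(features) {
  x <- .screen_columns(features)
  if (ncol(x) < 2) return(stats::setNames(rep(1, ncol(x)), names(x)))
  if (nrow(x) <= ncol(x))
    stop("need more rows than columns to compute VIFs")
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    fit <- stats::lm(x[[j]] ~ ., data = x[-j])
    # an essentially perfect fit is reported as infinite VIF, not a warning
    r2 <- suppressWarnings(summary(fit)$r.squared)
    out[j] <- if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  stats::setNames(pmax(1, out), names(x))
}

# shared removal loop; mode "cor" = vifcor, "vif" = vifstep
.screen_loop <- function(features, config, mode) {
  x <- .screen_columns(features)
  input_order <- names(x)
  removed <- data.frame(variable = character(0), reason = character(0),
                        value = numeric(0))
  repeat {
    if (ncol(x) < 2) break
    if (mode == "cor") {
      cm <- abs(pearson_matrix(x)); diag(cm) <- 0
      mx <- max(cm)
      if (mx <= config$r_threshold) break
      pair <- which(cm == mx, arr.ind = TRUE)[1, ]
      v <- vif(x)
      cand <- colnames(cm)[pair]
      vifs <- v[cand]
      if (is.finite(diff(vifs)) && abs(diff(vifs)) < 1e-12 ||
          (is.infinite(vifs[1]) && is.infinite(vifs[2]))) {
        drop <- cand[which.max(match(cand, input_order))]
        message(sprintf("vifcor: VIF tie between %s; dropping later variable %s",
                        paste(cand, collapse = " and "), drop))
      } else {
        drop <- cand[which.max(vifs)]
      }
      removed <- rbind(removed, data.frame(variable = drop, reason = "max-r",
                                           value = mx))
    } else {
      v <- vif(x)
      mx <- max(v)
      if (mx <= config$vif_threshold) break
      worst <- names(v)[v == mx]
      drop <- worst[which.max(match(worst, input_order))]
      if (length(worst) > 1)
        message(sprintf("vifstep: VIF tie between %s; dropping later variable %s",
                        paste(worst, collapse = " and "), drop))
      removed <- rbind(removed, data.frame(variable = drop, reason = "max-VIF",
                                           value = mx))
    }
    x <- x[, setdiff(names(x), drop), drop = FALSE]
  }
  # a single remaining variable has VIF 1 by definition, so the loop always
  # retains at least one; an empty result would be a degenerate screening
  if (ncol(x) == 0) stop("degenerate screening: all variables removed")
  structure(list(retained = names(x), removed = removed, config = config,
                 method = if (mode == "cor") "vifcor" else "vifstep"),
            class = "screening_report")
}

#' Iterative correlation-driven exclusion (vifcor)
#'
#' Repeatedly finds the pair of predictors with the highest absolute Pearson
#' correlation; while it exceeds `r_threshold`, the pair member with the
#' higher VIF (computed on the current variable set) is excluded. VIF ties
#' drop the variable later in input order (logged).
#'
#' @inheritParams pearson_matrix
#' @param config a [collinearity_config()].
#' @return a `screening_report`: `retained` variable names and a `removed`
#'   data frame (variable, reason, value at removal).
#' @export
vifcor <- function(features, config = collinearity_config()) {
  .screen_loop(features, config, "cor")
}

#' Iterative maximum-VIF exclusion (vifstep)
#'
#' Repeatedly excludes the predictor with the highest VIF while that VIF
#' exceeds `vif_threshold`.
#'
#' @inheritParams vifcor
#' @return a `screening_report`.
#' @export
vifstep <- function(features, config = collinearity_config()) {
  .screen_loop(features, config, "vif")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("%s screening: %d retained, %d removed\n", x$method,
              length(x$retained), nrow(x$removed)))
  if (nrow(x$removed)) {
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  - %s (%s = %.3g)\n", x$removed$variable[i],
                  x$removed$reason[i], x$removed$value[i]))
  }
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Screen a feature table with vifcor then vifstep
#'
#' Applies the two procedures sequentially -- vifcor on the continuous
#' predictors, then vifstep on the survivors -- and returns both reports plus
#' the final retained set (with categorical predictors passed through
#' unscreened).
#'
#' @param features a `feature_table`.
#' @param config a [collinearity_config()].
#' @return list with `vifcor`, `vifstep` (the two reports), and `retained`
#'   (final predictor names, categorical predictors included).
#' @export
screen_predictors <- function(features, config = collinearity_config()) {
  stopifnot(inherits(features, "feature_table"))
  rep1 <- vifcor(features, config)
  x <- .screen_columns(features)[, , drop = FALSE]
  rep2 <- vifstep(x[rep1$retained], config)
  cat_ <- attr(features, "categorical")
  pred <- attr(features, "predictors")
  retained <- pred[pred %in% c(rep2$retained, cat_)]
  list(vifcor = rep1, vifstep = rep2, retained = retained)
}
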