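#' Area under the ROC curve
#'
#' Computed as the rank-sum (concordance) statistic: the probability that a
#' randomly chosen presence is scored above a randomly chosen absence, with
#' tied scores counted one half.
#'
#' @param scores numeric predicted probabilities (or any monotone scores).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified calibration/test split
#'
#' Splits rows at `calib_fraction` for calibration, stratified by the 0/1
#' response so both classes appear on both sides (error otherwise). The total
#' calibration size is `round(calib_fraction * n)`, allocated across classes
#' by largest remainder, so a balanced 100-row table splits 75/25 with both
#' parts balanced within one row. Deterministic given `split_seed`.
#'
#' @param response 0/1 vector.
#' @param calib_fraction fraction of rows used for calibration, in (0, 1).
#' @param split_seed integer seed.
#' @return list with integer row indices `calib` and `test`.
#' @export
split_calibration <- function(response, calib_fraction = 0.75, split_seed = 1) {
  stopifnot(calib_fraction > 0, calib_fraction < 1)
  n <- length(response)
  if (n < 8) stop("need at least 8 rows to split")
  cls <- sort(unique(response))
  if (length(cls) != 2) stop("both classes must be present")
  n_cal_total <- round(calib_fraction * n)
  n_k <- vapply(cls, function(k) sum(response == k), numeric(1))
  base <- floor(calib_fraction * n_k)
  rem <- n_cal_total - sum(base)
  if (rem > 0) {
    frac <- calib_fraction * n_k - base
    add <- order(-frac)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  if (any(base < 1) || any(base > n_k - 1))
    stop("a class would be absent from the calibration or test part")
  set.seed(as.integer(split_seed))
  calib <- unlist(lapply(seq_along(cls), function(i) {
    idx <- which(response == cls[i])
    sample(idx, base[i])
  }))
  calib <- sort(calib)
  list(calib = calib, test = setdiff(seq_len(n), calib))
}

#' Permutation variable importance
#'
#' The biomod2-style randomisation statistic: for each predictor, the Pearson
#' correlation between the model's standard predictions and predictions after
#' randomly permuting that predictor, averaged over `n_perm` permutations;
#' importance is `1 - mean(r)`, clipped to `[0, 1]`. A variable the model
#' ignores scores 0; a variable the predictions hinge on scores near 1. If
#' the standard predictions are constant the correlation is undefined and all
#' importances are 0 (logged).
#'
#' @param model an `esdm_model` (or anything with a `predict` method
#'   returning probabilities).
#' @param data data frame of rows to evaluate on (typically the calibration
#'   rows).
#' @param predictors predictor column names to assess.
#' @param n_perm number of permutations per variable.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of importances in `[0, 1]`.
#' @export
variable_importance <- function(model, data, predictors = NULL, n_perm = 10,
                                seed = 1) {
  if (is.null(predictors)) predictors <- model$predictors
  std <- stats::predict(model, data)
  out <- stats::setNames(numeric(length(predictors)), predictors)
  if (stats::sd(std) == 0) {
    message("variable_importance: constant predictions; importances set to 0")
    return(out)
  }
  set.seed(as.integer(seed))
  n <- nrow(data)
  for (v in predictors) {
    # all permutations stacked into one predict call
    perm_idx <- lapply(seq_len(n_perm), function(i) sample.int(n))
    big <- data[rep(seq_len(n), n_perm), , drop = FALSE]
    big[[v]] <- data[[v]][unlist(perm_idx)]
    pred <- stats::predict(model, big)
    rs <- vapply(seq_len(n_perm), function(i) {
      p <- pred[((i - 1) * n + 1):(i * n)]
      if (stats::sd(p) == 0) 0 else stats::cor(std, p)
    }, numeric(1))
    out[v] <- min(1, max(0, 1 - mean(rs)))
  }
  out
}

#' Repeated-split cross-validation of the base learners
#'
#' Runs every requested algorithm on `n_runs` random 75/25 (by default)
#' calibration/test splits. Each run records the held-out test AUC and the
#' permutation variable importance of the calibrated model. Failed fits are
#' dropped with a warning; more than 20% failures aborts.
#'
#' @param data a `feature_table` (or data frame with a 0/1 `response`
#'   column).
#' @param predictors predictor column names.
#' @param algorithms subset of `GAM, GBM, CTA, FDA, RF, MAXENT`.
#' @param n_runs number of calibration/test splits per algorithm.
#' @param calib_fraction calibration fraction.
#' @param seed master seed; run seeds are derived from it.
#' @param n_perm permutations for [variable_importance()].
#' @param compute_importance set `FALSE` to skip importance (faster when only
#'   AUCs are needed).
#' @param control an [esdm_control()].
#' @return list of `ModelRun`s: each has `algorithm`, `run_index`,
#'   `split_seed`, `split`, `auc_test`, `importance`, and the fitted `model`.
#' @export
run_cross_validation <- function(data, predictors,
                                 algorithms = .esdm_algorithms,
                                 n_runs = 10, calib_fraction = 0.75,
                                 seed = 1, n_perm = 10,
                                 compute_importance = TRUE,
                                 control = esdm_control()) {
  algorithms <- match.arg(algorithms, .esdm_algorithms, several.ok = TRUE)
  stopifnot(n_runs >= 1)
  set.seed(as.integer(seed))
  split_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  fit_seeds <- sample.int(.Machine$integer.max - 1, n_runs * length(algorithms))
  runs <- list()
  n_fail <- 0
  k <- 0
  for (alg in algorithms) {
    for (r in seq_len(n_runs)) {
      k <- k + 1
      sp <- split_calibration(data$response, calib_fraction, split_seeds[r])
      run <- tryCatch({
        model <- fit_single(alg, data[sp$calib, , drop = FALSE], predictors,
                            control, seed = fit_seeds[k])
        test_pred <- stats::predict(model, data[sp$test, , drop = FALSE])
        imp <- if (compute_importance)
          variable_importance(model, data[sp$calib, , drop = FALSE],
                              predictors, n_perm, seed = fit_seeds[k])
        else NULL
        list(algorithm = alg, run_index = r, split_seed = split_seeds[r],
             split = sp, auc_test = auc(test_pred, data$response[sp$test]),
             importance = imp, model = model)
      }, error = function(e) {
        warning(sprintf("%s run %d failed: %s", alg, r, conditionMessage(e)))
        NULL
      })
      if (is.null(run)) n_fail <- n_fail + 1 else runs[[length(runs) + 1]] <- run
    }
  }
  if (n_fail > 0.2 * (n_runs * length(algorithms)))
    stop(sprintf("%d of %d model runs failed", n_fail,
                 n_runs * length(algorithms)))
  runs
}

#' Variable-importance table
#'
#' Per-algorithm mean importance over cross-validation runs, plus the
#' unweighted mean of means across algorithms (the headline ranking of
#' predictors).
#'
#' @param runs output of [run_cross_validation()].
#' @return data frame with one row per algorithm plus a `mean_of_means` row;
#'   columns are predictors, entries in `[0, 1]`.
#' @export
build_importance_table <- function(runs) {
  runs <- Filter(function(r) !is.null(r$importance), runs)
  if (length(runs) == 0) stop("no runs with importance information")
  algs <- unique(vapply(runs, `[[`, character(1), "algorithm"))
  vars <- names(runs[[1]]$importance)
  tab <- matrix(NA_real_, length(algs), length(vars),
                dimnames = list(algs, vars))
  for (a in algs) {
    imp <- do.call(rbind, lapply(Filter(function(r) r$algorithm == a, runs),
                                 `[[`, "importance"))
    tab[a, ] <- colMeans(imp)
  }
  out <- rbind(tab, mean_of_means = colMeans(tab))
  as.data.frame(out)
}

#' AUC-weighted ensemble prediction
#'
#' Combines the calibrated models: runs with test AUC strictly above 0.5
#' (better than chance) contribute with weight proportional to their AUC;
#' the ensemble probability is the weighted mean of the included models'
#' probabilities, a convex combination bounded by their per-cell min and max.
#'
#' @param runs output of [run_cross_validation()].
#' @param newdata data frame of cells to predict (e.g. all marine cells).
#' @return an `ensemble_surface`: list with `probability` (per row of
#'   `newdata`), `weights` (data frame: algorithm, run, auc, weight), and
#'   `n_excluded` (runs with AUC <= 0.5).
#' @export
ensemble_predict <- function(runs, newdata) {
  aucs <- vapply(runs, `[[`, numeric(1), "auc_test")
  incl <- which(aucs > 0.5)
  if (length(incl) == 0) stop("no skillful models: every run has AUC <= 0.5")
  w <- aucs[incl] / sum(aucs[incl])
  preds <- vapply(runs[incl], function(r) stats::predict(r$model, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  p <- as.numeric(preds %*% w)
  structure(list(
    probability = p,
    weights = data.frame(
      algorithm = vapply(runs[incl], `[[`, character(1), "algorithm"),
      run = vapply(runs[incl], `[[`, numeric(1), "run_index"),
      auc = aucs[incl], weight = w),
    n_excluded = length(runs) - length(incl),
    member_predictions = preds), class = "ensemble_surface")
}

# out-of-fold ensemble evaluation: each row is scored by the AUC-weighted
# mean of included models in whose *test* split it fell; rows never held out
# are dropped
.ensemble_oof_auc <- function(runs, data) {
  aucs <- vapply(runs, `[[`, numeric(1), "auc_test")
  incl <- which(aucs > 0.5)
  if (length(incl) == 0) return(NA_real_)
  n <- nrow(data)
  num <- numeric(n); den <- numeric(n)
  for (i in incl) {
    r <- runs[[i]]
    p <- stats::predict(r$model, data[r$split$test, , drop = FALSE])
    num[r$split$test] <- num[r$split$test] + aucs[i] * p
    den[r$split$test] <- den[r$split$test] + aucs[i]
  }
  has <- den > 0
  if (length(unique(data$response[has])) < 2) return(NA_real_)
  auc(num[has] / den[has], data$response[has])
}

#' Fit an AUC-weighted ensemble species distribution model
#'
#' The package's central fitting function. Takes a presence/absence response
#' and ecogeographic predictors (formula interface), runs six classification
#' algorithms over repeated stratified calibration/test splits, scores every
#' run by held-out AUC, computes permutation variable importance, and forms
#' the AUC-weighted ensemble of the better-than-chance runs.
#'
#' @param formula model formula, e.g. `response ~ depth + slope + habitat`
#'   (or `response ~ .` over a feature table's predictors).
#' @param data a `feature_table` or data frame; the response must be 0/1.
#' @param algorithms subset of `GAM, GBM, CTA, FDA, RF, MAXENT`.
#' @param n_runs calibration/test splits per algorithm (paper-style default
#'   10, i.e. 60 model runs).
#' @param calib_fraction calibration fraction of each split.
#' @param seed master seed controlling splits, stochastic learners and
#'   importance permutations.
#' @param n_perm permutations per variable for importance.
#' @param compute_importance set `FALSE` to skip the importance table.
#' @param control an [esdm_control()].
#' @return an object of class `esdm` with components `runs`, `importance`
#'   (per-algorithm means and mean of means), `auc_ensemble` (out-of-fold
#'   AUC of the weighted ensemble), `auc_by_algorithm`, and the call
#'   metadata. Methods: `print`, `summary`, `predict`, `plot`.
#' @seealso [ensemble_predict()], [variable_importance()], [auc()]
#' @export
#' @examples
#' set.seed(1)
#' n <- 120
#' d <- data.frame(depth = runif(n, 1, 40), dist = runif(n, 0, 4000))
#' d$response <- rbinom(n, 1, plogis(1 - ((d$depth - 10) / 5)^2 - d$dist / 1000))
#' fit <- esdm(response ~ depth + dist, d, algorithms = c("CTA", "RF"),
#'             n_runs = 2, seed = 1)
#' print(fit)
esdm <- function(formula, data, algorithms = .esdm_algorithms, n_runs = 10,
                 calib_fraction = 0.75, seed = 1, n_perm = 10,
                 compute_importance = TRUE, control = esdm_control()) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  resp_name <- all.vars(formula)[1]
  predictors <- attr(stats::terms(mf), "term.labels")
  d <- mf
  names(d)[1] <- "response"
  if (!all(d$response %in% c(0, 1))) stop("response must be 0/1")
  runs <- run_cross_validation(d, predictors, algorithms, n_runs,
                               calib_fraction, seed, n_perm,
                               compute_importance, control)
  aucs <- vapply(runs, `[[`, numeric(1), "auc_test")
  algs <- vapply(runs, `[[`, character(1), "algorithm")
  importance <- if (compute_importance) build_importance_table(runs) else NULL
  structure(list(runs = runs, importance = importance,
                 auc_ensemble = .ensemble_oof_auc(runs, d),
                 auc_by_algorithm = split(aucs, algs),
                 formula = formula, response_name = resp_name,
                 predictors = predictors, data = d,
                 seed = seed, n_runs = n_runs,
                 calib_fraction = calib_fraction),
            class = "esdm")
}

#' @export
print.esdm <- function(x, ...) {
  aucs <- vapply(x$runs, `[[`, numeric(1), "auc_test")
  cat(sprintf("Ensemble SDM: %d model runs (%s x %d splits)\n",
              length(x$runs),
              paste(unique(vapply(x$runs, `[[`, character(1), "algorithm")),
                    collapse = "/"), x$n_runs))
  cat(sprintf("median single-model test AUC: %.3f\n", stats::median(aucs)))
  cat(sprintf("ensemble out-of-fold AUC:     %.3f\n", x$auc_ensemble))
  invisible(x)
}

#' @export
summary.esdm <- function(object, ...) {
  aucs <- vapply(object$runs, `[[`, numeric(1), "auc_test")
  algs <- vapply(object$runs, `[[`, character(1), "algorithm")
  by_alg <- t(vapply(split(aucs, algs), function(a)
    c(n = length(a), min = min(a), median = stats::median(a), max = max(a)),
    numeric(4)))
  out <- list(auc_by_algorithm = by_alg,
              median_auc = stats::median(aucs),
              auc_ensemble = object$auc_ensemble,
              importance = object$importance,
              n_excluded = sum(aucs <= 0.5))
  class(out) <- "summary.esdm"
  out
}

#' @export
print.summary.esdm <- function(x, ...) {
  cat("Held-out AUC by algorithm:\n")
  print(round(x$auc_by_algorithm, 3))
  cat(sprintf("\nmedian single-model AUC: %.3f\nensemble AUC: %.3f (%d run(s) excluded at AUC <= 0.5)\n",
              x$median_auc, x$auc_ensemble, x$n_excluded))
  if (!is.null(x$importance)) {
    cat("\nVariable importance (mean of means):\n")
    mm <- sort(unlist(x$importance["mean_of_means", ]), decreasing = TRUE)
    print(round(mm, 3))
  }
  invisible(x)
}

#' Predict ensemble occurrence probability
#' @param object a fitted [esdm()] model.
#' @param newdata data frame with the predictor columns (defaults to the
#'   training table).
#' @param ... unused.
#' @return numeric vector of ensemble probabilities; the full
#'   `ensemble_surface` is available via [ensemble_predict()].
#' @export
predict.esdm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  ensemble_predict(object$runs, newdata)$probability
}

#' AUC box plot by algorithm
#'
#' Box plot of held-out AUC per algorithm with the ensemble's out-of-fold AUC
#' as a dashed line -- the standard model-performance figure for ensemble
#' SDMs.
#' @param x a fitted [esdm()] model.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.esdm <- function(x, ...) {
  aucs <- vapply(x$runs, `[[`, numeric(1), "auc_test")
  algs <- factor(vapply(x$runs, `[[`, character(1), "algorithm"),
                 levels = unique(vapply(x$runs, `[[`, character(1),
                                        "algorithm")))
  graphics::boxplot(aucs ~ algs, ylab = "held-out AUC", xlab = "",
                    ylim = c(min(0.4, min(aucs)), 1), ...)
  graphics::abline(h = x$auc_ensemble, lty = 2)
  graphics::abline(h = 0.5, col = "grey")
  invisible(x)
}

#' Residuals of the ensemble fit
#' @param object a fitted [esdm()] model.
#' @param ... unused.
#' @return response residuals (observed 0/1 minus ensemble probability) on
#'   the training rows.
#' @export
residuals.esdm <- function(object, ...) {
  object$data$response - predict.esdm(object)
}
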