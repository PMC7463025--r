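#' Base-learner control settings
#'
#' Fixed hyperparameters for the six presence/absence classifiers. These are
#' documented defaults chosen to be conventional for ecological SDM work at
#' a few hundred response cells; none of the package's contracts depend on
#' their exact values.
#'
#' @param gam_k basis dimension for GAM smooths.
#' @param gbm_nrounds,gbm_depth,gbm_eta boosting rounds, tree depth and
#'   learning rate for the boosted-trees learner.
#' @param cta_cp,cta_minbucket complexity parameter and minimum terminal-node
#'   size for the classification tree.
#' @param fda_df degrees of freedom of the natural-spline basis expansion
#'   behind the flexible discriminant.
#' @param rf_ntree number of random-forest trees.
#' @param maxent_lambda fallback lasso penalty when cross-validated selection
#'   is not feasible (fewer than 20 calibration rows).
#' @return an `esdm_control` list.
#' @export
esdm_control <- function(gam_k = 4, gbm_nrounds = 100, gbm_depth = 3,
                         gbm_eta = 0.1, cta_cp = 0.01, cta_minbucket = 5,
                         fda_df = 3, rf_ntree = 500, maxent_lambda = 0.01) {
  structure(list(gam_k = gam_k, gbm_nrounds = gbm_nrounds,
                 gbm_depth = gbm_depth, gbm_eta = gbm_eta, cta_cp = cta_cp,
                 cta_minbucket = cta_minbucket, fda_df = fda_df,
                 rf_ntree = rf_ntree, maxent_lambda = maxent_lambda),
            class = "esdm_control")
}

#' @keywords internal
.esdm_algorithms <- c("GAM", "GBM", "CTA", "FDA", "RF", "MAXENT")

# ---- shared design-matrix plumbing -----------------------------------------

# record per-column metadata of the predictor frame at training time
.col_spec <- function(x) {
  lapply(x, function(col) {
    if (is.factor(col) || is.character(col)) {
      f <- as.factor(col)
      tab <- table(f)
      list(type = "factor", levels = levels(f),
           modal = names(tab)[which.max(tab)])
    } else list(type = "numeric")
  })
}

# coerce newdata to the training column spec; unseen factor levels collapse
# to the modal training level (documented fallback for prediction over the
# full grid)
.conform <- function(newdata, spec) {
  out <- newdata[names(spec)]
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s$type == "factor") {
      v <- as.character(out[[nm]])
      v[!(v %in% s$levels)] <- s$modal
      out[[nm]] <- factor(v, levels = s$levels)
    } else out[[nm]] <- as.numeric(out[[nm]])
  }
  out
}

# plain dummy-coded model matrix (no intercept column)
.make_mm <- function(x) {
  mm <- stats::model.matrix(~ ., data = x)
  mm[, -1, drop = FALSE]
}

# MAXENT-style feature expansion: linear + quadratic + three forward hinges
# per numeric variable (hinge knots at training quartiles), dummies for
# factors
.maxent_features <- function(x, knots = NULL) {
  cols <- list(); kn <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) {
      cols[[paste0(nm, "_lin")]] <- v
      cols[[paste0(nm, "_sq")]] <- v^2
      q <- if (is.null(knots)) stats::quantile(v, c(0.25, 0.5, 0.75),
                                               names = FALSE)
           else knots[[nm]]
      kn[[nm]] <- q
      for (j in seq_along(q))
        cols[[paste0(nm, "_h", j)]] <- pmax(0, v - q[j])
    } else {
      mm <- stats::model.matrix(~ v)[, -1, drop = FALSE]
      for (j in seq_len(ncol(mm))) cols[[paste0(nm, "_d", j)]] <- mm[, j]
    }
  }
  list(mm = do.call(cbind, cols), knots = kn)
}

# natural-spline basis for the flexible discriminant, with stored knots so
# the same basis is evaluated on newdata
.fda_basis <- function(x, df, spec = NULL) {
  cols <- list(); sp <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) {
      if (is.null(spec)) {
        if (length(unique(v)) > df) {
          b <- suppressWarnings(splines::ns(v, df = df))
          sp[[nm]] <- list(kind = "ns", knots = attr(b, "knots"),
                           bk = attr(b, "Boundary.knots"))
        } else {
          b <- matrix(v, ncol = 1)
          sp[[nm]] <- list(kind = "lin")
        }
      } else {
        s <- spec[[nm]]
        b <- if (s$kind == "ns")
          suppressWarnings(splines::ns(v, knots = s$knots,
                                       Boundary.knots = s$bk))
        else matrix(v, ncol = 1)
      }
      for (j in seq_len(ncol(b))) cols[[paste0(nm, "_b", j)]] <- b[, j]
    } else {
      mm <- stats::model.matrix(~ v)[, -1, drop = FALSE]
      for (j in seq_len(ncol(mm))) cols[[paste0(nm, "_d", j)]] <- mm[, j]
      if (is.null(spec)) sp[[nm]] <- list(kind = "factor")
    }
  }
  list(mm = do.call(cbind, cols), spec = if (is.null(spec)) sp else spec)
}

# ---- the six fitters -------------------------------------------------------

#' Fit one presence/absence classifier
#'
#' Fits a single algorithm on calibration rows and returns a
#' probability-emitting predictor. The regression methods (GAM, GBM) use a
#' binomial error structure with the logit link; CTA and FDA are
#' classification methods (FDA realized as linear discriminant analysis over
#' a natural-spline basis expansion); RF is a probability forest; MAXENT is
#' realized as an L1-regularized logistic regression over a
#' linear+quadratic+hinge feature expansion, which maximum entropy reduces to
#' under a presence/absence design. Non-converging fits fall back to a
#' binomial GLM (recorded on the returned object).
#'
#' @param algorithm one of `"GAM"`, `"GBM"`, `"CTA"`, `"FDA"`, `"RF"`,
#'   `"MAXENT"`.
#' @param data data frame holding the 0/1 column `response` plus predictor
#'   columns.
#' @param predictors character vector of predictor column names.
#' @param control an [esdm_control()].
#' @param seed integer seed for the stochastic learners.
#' @return an `esdm_model`; use `predict(model, newdata)` to get occurrence
#'   probabilities.
#' @export
fit_single <- function(algorithm, data, predictors,
                       control = esdm_control(), seed = 1) {
  algorithm <- match.arg(algorithm, .esdm_algorithms)
  y <- data$response
  if (length(unique(y)) < 2) stop("both classes must be present to fit")
  x <- data[predictors]
  spec <- .col_spec(x)
  x <- .conform(x, spec)
  set.seed(as.integer(seed))
  fallback <- FALSE
  fit <- extra <- NULL
  glm_fallback <- function() {
    stats::glm(y ~ ., data = cbind(y = y, .as_numeric_frame(x)),
               family = stats::binomial())
  }
  if (algorithm == "GAM") {
    terms <- vapply(names(x), function(nm) {
      v <- x[[nm]]
      if (is.numeric(v) && length(unique(v)) >= 2 * control$gam_k)
        sprintf("s(%s, k = %d)", nm, control$gam_k)
      else if (length(unique(v)) >= 2) nm else ""
    }, character(1))
    terms <- terms[terms != ""]
    fml <- if (length(terms) == 0) y ~ 1 else
      stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    fit <- tryCatch(mgcv::gam(fml, data = cbind(y = y, x),
                              family = stats::binomial()),
                    error = function(e) NULL)
    if (is.null(fit)) { fit <- glm_fallback(); fallback <- TRUE }
  } else if (algorithm == "GBM") {
    mm <- .make_mm(x)
    dtrain <- xgboost::xgb.DMatrix(mm, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = control$gbm_depth, eta = control$gbm_eta,
                    nthread = 1, seed = as.integer(seed)),
      data = dtrain, nrounds = control$gbm_nrounds, verbose = 0)
    extra <- list(mm_names = colnames(mm))
  } else if (algorithm == "CTA") {
    fit <- rpart::rpart(
      yf ~ ., data = cbind(yf = factor(y, levels = c(0, 1)), x),
      method = "class",
      control = rpart::rpart.control(cp = control$cta_cp,
                                     minbucket = control$cta_minbucket,
                                     xval = 0))
  } else if (algorithm == "FDA") {
    fb <- .fda_basis(x, control$fda_df)
    keep <- which(apply(fb$mm, 2, stats::sd) > 1e-12)
    mm <- fb$mm[, keep, drop = FALSE]
    qr_ <- qr(mm)
    mm <- mm[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(MASS::lda(mm, grouping = factor(y, levels = c(0, 1)))),
      error = function(e) NULL)
    if (is.null(fit)) { fit <- glm_fallback(); fallback <- TRUE }
    else extra <- list(basis_spec = fb$spec, keep_names = colnames(mm))
  } else if (algorithm == "RF") {
    fit <- randomForest::randomForest(x = x,
                                      y = factor(y, levels = c(0, 1)),
                                      ntree = control$rf_ntree)
  } else if (algorithm == "MAXENT") {
    mf <- .maxent_features(x)
    if (nrow(x) >= 20) {
      foldid <- sample(rep(1:5, length.out = nrow(x)))
      cvfit <- tryCatch(suppressWarnings(
        glmnet::cv.glmnet(mf$mm, y, family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = 30)),
        error = function(e) NULL)
      if (!is.null(cvfit)) {
        fit <- cvfit; extra <- list(knots = mf$knots, lambda = "lambda.min")
      }
    }
    if (is.null(fit)) {
      fit <- tryCatch(glmnet::glmnet(mf$mm, y, family = "binomial", alpha = 1,
                                     lambda = control$maxent_lambda),
                      error = function(e) NULL)
      if (is.null(fit)) { fit <- glm_fallback(); fallback <- TRUE }
      else extra <- list(knots = mf$knots, lambda = control$maxent_lambda)
    }
  }
  structure(list(algorithm = algorithm, fit = fit, col_spec = spec,
                 predictors = predictors, control = control, extra = extra,
                 fallback = fallback),
            class = "esdm_model")
}

# numeric-only copy used by the GLM fallback (factors dummy-coded)
.as_numeric_frame <- function(x) {
  as.data.frame(.make_mm(x))
}

#' Predict occurrence probability from a single fitted classifier
#' @param object an `esdm_model` from [fit_single()].
#' @param newdata data frame with the predictor columns.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.esdm_model <- function(object, newdata, ...) {
  x <- .conform(newdata, object$col_spec)
  if (object$fallback)
    return(as.numeric(stats::predict(object$fit,
                                     newdata = .as_numeric_frame(x),
                                     type = "response")))
  switch(object$algorithm,
    GAM = as.numeric(stats::predict(object$fit, newdata = x,
                                    type = "response")),
    GBM = {
      mm <- .make_mm(x)
      mm <- mm[, object$extra$mm_names, drop = FALSE]
      as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(mm)))
    },
    CTA = as.numeric(stats::predict(object$fit, newdata = x,
                                    type = "prob")[, "1"]),
    FDA = {
      fb <- .fda_basis(x, object$control$fda_df, spec = object$extra$basis_spec)
      mm <- fb$mm[, object$extra$keep_names, drop = FALSE]
      as.numeric(stats::predict(object$fit, mm)$posterior[, "1"])
    },
    RF = as.numeric(stats::predict(object$fit, newdata = x,
                                   type = "prob")[, "1"]),
    MAXENT = {
      mf <- .maxent_features(x, knots = object$extra$knots)
      s <- object$extra$lambda
      as.numeric(stats::predict(object$fit, newx = mf$mm, s = s,
                                type = "response"))
    })
}
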