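test_that("AUC is the rank-sum concordance statistic", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # three positives (0.9, 0.8, 0.3), one negative (0.4): 2 of 3 pairs concordant
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.4), c(1, 1, 1, 0)), 2 / 3)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(auc(1:3, c(1, 0)), "length")
})

test_that("AUC equals exhaustive pair enumeration with ties", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc(scores, labels), auc_enum(scores, labels))
  }
})

test_that("stratified splits have the right sizes and are reproducible", {
  resp <- rep(c(0, 1), each = 50)
  sp <- split_calibration(resp, 0.75, split_seed = 3)
  expect_length(sp$calib, 75)
  expect_length(sp$test, 25)
  expect_lte(abs(sum(resp[sp$calib] == 1) - sum(resp[sp$calib] == 0)), 1)
  expect_lte(abs(sum(resp[sp$test] == 1) - sum(resp[sp$test] == 0)), 1)
  expect_identical(sp, split_calibration(resp, 0.75, split_seed = 3))
  sp2 <- split_calibration(resp, 0.75, split_seed = 4)
  expect_false(identical(sp$calib, sp2$calib))
  # ten runs give ten distinct splits
  splits <- lapply(1:10, function(s) split_calibration(resp, 0.75, s)$calib)
  expect_equal(length(unique(splits)), 10)
})

test_that("splits that would empty a class stratum are rejected", {
  expect_error(split_calibration(c(1, rep(0, 7)), 0.75, 1), "absent")
  expect_error(split_calibration(c(1, 0, 1, 0), 0.75, 1), "at least 8")
})

test_that("every algorithm emits probabilities and CTA separates separable data", {
  d <- toy_table(n = 100, seed = 2)
  for (alg in c("GAM", "GBM", "CTA", "FDA", "RF", "MAXENT")) {
    m <- fit_single(alg, d, c("depth", "dist", "noise"), seed = 5)
    p <- predict(m, d)
    expect_length(p, 100)
    expect_true(all(p >= 0 & p <= 1), info = alg)
  }
  # a perfectly separating predictor gives training AUC 1 for the tree
  sep <- data.frame(x = c(1:20, 41:60),
                    response = rep(c(0, 1), each = 20))
  m <- fit_single("CTA", sep, "x", seed = 1)
  expect_equal(auc(predict(m, sep), sep$response), 1)
})

test_that("a GAM recovers a smooth unimodal depth effect", {
  set.seed(6)
  n <- 400
  d <- data.frame(depth = runif(n, 1, 40), other = rnorm(n))
  d$response <- rbinom(n, 1, plogis(1.5 - ((d$depth - 12) / 6)^2))
  m <- fit_single("GAM", d, c("depth", "other"), seed = 1)
  prof <- predict(m, data.frame(depth = seq(2, 38, by = 0.5), other = 0))
  peak <- which.max(prof)
  expect_gt(peak, 5)               # interior maximum,
  expect_lt(peak, length(prof) - 5)  # not at a boundary
  expect_equal(seq(2, 38, by = 0.5)[peak], 12, tolerance = 6)
})

test_that("held-out AUC is centred near chance when the response is noise", {
  set.seed(7)
  aucs <- vapply(1:30, function(s) {
    d <- data.frame(a = rnorm(60), b = rnorm(60),
                    response = rep(c(0, 1), 30))
    sp <- split_calibration(d$response, 0.75, s)
    m <- fit_single("CTA", d[sp$calib, ], c("a", "b"), seed = s)
    auc(predict(m, d[sp$test, ]), d$response[sp$test])
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("permutation importance ignores unused variables and finds drivers", {
  set.seed(8)
  d <- data.frame(v = runif(40), w = runif(40))
  # a predictor that is the identity on v and blind to w
  m <- mock_model(function(nd) nd$v)
  imp <- variable_importance(m, d, c("v", "w"), n_perm = 10, seed = 1)
  expect_equal(unname(imp["w"]), 0)
  expect_gt(imp["v"], 0.5)
  expect_true(all(imp >= 0 & imp <= 1))
})

test_that("duplicated additive variables get symmetric importance", {
  set.seed(9)
  d <- data.frame(a = runif(60))
  d$b <- d$a
  m <- mock_model(function(nd) plogis(nd$a + nd$b))
  imp <- variable_importance(m, d, c("a", "b"), n_perm = 20, seed = 2)
  expect_equal(unname(imp["a"]), unname(imp["b"]), tolerance = 0.1)
})

test_that("constant predictions give zero importance with a note", {
  d <- data.frame(a = runif(20))
  m <- mock_model(function(nd) rep(0.4, nrow(nd)))
  expect_message(imp <- variable_importance(m, d, "a", seed = 1), "constant")
  expect_equal(unname(imp), 0)
})

test_that("cross-validation produces algorithms x runs results, reproducibly", {
  d <- toy_table(n = 90, seed = 10)
  runs <- run_cross_validation(d, c("depth", "dist"),
                               algorithms = c("CTA", "RF"), n_runs = 2,
                               seed = 4, n_perm = 3)
  expect_length(runs, 4)
  expect_setequal(vapply(runs, `[[`, character(1), "algorithm"),
                  c("CTA", "RF"))
  aucs1 <- vapply(runs, `[[`, numeric(1), "auc_test")
  runs2 <- run_cross_validation(d, c("depth", "dist"),
                                algorithms = c("CTA", "RF"), n_runs = 2,
                                seed = 4, n_perm = 3)
  expect_identical(aucs1, vapply(runs2, `[[`, numeric(1), "auc_test"))
  one <- run_cross_validation(d, "depth", algorithms = "CTA", n_runs = 1,
                              seed = 1, compute_importance = FALSE)
  expect_length(one, 1)
  expect_null(one[[1]]$importance)
})

test_that("the importance table averages runs and algorithms correctly", {
  mk_run <- function(alg, run, imp) list(algorithm = alg, run_index = run,
                                         auc_test = 0.8, importance = imp)
  runs <- list(mk_run("A", 1, c(x = 0.2, y = 0.6)),
               mk_run("A", 2, c(x = 0.4, y = 0.8)),
               mk_run("B", 1, c(x = 1.0, y = 0.0)))
  tab <- build_importance_table(runs)
  expect_equal(tab["A", "x"], 0.3)
  expect_equal(tab["A", "y"], 0.7)
  expect_equal(tab["mean_of_means", "x"], mean(c(0.3, 1.0)))
  expect_true(all(as.matrix(tab) >= 0 & as.matrix(tab) <= 1))
  single <- build_importance_table(runs[3])
  expect_equal(unlist(single["B", ]), c(x = 1, y = 0))
})

test_that("ensemble weighting follows the documented AUC-proportional rule", {
  d <- data.frame(z = 1:5)
  mk <- function(auc_, p) list(algorithm = "M", run_index = 1, auc_test = auc_,
                               model = mock_model(function(nd)
                                 rep(p, nrow(nd))))
  runs <- list(mk(0.6, 0.2), mk(0.8, 0.9))
  surf <- ensemble_predict(runs, d)
  expect_equal(surf$probability,
               rep((0.6 * 0.2 + 0.8 * 0.9) / 1.4, 5), tolerance = 1e-12)
  expect_equal(sum(surf$weights$weight), 1)
  # a run at exactly 0.5 is excluded (strict inequality)
  surf2 <- ensemble_predict(list(mk(0.5, 0.0), mk(0.8, 0.9)), d)
  expect_equal(surf2$probability, rep(0.9, 5))
  expect_equal(surf2$n_excluded, 1)
  # a single included run reproduces its own predictions with weight 1
  surf3 <- ensemble_predict(list(mk(0.7, 0.33)), d)
  expect_equal(surf3$probability, rep(0.33, 5))
  expect_equal(surf3$weights$weight, 1)
  expect_error(ensemble_predict(list(mk(0.4, 0.1)), d), "no skillful")
})

test_that("the fitted ensemble is a convex combination per cell", {
  d <- toy_table(n = 100, seed = 11)
  fit <- esdm(response ~ depth + dist + noise, d,
              algorithms = c("CTA", "RF", "GBM"), n_runs = 2, seed = 2,
              compute_importance = FALSE)
  surf <- ensemble_predict(fit$runs, d)
  lo <- apply(surf$member_predictions, 1, min)
  hi <- apply(surf$member_predictions, 1, max)
  expect_true(all(surf$probability >= lo - 1e-12))
  expect_true(all(surf$probability <= hi + 1e-12))
})

test_that("esdm objects carry the standard modelling methods", {
  d <- toy_table(n = 100, seed = 12)
  fit <- esdm(response ~ depth + dist, d, algorithms = c("CTA", "RF"),
              n_runs = 2, seed = 3, n_perm = 3)
  expect_s3_class(fit, "esdm")
  expect_output(print(fit), "Ensemble SDM")
  s <- summary(fit)
  expect_output(print(s), "median single-model AUC")
  p <- predict(fit, d)
  expect_true(all(p >= 0 & p <= 1))
  expect_length(residuals(fit), 100)
  expect_equal(residuals(fit), d$response - predict(fit), tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_true(is.finite(fit$auc_ensemble))
  expect_error(esdm(response ~ depth, transform(d, response = response + 1),
                    algorithms = "CTA"), "0/1")
})
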