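# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written via a different route than the code it checks.

# AUC by exhaustive enumeration of presence/absence pairs (ties count half)
auc_enum <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# VIFs via the inverse-correlation-matrix identity (diag of solve(R))
vif_invcor <- function(x) {
  R <- stats::cor(as.matrix(x))
  v <- tryCatch(diag(solve(R)), error = function(e) rep(Inf, ncol(x)))
  v[v > 1e10] <- Inf
  stats::setNames(v, colnames(x))
}

# literal re-implementations of the two screening loops
brute_vifcor <- function(x, r_thr = 0.7) {
  x <- as.data.frame(x)
  order0 <- names(x)
  repeat {
    if (ncol(x) < 2) break
    R <- abs(stats::cor(as.matrix(x))); diag(R) <- 0
    if (max(R) <= r_thr) break
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    pair <- colnames(R)[ij]
    v <- vif_invcor(x)[pair]
    drop <- if (isTRUE(all.equal(v[1], v[2])) || all(is.infinite(v)))
      pair[which.max(match(pair, order0))] else pair[which.max(v)]
    x <- x[setdiff(names(x), drop)]
  }
  names(x)
}

brute_vifstep <- function(x, v_thr = 3) {
  x <- as.data.frame(x)
  order0 <- names(x)
  repeat {
    if (ncol(x) < 2) break
    v <- vif_invcor(x)
    if (max(v) <= v_thr) break
    worst <- names(v)[v == max(v)]
    drop <- worst[which.max(match(worst, order0))]
    x <- x[setdiff(names(x), drop)]
  }
  names(x)
}

# exact upper-tail hypergeometric probability P(X >= obs),
# X ~ Hypergeom(N cells, m in mask, k placed)
hyper_tail <- function(N, m, k, obs) {
  stats::phyper(obs - 1, m, N - m, k, lower.tail = FALSE)
}

# per-cell track length by 1 m polyline walking
walk_effort <- function(lines, grid) {
  out <- numeric(grid$n_rows * grid$n_cols)
  for (m in lines) {
    for (i in seq_len(nrow(m) - 1)) {
      a <- m[i, ]; b <- m[i + 1, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      n <- ceiling(L)
      t <- (seq_len(n) - 0.5) / n
      pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
      cells <- cell_of_point(grid, pts)
      tab <- table(cells[!is.na(cells)])
      idx <- as.integer(names(tab))
      out[idx] <- out[idx] + as.numeric(tab) * L / n
    }
  }
  out
}

# mock probability model whose predictions are an arbitrary function of the
# data; used to test permutation importance and ensemble weighting without a
# real learner in the way
mock_model <- function(fun) structure(list(fun = fun), class = "mock_model")
predict.mock_model <- function(object, newdata, ...) object$fun(newdata)
registerS3method("predict", "mock_model", predict.mock_model)
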