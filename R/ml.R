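# Internal two-class learners sharing one interface:
#   .fit_<algo>(X, y, hyper)   X: numeric matrix (already standardized),
#                              y: -1/+1; returns a fit object
#   .decision(fit, X)          signed raw score, positive -> positive class
# LDA: pooled-covariance discriminant with ridge regularization.
# SVM: linear, L1-loss dual coordinate descent (compiled).
# GBM: logistic gradient-boosted depth-limited regression trees.

.fit_lda <- function(X, y, hyper = list()) {
  lam <- hyper$lambda %||% 1e-3
  i0 <- y < 0; i1 <- y > 0
  mu0 <- colMeans(X[i0, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  S <- (crossprod(sweep(X[i0, , drop = FALSE], 2, mu0)) +
        crossprod(sweep(X[i1, , drop = FALSE], 2, mu1))) /
    (nrow(X) - 2)
  p <- ncol(X)
  S <- S + diag(lam * mean(diag(S)) + 1e-10, p)
  w <- solve(S, mu1 - mu0)
  list(type = "lda", w = w, b = -sum(w * (mu0 + mu1)) / 2)
}

.fit_svm <- function(X, y, hyper = list()) {
  C <- hyper$C %||% 1
  wv <- .cpp_svm_dcd(X, as.numeric(y), C, 200L, 1e-4, 7L)
  p <- ncol(X)
  list(type = "svm", w = wv[seq_len(p)], b = wv[p + 1], C = C)
}

# exact greedy regression tree on gradient/hessian pairs
.fit_tree <- function(X, g, h, depth, min_obs = 5L) {
  build <- function(idx, d) {
    G <- sum(g[idx]); H <- sum(h[idx])
    leaf <- list(leaf = TRUE, value = G / (H + 1e-9))
    if (d >= depth || length(idx) < 2 * min_obs) return(leaf)
    best <- list(gain = 1e-8)
    for (j in seq_len(ncol(X))) {
      xo <- X[idx, j]
      o <- order(xo)
      xs <- xo[o]; gs <- cumsum(g[idx][o]); hs <- cumsum(h[idx][o])
      n <- length(idx)
      valid <- which(xs[-n] < xs[-1])  # split between distinct values
      valid <- valid[valid >= min_obs & valid <= n - min_obs]
      if (!length(valid)) next
      gl <- gs[valid]; hl <- hs[valid]
      gain <- gl^2 / (hl + 1e-9) + (G - gl)^2 / (H - hl + 1e-9) -
        G^2 / (H + 1e-9)
      k <- which.max(gain)
      if (gain[k] > best$gain)
        best <- list(gain = gain[k], j = j,
                     cut = (xs[valid[k]] + xs[valid[k] + 1]) / 2)
    }
    if (is.null(best$j)) return(leaf)
    left <- idx[X[idx, best$j] <= best$cut]
    right <- setdiff(idx, left)
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = build(left, d + 1), right = build(right, d + 1))
  }
  build(seq_len(nrow(X)), 0L)
}

.predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    l <- idx[X[idx, node$j] <= node$cut]
    rec(node$left, l)
    rec(node$right, setdiff(idx, l))
  }
  rec(tree, seq_len(nrow(X)))
  out
}

.fit_gbm <- function(X, y, hyper = list()) {
  n_trees <- hyper$n_trees %||% 100L
  depth <- hyper$depth %||% 3L
  lr <- hyper$lr %||% 0.1
  y01 <- as.numeric(y > 0)
  p1 <- mean(y01)
  f0 <- log(max(p1, 1e-6) / max(1 - p1, 1e-6))
  F <- rep(f0, nrow(X))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    pr <- 1 / (1 + exp(-F))
    g <- y01 - pr
    h <- pmax(pr * (1 - pr), 1e-6)
    tr <- .fit_tree(X, g, h, depth)
    trees[[t]] <- tr
    F <- F + lr * .predict_tree(tr, X)
  }
  list(type = "gbm", f0 = f0, lr = lr, trees = trees)
}

.decision <- function(fit, X) {
  if (fit$type %in% c("lda", "svm"))
    return(drop(X %*% fit$w) + fit$b)
  F <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) F <- F + fit$lr * .predict_tree(tr, X)
  F  # log-odds of the positive class
}

.default_grid <- function(algorithm) {
  switch(algorithm,
    SVM = lapply(c(0.01, 0.1, 1, 10), function(C) list(C = C)),
    LDA = lapply(c(1e-4, 1e-3, 1e-2), function(l) list(lambda = l)),
    GBM = {
      g <- expand.grid(n_trees = c(100L, 300L), depth = c(3L, 5L),
                       lr = c(0.05, 0.1))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    })
}

.fit_algo <- function(algorithm, X, y, hyper)
  switch(algorithm, LDA = .fit_lda(X, y, hyper),
         SVM = .fit_svm(X, y, hyper), GBM = .fit_gbm(X, y, hyper))

# standardization learned on the training split; zero-variance features
# are kept but contribute nothing (scale set to 1, centered values 0)
.standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- Inf  # zero-variance -> ignored
  list(mu = mu, sd = sdv)
}

.apply_std <- function(std, X) sweep(sweep(X, 2, std$mu), 2, std$sd, "/")

# grid search by k-fold CV accuracy on the training portion
.grid_search <- function(algorithm, X, y, grid, k = 5L, seed = 1L) {
  if (length(grid) == 1) return(grid[[1]])
  folds <- with_seed(seed, "folds", {
    f <- integer(length(y))
    for (cl in c(-1, 1)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    f
  })
  acc <- vapply(grid, function(hp) {
    mean(vapply(seq_len(k), function(i) {
      tr <- folds != i
      if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      std <- .standardizer(X[tr, , drop = FALSE])
      fit <- .fit_algo(algorithm, .apply_std(std, X[tr, , drop = FALSE]),
                       y[tr], hp)
      sc <- .decision(fit, .apply_std(std, X[!tr, , drop = FALSE]))
      mean((sc > 0) == (y[!tr] > 0))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(acc)]]
}
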