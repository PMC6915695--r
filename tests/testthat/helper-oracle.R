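# Independent brute-force NIPALS PLS1 oracle: straight loops, no deflation
# tricks, no code shared with the implementation under test. Input X must
# already be column-preprocessed and y centered.
oracle_nipals <- function(X, yc, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  C <- numeric(ncomp)
  Xd <- X
  for (a in seq_len(ncomp)) {
    w <- numeric(p)
    for (j in seq_len(p)) w[j] <- sum(Xd[, j] * yc)
    w <- w / sqrt(sum(w * w))
    t <- numeric(n)
    for (i in seq_len(n)) t[i] <- sum(Xd[i, ] * w)
    tt <- sum(t * t)
    pv <- numeric(p)
    for (j in seq_len(p)) pv[j] <- sum(Xd[, j] * t) / tt
    cv <- sum(yc * t) / tt
    for (i in seq_len(n)) for (j in seq_len(p)) {
      Xd[i, j] <- Xd[i, j] - t[i] * pv[j]
    }
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; C[a] <- cv
  }
  predict_row <- function(x) {
    yhat <- 0
    for (a in seq_len(ncomp)) {
      ta <- sum(x * W[, a])
      yhat <- yhat + ta * C[a]
      x <- x - ta * P[, a]
    }
    yhat
  }
  list(W = W, P = P, C = C, T = Tm,
       predict = function(Xnew) apply(Xnew, 1, predict_row))
}

# Random two-class system: n/2 vs n/2 samples, p proteins.
random_system <- function(n, p, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p),
       y = rep(c(1L, 0L), length.out = n))
}

# Manual column preprocessing mirroring uv scaling, for oracle input.
uv_scale <- function(X) {
  Xs <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  Xs[, , drop = FALSE]
}
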