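#' Column-wise preprocessing of a modeling matrix
#'
#' Centers each column (protein) and optionally divides by its standard
#' deviation (`"uv"`, the chemometrics default) or its square root
#' (`"pareto"`). Constant columns cannot be scaled; they are flagged and
#' excluded from modeling.
#'
#' @param X numeric matrix, samples x proteins, no missing values (use the
#'   `"complete"` merge policy upstream), or an [expression_matrix()] whose
#'   transposed values will be used.
#' @param mode `"uv"`, `"pareto"` or `"center"`.
#' @return Object of class `scaled_matrix`: `X` (scaled, constant columns
#'   dropped), `X_raw`, `centers`, `scales`, `mode`, `excluded` (names of
#'   constant columns).
#' @export
scale_matrix <- function(X, mode = c("uv", "pareto", "center")) {
  mode <- match.arg(mode)
  if (inherits(X, "expression_matrix")) X <- t(X$values)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyNA(X)) {
    stop("matrix contains missing values; merge with policy = \"complete\" ",
         "before modeling")
  }
  prep <- .scale_fit(X, mode)
  structure(c(prep, list(X_raw = X, mode = mode)), class = "scaled_matrix")
}

# Fit preprocessing statistics on X and apply them; shared with CV refits.
.scale_fit <- function(X, mode) {
  centers <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  excluded <- colnames(X)[sds == 0]
  if (is.null(excluded)) excluded <- character(0)
  keep <- sds > 0
  scales <- switch(mode,
                   uv = sds,
                   pareto = sqrt(sds),
                   center = rep(1, length(sds)))
  Xs <- sweep(X[, keep, drop = FALSE], 2, centers[keep], `-`)
  Xs <- sweep(Xs, 2, scales[keep], `/`)
  list(X = Xs, centers = centers[keep], scales = scales[keep],
       excluded = excluded, all_cols = colnames(X))
}

.scale_apply <- function(Xnew, prep) {
  if (is.null(colnames(Xnew))) {
    stopifnot(ncol(Xnew) == length(prep$all_cols))
    colnames(Xnew) <- prep$all_cols
  }
  Xs <- Xnew[, names(prep$centers), drop = FALSE]
  Xs <- sweep(Xs, 2, prep$centers, `-`)
  sweep(Xs, 2, prep$scales, `/`)
}

# Encode a two-class vector as centered 0/1 with `positive` coded 1.
.encode_y <- function(y, positive = NULL) {
  if (is.numeric(y)) {
    y01 <- as.numeric(y)
  } else {
    y <- as.character(y)
    if (is.null(positive)) positive <- sort(unique(y))[1]
    y01 <- as.numeric(y == positive)
  }
  if (stats::var(y01) == 0) stop("class vector has zero variance")
  list(y01 = y01, yc = y01 - mean(y01), y_mean = mean(y01))
}

.as_scaled <- function(X, scaling) {
  if (inherits(X, "scaled_matrix")) X else scale_matrix(X, scaling)
}

#' Fit a PLS(-DA) model by NIPALS
#'
#' Single-response NIPALS partial least squares: for each component,
#' `w = X'y / ||X'y||`, `t = Xw`, `p = X't / (t't)`, `c = y't / (t't)`,
#' then X is deflated by `t p'`. Deterministic given the input order.
#'
#' @param X a [scale_matrix()] result, or a raw samples x proteins matrix
#'   (scaled internally with `scaling`).
#' @param y two-class vector (character/factor/0-1 numeric); coded 1 for
#'   the contrasted class and 0 otherwise, then centered.
#' @param n_components number of latent components.
#' @param scaling preprocessing mode when `X` is raw.
#' @param positive which class is coded 1 (default: first sorted level).
#' @return Object of class `opls_model` with `n_ortho = 0`: unit weight
#'   matrix `W`, scores `T`, loadings `P`, y-loadings `C`, `r2x`, `r2y`,
#'   `vip` and the preprocessing statistics needed for prediction.
#' @export
fit_pls <- function(X, y, n_components = 2L, scaling = "uv",
                    positive = NULL) {
  sm <- .as_scaled(X, scaling)
  enc <- .encode_y(y, positive)
  Xw <- sm$X
  n <- nrow(Xw); p <- ncol(Xw)
  if (n_components > min(n - 1L, p)) {
    stop("n_components exceeds the rank bound min(n - 1, p) = ",
         min(n - 1L, p))
  }
  ssx0 <- sum(Xw^2); ssy0 <- sum(enc$yc^2)
  W <- P <- matrix(0, p, n_components,
                   dimnames = list(colnames(Xw), NULL))
  Tm <- matrix(0, n, n_components)
  C <- ssy_a <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xw, enc$yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("residual X is uncorrelated with y at component ", a)
    w <- w / nw
    t <- drop(Xw %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(Xw, t)) / tt
    cv <- sum(enc$yc * t) / tt
    Xw <- Xw - tcrossprod(t, pv)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; C[a] <- cv
    ssy_a[a] <- cv^2 * tt
  }
  yhat <- Tm %*% C
  model <- structure(list(
    W = W, T = Tm, P = P, C = C,
    W_ortho = matrix(0, p, 0), T_ortho = matrix(0, n, 0),
    P_ortho = matrix(0, p, 0), c_ortho = numeric(0),
    n_ortho = 0L, n_components = n_components,
    ssy_components = ssy_a,
    r2x = 1 - sum(Xw^2) / ssx0,
    r2y = 1 - sum((enc$yc - yhat)^2) / ssy0,
    q2 = NA_real_,
    y_mean = enc$y_mean, y = enc$y01,
    prep = sm[c("centers", "scales", "all_cols")], scaling_mode = sm$mode,
    excluded = sm$excluded, kind = "pls"),
    class = "opls_model")
  model$vip <- compute_vip(model)
  model
}

#' Fit a two-group OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis with a
#' single predictive component and `n_ortho` y-orthogonal components,
#' following the orthogonal-signal-correction loop: with `w` the normalized
#' covariance direction `X'y`, each round computes `p = X't/(t't)`,
#' `w_o = p - (w'p) w` (normalized), `t_o = X w_o`, and deflates X by
#' `t_o p_o'`. The predictive component is fitted on the fully deflated X.
#' The predictive score sign is fixed so the contrasted class has positive
#' mean score, making positive predictive loadings read as specifically
#' up-regulated proteins.
#'
#' @inheritParams fit_pls
#' @param n_ortho number of orthogonal components, or `"auto"` to add
#'   components while seven-fold cross-validated Q2 improves by more than
#'   0.01 (capped at 5).
#' @param seed seed for the cross-validation fold assignment used by
#'   `n_ortho = "auto"` and stored Q2.
#' @param compute_q2 if `TRUE` (default) the model's `q2` slot is filled by
#'   [cross_validate_q2()].
#' @return Object of class `opls_model` with predictive weight `W`
#'   (unit-norm column), scores `T`, loadings `P`, orthogonal analogues
#'   `W_ortho`/`T_ortho`/`P_ortho`, `r2x`, `r2y`, `q2`, `vip`.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1L, scaling = "uv", positive = NULL,
                       seed = 1L, compute_q2 = TRUE) {
  sm <- .as_scaled(X, scaling)
  if (identical(n_ortho, "auto")) {
    best <- fit_oplsda(sm, y, 0L, scaling, positive, seed, compute_q2 = TRUE)
    for (k in 1:5) {
      # running out of orthogonal variation (or rank) ends the search
      cand <- tryCatch(
        fit_oplsda(sm, y, k, scaling, positive, seed, compute_q2 = TRUE),
        error = function(e) NULL)
      if (is.null(cand) || cand$q2 <= best$q2 + 0.01) break
      best <- cand
    }
    return(best)
  }
  n_ortho <- as.integer(n_ortho)
  enc <- .encode_y(y, positive)
  Xw <- sm$X
  n <- nrow(Xw); p <- ncol(Xw)
  if (n_ortho + 1L > min(n - 1L, p)) {
    stop("n_ortho + 1 exceeds the rank bound min(n - 1, p) = ",
         min(n - 1L, p))
  }
  ssx0 <- sum(Xw^2); ssy0 <- sum(enc$yc^2)
  w <- drop(crossprod(Xw, enc$yc))
  w <- w / sqrt(sum(w^2))
  W_o <- P_o <- matrix(0, p, n_ortho, dimnames = list(colnames(Xw), NULL))
  T_o <- matrix(0, n, n_ortho)
  c_o <- ssy_o <- numeric(n_ortho)
  for (k in seq_len(n_ortho)) {
    t <- drop(Xw %*% w)
    pv <- drop(crossprod(Xw, t)) / sum(t^2)
    wo <- pv - sum(w * pv) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      stop("no orthogonal variation left at component ", k)
    }
    wo <- wo / nwo
    to <- drop(Xw %*% wo)
    po <- drop(crossprod(Xw, to)) / sum(to^2)
    Xw <- Xw - tcrossprod(to, po)
    W_o[, k] <- wo; P_o[, k] <- po; T_o[, k] <- to
    cv <- sum(enc$yc * to) / sum(to^2)
    c_o[k] <- cv
    ssy_o[k] <- cv^2 * sum(to^2)
  }
  t <- drop(Xw %*% w)
  tt <- sum(t^2)
  pv <- drop(crossprod(Xw, t)) / tt
  cv <- sum(enc$yc * t) / tt
  # sign convention: contrasted class (y = 1) on the positive score side
  if (mean(t[enc$y01 == 1]) < 0) {
    w <- -w; t <- -t; pv <- -pv; cv <- -cv
  }
  ssy_pred <- cv^2 * tt
  yhat <- t * cv + T_o %*% c_o
  xhat_res <- Xw - tcrossprod(t, pv)
  model <- structure(list(
    W = matrix(w, p, 1, dimnames = list(colnames(sm$X), NULL)),
    T = matrix(t, n, 1),
    P = matrix(pv, p, 1, dimnames = list(colnames(sm$X), NULL)),
    C = cv,
    W_ortho = W_o, T_ortho = T_o, P_ortho = P_o, c_ortho = c_o,
    n_ortho = n_ortho, n_components = 1L,
    ssy_components = ssy_pred, ssy_ortho = ssy_o,
    r2x = 1 - sum(xhat_res^2) / ssx0,
    r2y = 1 - sum((enc$yc - yhat)^2) / ssy0,
    q2 = NA_real_,
    y_mean = enc$y_mean, y = enc$y01,
    prep = sm[c("centers", "scales", "all_cols")], scaling_mode = sm$mode,
    excluded = sm$excluded, kind = "oplsda"),
    class = "opls_model")
  model$vip <- compute_vip(model)
  if (compute_q2) {
    cv_res <- cross_validate_q2(sm, y, n_ortho = n_ortho, scaling = sm$mode,
                                positive = positive, seed = seed,
                                kind = "oplsda")
    model$q2 <- cv_res$q2
    model$cv <- cv_res
  }
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("%s model: %d predictive + %d orthogonal component(s), %d proteins\n",
              toupper(x$kind), x$n_components, x$n_ortho, nrow(x$W)))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %s\n", x$r2x, x$r2y,
              ifelse(is.na(x$q2), "not computed", sprintf("%.3f", x$q2))))
  invisible(x)
}

#' Predict class scores for new samples
#'
#' Applies the training preprocessing, removes the fitted orthogonal
#' components from the new data, and returns the predicted (uncentered)
#' class value.
#'
#' @param object an `opls_model`.
#' @param newdata samples x proteins matrix on the raw (unscaled) scale of
#'   the training data.
#' @param ... unused.
#' @return Numeric vector of predicted class values (near 1 for the
#'   contrasted class, near 0 otherwise).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xs <- .scale_apply(as.matrix(newdata), object$prep)
  if (object$kind == "oplsda") {
    for (k in seq_len(object$n_ortho)) {
      to <- drop(Xs %*% object$W_ortho[, k])
      Xs <- Xs - tcrossprod(to, object$P_ortho[, k])
    }
    t <- drop(Xs %*% object$W[, 1])
    return(t * object$C + object$y_mean)
  }
  # PLS regression coefficients B = W (P'W)^-1 C
  B <- object$W %*% solve(crossprod(object$P, object$W), object$C)
  drop(Xs %*% B) + object$y_mean
}

#' Variable influence on projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a )`,
#' summed over all components (predictive and orthogonal) and weighted by
#' the Y variance `SSY_a` explained by each; orthogonal components explain
#' (essentially) none and so contribute negligibly. The squared VIPs sum to
#' the number of modeled proteins.
#'
#' @param model an `opls_model`.
#' @return Named non-negative numeric vector, one VIP per modeled protein.
#' @export
compute_vip <- function(model) {
  W <- cbind(model$W, model$W_ortho)
  ssy <- c(model$ssy_components, model$ssy_ortho)
  p <- nrow(W)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  vip <- sqrt(p * drop(Wn^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, rownames(W))
}

#' Seven-fold cross-validated Q2
#'
#' Splits the samples into (by default) seven folds, stratified by class
#' with a venetian-blind assignment of the seed-shuffled samples within
#' each class, refits the model on each 6/7 training set (including the
#' column preprocessing, refitted inside the fold), predicts the held-out
#' samples and accumulates PRESS. `Q2 = 1 - PRESS / SS` where SS is the
#' total sum of squares of the centered class vector.
#'
#' @param X raw samples x proteins matrix or [scale_matrix()] result (its
#'   stored raw matrix is used so fold preprocessing is honest).
#' @param y two-class vector.
#' @param n_ortho orthogonal components (OPLS-DA) — ignored for
#'   `kind = "pls"`.
#' @param n_components predictive components for `kind = "pls"`.
#' @param scaling preprocessing mode refitted inside each fold.
#' @param positive class coded 1.
#' @param n_folds number of folds (7, the chemometrics convention; reduced
#'   to the sample count when fewer samples are available).
#' @param seed integer controlling the fold assignment.
#' @param kind `"oplsda"` or `"pls"`.
#' @return Object of class `cv_result`: `q2`, `fold_assignments`,
#'   `per_fold_press`, `ss_y`.
#' @export
cross_validate_q2 <- function(X, y, n_ortho = 1L, n_components = 2L,
                              scaling = "uv", positive = NULL,
                              n_folds = 7L, seed = 1L,
                              kind = c("oplsda", "pls")) {
  kind <- match.arg(kind)
  Xr <- if (inherits(X, "scaled_matrix")) X$X_raw else as.matrix(X)
  enc <- .encode_y(y, positive)
  n <- nrow(Xr)
  cls <- enc$y01
  if (min(table(cls)) < 2L) stop("need at least 2 samples per class")
  n_folds <- min(n_folds, n)
  folds <- .stratified_folds(cls, n_folds, seed)
  press <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    hold <- folds == f
    fit <- if (kind == "oplsda") {
      fit_oplsda(Xr[!hold, , drop = FALSE], cls[!hold], n_ortho = n_ortho,
                 scaling = scaling, compute_q2 = FALSE)
    } else {
      fit_pls(Xr[!hold, , drop = FALSE], cls[!hold],
              n_components = n_components, scaling = scaling)
    }
    pred <- predict(fit, Xr[hold, , drop = FALSE])
    press[f] <- sum((cls[hold] - pred)^2)
  }
  structure(list(q2 = 1 - sum(press) / sum(enc$yc^2),
                 fold_assignments = folds,
                 per_fold_press = press,
                 ss_y = sum(enc$yc^2)),
            class = "cv_result")
}

# Stratified venetian-blind folds: shuffle within each class by seed, then
# deal samples round-robin so every fold keeps both classes where possible.
.stratified_folds <- function(cls, n_folds, seed) {
  folds <- integer(length(cls))
  rs <- .seeded_rng(seed)
  for (g in unique(cls)) {
    idx <- which(cls == g)
    idx <- idx[.rng_perm(rs, length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  # a fold that lost an entire class is only possible when a class has
  # fewer members than folds; predictions remain defined (training set
  # keeps both classes because folds hold out at most ceil(n_g/n_folds))
  folds
}

# Local RNG so CV fold assignment never disturbs the caller's RNG stream.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  env
}

.rng_perm <- function(rs, n) {
  # linear congruential shuffle: deterministic, isolated from .Random.seed
  s <- rs$state
  keys <- numeric(n)
  for (i in seq_len(n)) {
    s <- (1103515245 * (s %% 65536) + 12345) %% 2147483647
    keys[i] <- s
  }
  rs$state <- s
  order(keys)
}
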