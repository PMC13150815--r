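# NIPALS PLS1 regression, venetian-blinds cross-validation, latent-variable
# selection rules, and model diagnostics (regression vector, VIP scores,
# orthogonalized loadings).

#' Fit a PLS1 regression model (NIPALS)
#'
#' Deterministic NIPALS for a single response: at each latent variable the
#' weight is `w = X'y / |X'y|`, scores `t = Xw`, loadings `p = X't / t't`,
#' `q = y't / t't`, followed by deflation of `X` (and `y`). The regression
#' vector on the centered scale is `beta = W (P'W)^{-1} q`. `X` and `y` are
#' mean-centered internally; the means are stored so prediction uses only
#' training statistics.
#'
#' @param X predictor matrix (rows = samples).
#' @param y numeric response.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(rows - 1, cols)`.
#' @return object of class `pls_model` with fields `n_lv`, `W`, `P`, `q`,
#'   `scores`, `beta` (n_lv columns: the regression vector at 1..n_lv LVs),
#'   `ssy` (explained response sum of squares per LV), `x_mean`, `y_mean`.
#' @export
fit_pls <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`X` and `y` dimensions differ", call. = FALSE)
  if (n_lv < 1 || n_lv > min(n - 1, p)) {
    stop("`n_lv` must be in [1, min(rows - 1, cols)]", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("degenerate response: zero variance", call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean, `-`)
  f <- y - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv); ssy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { # residual X carries no covariance with y; stop early
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]; ssy <- ssy[seq_len(a - 1)]
      n_lv <- a - 1L
      break
    }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_
    q[a] <- q_; ssy[a] <- q_^2 * tt
  }
  if (n_lv == 0) stop("no predictive structure in `X`", call. = FALSE)
  beta <- matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    beta[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  structure(list(n_lv = as.integer(n_lv), W = W, P = P, q = q, scores = Tm,
                 beta = beta, ssy = ssy, x_mean = x_mean, y_mean = y_mean),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors\n",
              x$n_lv, length(x$x_mean)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata predictor matrix.
#' @param n_lv number of latent variables to use (default: all fitted).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = NULL, ...) {
  n_lv <- n_lv %||% object$n_lv
  if (n_lv < 1 || n_lv > object$n_lv) stop("invalid `n_lv`", call. = FALSE)
  Xc <- sweep(as.matrix(newdata), 2, object$x_mean, `-`)
  drop(Xc %*% object$beta[, n_lv]) + object$y_mean
}

#' Extract the regression vector
#'
#' The regression vector on the preprocessed (typically first-derivative)
#' scale, at the model's full number of latent variables.
#'
#' @param model a `pls_model`.
#' @return numeric vector, one entry per predictor.
#' @export
regression_vector <- function(model) {
  model$beta[, model$n_lv]
}

#' Cumulative-sum integration of a derivative-scale vector
#'
#' Regression vectors and loadings computed on first-derivative spectra look
#' derivative-shaped; integrating (cumulative sum along the wavenumber axis,
#' scaled by the point spacing) restores a band-shaped trace for visual
#' comparison.
#'
#' @param v numeric vector on the derivative scale.
#' @param step axis spacing in cm-1 (default 1: plain cumulative sum).
#' @return numeric vector of the same length.
#' @export
integrated_vector <- function(v, step = 1) {
  cumsum(v) * step
}

#' Venetian-blinds cross-validation of a PLS model
#'
#' Systematic interleaving: sample `i` is assigned to fold `((i - 1) mod k) +
#' 1`. For every fold, a model with `max_lv` latent variables is fitted on
#' the remaining samples (mean centering refitted inside the fold) and the
#' held-out samples are predicted at every LV count.
#'
#' @param X predictor matrix.
#' @param y numeric response.
#' @param max_lv maximum number of latent variables to assess.
#' @param k number of folds (default 10), `k <= rows`.
#' @return object of class `cv_result`: `rmsecv` (per-LV), `predictions`
#'   (rows x max_lv matrix of held-out predictions), `folds`, `max_lv`.
#' @export
venetian_cv <- function(X, y, max_lv = 10, k = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("more folds than samples", call. = FALSE)
  folds <- ((seq_len(n) - 1) %% k) + 1
  max_lv <- min(max_lv, min(n - ceiling(n / k) - 1, ncol(X)))
  preds <- matrix(NA_real_, n, max_lv)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- fit_pls(X[!test, , drop = FALSE], y[!test], max_lv)
    for (a in seq_len(fit$n_lv)) {
      preds[test, a] <- predict(fit, X[test, , drop = FALSE], n_lv = a)
    }
    if (fit$n_lv < max_lv) { # early NIPALS stop: carry the last column over
      for (a in seq((fit$n_lv + 1), max_lv)) preds[test, a] <- preds[test, fit$n_lv]
    }
  }
  rmsecv <- apply(preds, 2, function(p_) sqrt(mean((p_ - y)^2)))
  structure(list(rmsecv = rmsecv, predictions = preds, folds = folds,
                 max_lv = max_lv),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d LV(s); min RMSECV %.4g at %d LV\n",
              x$max_lv, min(x$rmsecv), which.min(x$rmsecv)))
  invisible(x)
}

#' Select latent variables at the global RMSECV minimum
#'
#' Ties are broken toward fewer latent variables.
#'
#' @param cv a `cv_result` (or a bare per-LV RMSECV vector).
#' @return integer LV count.
#' @export
select_lv_min <- function(cv) {
  r <- if (inherits(cv, "cv_result")) cv$rmsecv else as.numeric(cv)
  which(r <= min(r))[1]
}

#' Select latent variables by the incremental-improvement rule
#'
#' Starting at 1 LV, the next LV is accepted when it reduces the RMSECV by
#' more than `rel_improvement` (default 10%); while the candidate LV count is
#' at most `floor` (default 5), any reduction at all is accepted. The first
#' rejected LV stops the search.
#'
#' With `floor_mode = "min_lv"` the exception is instead read as a minimum
#' model size: at least `floor` LVs are used (capped at the available LV
#' count), then growth continues only on >10% improvements.
#'
#' @param cv a `cv_result` or per-LV RMSECV vector.
#' @param rel_improvement required relative RMSECV drop, default 0.10.
#' @param floor LV count below which the exception applies, default 5.
#' @param floor_mode `"explore"` (default) or `"min_lv"`.
#' @return integer LV count.
#' @export
select_lv_incremental <- function(cv, rel_improvement = 0.10, floor = 5,
                                  floor_mode = c("explore", "min_lv")) {
  floor_mode <- match.arg(floor_mode)
  r <- if (inherits(cv, "cv_result")) cv$rmsecv else as.numeric(cv)
  n <- length(r)
  k <- 1L
  while (k < n) {
    big_drop <- r[k + 1] < (1 - rel_improvement) * r[k]
    small_drop <- r[k + 1] < r[k]
    accept <- if (floor_mode == "explore") {
      big_drop || (k + 1 <= floor && small_drop)
    } else {
      big_drop || k + 1 <= min(floor, n)
    }
    if (!accept) break
    k <- k + 1L
  }
  k
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP over the PLS weights and per-LV explained response variance:
#' `VIP_j = sqrt( p * sum_a ssy_a (w_ja / |w_a|)^2 / sum_a ssy_a )`, so the
#' mean squared VIP equals 1.
#'
#' @param model a fitted `pls_model`.
#' @return numeric vector, one score per predictor.
#' @export
vip_scores <- function(model) {
  W <- model$W
  wnorm2 <- colSums(W^2)
  ssy <- model$ssy
  p <- nrow(W)
  sqrt(p * drop((W^2 %*% (ssy / wnorm2))) / sum(ssy))
}

#' Orthogonalized loadings
#'
#' Rotates the X-loading basis so that the first vector is the (normalized)
#' projection of the regression vector onto the loading span, and the
#' remaining vectors are orthogonalized against it (Gram-Schmidt). The span
#' of the loadings is preserved; only the basis rotates.
#'
#' @param model a fitted `pls_model`.
#' @return matrix with `n_lv` orthonormal columns, the first aligned with the
#'   predictive direction.
#' @export
orthogonalized_loadings <- function(model) {
  P <- model$P
  beta <- regression_vector(model)
  # projection of beta onto span(P)
  coef <- solve(crossprod(P), crossprod(P, beta))
  v1 <- drop(P %*% coef)
  nv <- sqrt(sum(v1^2))
  if (nv < 1e-300) stop("regression vector has no component in the loading span",
                        call. = FALSE)
  Q <- qr.Q(qr(cbind(v1 / nv, P)))[, seq_len(ncol(P)), drop = FALSE]
  # qr may flip signs; force the first column to align with v1
  if (sum(Q[, 1] * v1) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Root-mean-square error
#' @param pred,ref numeric vectors of equal length.
#' @return `sqrt(mean((pred - ref)^2))`.
#' @export
rmse <- function(pred, ref) sqrt(mean((pred - ref)^2))

#' Coefficient of determination
#' @param pred,ref numeric vectors of equal length.
#' @return `1 - SSE/SST` with SST about the mean of `ref`.
#' @export
r2 <- function(pred, ref) 1 - sum((ref - pred)^2) / sum((ref - mean(ref))^2)
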