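# Multivariate partial least squares regression via the kernel algorithm
# (cross-product based), with leave-one-out cross-validation for component
# selection and jackknife inference on the coefficients.

#' Preprocess a PLSR design
#'
#' Predictors are centered and scaled to unit SD; responses are min-max
#' normalized to \[0, 1\]. All statistics come from `fit_rows` only, so the
#' same transform can be applied to held-out rows without leakage (held-out
#' values outside the training range map outside \[0, 1\] and are not
#' clamped). The transform is invertible.
#'
#' @param X numeric predictor matrix (n x p).
#' @param Y numeric response matrix (n x q).
#' @param fit_rows rows used to estimate the transform (default all).
#' @return A list of class `plsr_preprocess` with the transform parameters
#'   and the transformed `X`, `Y` (all rows, transform from `fit_rows`).
#' @export
plsr_preprocess <- function(X, Y, fit_rows = seq_len(nrow(X))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (length(fit_rows) == 0) stop("`fit_rows` is empty")
  xc <- colMeans(X[fit_rows, , drop = FALSE])
  xs <- apply(X[fit_rows, , drop = FALSE], 2, sd)
  if (any(xs == 0))
    stop(sprintf("zero-variance predictor on fit rows: %s",
                 paste(colnames(X)[xs == 0], collapse = ", ")))
  ymin <- apply(Y[fit_rows, , drop = FALSE], 2, min)
  ymax <- apply(Y[fit_rows, , drop = FALSE], 2, max)
  if (any(ymax == ymin))
    stop(sprintf("constant response on fit rows: %s",
                 paste(colnames(Y)[ymax == ymin], collapse = ", ")))
  Xp <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Yp <- sweep(sweep(Y, 2, ymin), 2, ymax - ymin, "/")
  structure(list(x_center = xc, x_scale = xs, y_min = ymin, y_max = ymax,
                 X = Xp, Y = Yp),
            class = "plsr_preprocess")
}

#' @rdname plsr_preprocess
#' @param pp a `plsr_preprocess` object.
#' @param newX,newY matrices to transform with the stored parameters.
#' @export
apply_preprocess <- function(pp, newX = NULL, newY = NULL) {
  out <- list()
  if (!is.null(newX))
    out$X <- sweep(sweep(as.matrix(newX), 2, pp$x_center), 2, pp$x_scale, "/")
  if (!is.null(newY))
    out$Y <- sweep(sweep(as.matrix(newY), 2, pp$y_min), 2,
                   pp$y_max - pp$y_min, "/")
  out
}

#' @rdname plsr_preprocess
#' @param Yp normalized response matrix to map back to original units.
#' @export
inverse_preprocess_y <- function(pp, Yp) {
  sweep(sweep(as.matrix(Yp), 2, pp$y_max - pp$y_min, "*"), 2, pp$y_min, "+")
}

# Core kernel PLS (Dayal & MacGregor modified kernel algorithm #2):
# everything is computed from the p x p and p x q cross-product matrices,
# so each leave-one-out refit is cheap. Xp/Yp must already be preprocessed
# (Xp centered). Returns weights W, x-loadings P, y-loadings Q, rotation R
# and the per-k coefficient array.
kernel_pls_core <- function(Xp, Yp, k) {
  p <- ncol(Xp); q <- ncol(Yp)
  XtX <- crossprod(Xp)
  XtY <- crossprod(Xp, Yp)
  W <- P <- R <- matrix(0, p, k)
  Q <- matrix(0, q, k)
  tt <- numeric(k)
  for (a in seq_len(k)) {
    if (q == 1) {
      w <- XtY[, 1]
    } else {
      ev <- eigen(crossprod(XtY), symmetric = TRUE)
      w <- as.vector(XtY %*% ev$vectors[, 1])
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # no covariance left; truncate
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      R <- R[, seq_len(a - 1), drop = FALSE]
      Q <- Q[, seq_len(a - 1), drop = FALSE]
      tt <- tt[seq_len(a - 1)]
      k <- a - 1L
      break
    }
    w <- w / nw
    r <- w
    if (a > 1)
      r <- r - R[, 1:(a - 1), drop = FALSE] %*%
        crossprod(P[, 1:(a - 1), drop = FALSE], w)
    XtXr <- XtX %*% r
    tta <- drop(crossprod(r, XtXr))
    pa <- XtXr / tta
    qa <- crossprod(XtY, r) / tta
    XtY <- XtY - XtXr %*% t(qa)
    W[, a] <- w; P[, a] <- pa; R[, a] <- r; Q[, a] <- qa; tt[a] <- tta
  }
  list(W = W, P = P, R = R, Q = Q, tt = tt, k = k)
}

#' Fit a multivariate PLSR model with the kernel algorithm
#'
#' Fits `k` latent components by the cross-product (kernel) PLS algorithm.
#' By default the design is preprocessed first ([plsr_preprocess()]); pass
#' `preprocess = FALSE` for matrices that are already centered/scaled and
#' min-max normalized.
#'
#' @param X predictor matrix (n x p).
#' @param Y response matrix (n x q).
#' @param k number of components, `1 <= k <= rank of centered X`.
#' @param preprocess apply [plsr_preprocess()] internally (default TRUE).
#' @return An object of class `plsr_model`: component count `k`, transform
#'   parameters, weight (`W`), x-loading (`P`), rotation (`R`) and
#'   y-loading (`Q`) matrices, scores `T`, and `beta` (p x q, on the
#'   preprocessed scales).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4)
#' Y <- cbind(X %*% c(1, -1, 0, 0.5) + rnorm(50, sd = 0.1))
#' fit <- fit_kernel_plsr(X, Y, k = 2)
#' fit$k
#' @export
fit_kernel_plsr <- function(X, Y, k, preprocess = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  pp <- NULL
  if (preprocess) {
    pp <- plsr_preprocess(X, Y)
    Xp <- pp$X; Yp <- pp$Y
  } else {
    Xp <- X; Yp <- Y
  }
  rk <- qr(sweep(Xp, 2, colMeans(Xp)))$rank
  if (k < 1 || k > rk)
    stop(sprintf("k = %d outside 1..rank(X) = %d", k, rk))
  core <- kernel_pls_core(Xp, Yp, k)
  beta <- core$R %*% t(core$Q)
  dimnames(beta) <- list(colnames(X), colnames(Y))
  scores <- Xp %*% core$R
  # X is centered, Y only min-max normalized: predictions need the
  # training-mean response offset
  intercept <- colMeans(Yp) - drop(crossprod(colMeans(Xp), beta))
  structure(list(k = core$k, preprocess = pp,
                 W = core$W, P = core$P, R = core$R, Q = core$Q,
                 scores = scores, beta = beta, intercept = intercept,
                 x_names = colnames(X), y_names = colnames(Y)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s), %d predictor(s) -> %d response(s)\n",
              x$k, nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata predictor matrix on the original scale (or preprocessed if
#'   the model was fitted with `preprocess = FALSE`).
#' @param scale return predictions on the `"response"` (original) or
#'   `"normalized"` \[0, 1\] scale.
#' @param ... unused.
#' @return Matrix of predictions (n x q).
#' @export
predict.plsr_model <- function(object, newdata,
                               scale = c("response", "normalized"), ...) {
  scale <- match.arg(scale)
  newdata <- as.matrix(newdata)
  if (!is.null(object$preprocess)) {
    Xp <- apply_preprocess(object$preprocess, newX = newdata)$X
  } else Xp <- newdata
  Yp <- sweep(Xp %*% object$beta, 2, object$intercept, "+")
  if (scale == "normalized" || is.null(object$preprocess)) return(Yp)
  inverse_preprocess_y(object$preprocess, Yp)
}

# betas for every k in 1..k_max from one core decomposition
beta_per_k <- function(core) {
  lapply(seq_len(core$k), function(a)
    core$R[, 1:a, drop = FALSE] %*% t(core$Q[, 1:a, drop = FALSE]))
}

#' Leave-one-out cross-validation for PLSR component selection
#'
#' For each held-out row the preprocessing and the model are re-estimated
#' on the remaining rows (no information leaks from the held-out subject),
#' the row is predicted, and the per-component, per-response RMSE is
#' accumulated on the normalized response scale. The chosen component count
#' minimizes the response-averaged RMSE, with ties going to the smaller k:
#' two component counts whose RMSE differ by less than `tol` (relative, at
#' the fourth significant digit by default) are treated as tied, since
#' differences at that level are CV noise, not model structure.
#'
#' @param X predictor matrix (n x p), original scale.
#' @param Y response matrix (n x q), original scale.
#' @param k_max largest component count to evaluate.
#' @param tol relative RMSE tolerance within which component counts count
#'   as tied (default 0.001).
#' @return An object of class `plsr_cv`: `rmse` (k_max x q matrix),
#'   `rmse_avg`, `chosen_k`.
#' @export
loo_cv <- function(X, Y, k_max, tol = 0.001) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out CV needs n >= 3")
  q <- ncol(Y)
  se_acc <- matrix(0, k_max, q) # accumulated squared errors
  n_eff <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      pp <- plsr_preprocess(X, Y, fit_rows = setdiff(seq_len(n), i))
      core <- kernel_pls_core(pp$X[-i, , drop = FALSE],
                              pp$Y[-i, , drop = FALSE], k_max)
      if (core$k < k_max)
        stop(sprintf("rank ran out at %d components", core$k))
      betas <- beta_per_k(core)
      xm <- colMeans(pp$X[-i, , drop = FALSE])
      ym <- colMeans(pp$Y[-i, , drop = FALSE])
      xh <- pp$X[i, , drop = FALSE]
      yh <- pp$Y[i, , drop = FALSE]
      t(vapply(betas, function(b)
        as.numeric(ym + (xh - xm) %*% b - yh), numeric(q)))
    }, error = function(e)
      stop(sprintf("LOO fold %d: %s", i, conditionMessage(e)), call. = FALSE))
    se_acc <- se_acc + if (q == 1) matrix(res^2, k_max, 1) else res^2
    n_eff <- n_eff + 1L
  }
  rmse <- sqrt(se_acc / n_eff)
  colnames(rmse) <- colnames(Y)
  rmse_avg <- rowMeans(rmse)
  # smallest k within the tie tolerance of the global minimum
  chosen_k <- which(rmse_avg <= min(rmse_avg) * (1 + tol))[1]
  structure(list(rmse = rmse, rmse_avg = rmse_avg,
                 chosen_k = as.integer(chosen_k), k_max = k_max, n = n),
            class = "plsr_cv")
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("<plsr_cv> n = %d, k_max = %d, chosen k = %d (avg RMSE %.4f)\n",
              x$n, x$k_max, x$chosen_k, x$rmse_avg[x$chosen_k]))
  invisible(x)
}

#' Jackknife inference for PLSR coefficients
#'
#' Re-fits preprocessing and model on each leave-one-out subsample. Because
#' the min-max / SD transforms differ per subsample, each subsample's beta
#' is first mapped to the raw scale (response units per predictor unit),
#' where betas are comparable; the jackknife variance uses the Tukey
#' (n-1)/n factor, and two-sided p-values come from a t reference with
#' n - 1 degrees of freedom. Reported `beta` stays on the full-fit
#' preprocessed scale, as in the model tables.
#'
#' @param X predictor matrix (n x p), original scale, n >= 10.
#' @param Y response matrix (n x q), original scale.
#' @param k number of components.
#' @return An object of class `plsr_jackknife` with matrices `beta`
#'   (preprocessed scale), `beta_raw`, `se` (raw scale), `t`, `p`, and
#'   logical `sig05` / `sig01` marks.
#' @export
jackknife_pvalues <- function(X, Y, k) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10) stop("jackknife inference needs n >= 10")
  full <- fit_kernel_plsr(X, Y, k)
  pp <- full$preprocess
  to_raw <- function(beta, pp)
    sweep(sweep(beta, 2, pp$y_max - pp$y_min, "*"), 1, pp$x_scale, "/")
  beta_full_raw <- to_raw(full$beta, pp)
  p <- nrow(full$beta); q <- ncol(full$beta)
  boots <- array(0, c(p, q, n))
  for (i in seq_len(n)) {
    ppi <- plsr_preprocess(X, Y, fit_rows = setdiff(seq_len(n), i))
    core <- kernel_pls_core(ppi$X[-i, , drop = FALSE],
                            ppi$Y[-i, , drop = FALSE], k)
    if (core$k < k)
      stop(sprintf("jackknife fold %d: rank ran out at %d components", i, core$k))
    boots[, , i] <- to_raw(core$R %*% t(core$Q), ppi)
  }
  bmean <- apply(boots, c(1, 2), mean)
  v <- apply(sweep(boots, c(1, 2), bmean)^2, c(1, 2), sum) * (n - 1) / n
  se <- sqrt(v)
  tstat <- beta_full_raw / se
  zero_se <- se == 0
  if (any(zero_se & beta_full_raw != 0)) {
    warning("zero jackknife variance with nonzero beta: p reported at ",
            "the machine floor")
  }
  pval <- 2 * pt(-abs(tstat), df = n - 1)
  pval[zero_se & beta_full_raw != 0] <- .Machine$double.xmin
  pval[zero_se & beta_full_raw == 0] <- 1
  dn <- dimnames(full$beta)
  dimnames(beta_full_raw) <- dimnames(se) <- dimnames(tstat) <-
    dimnames(pval) <- dn
  structure(list(beta = full$beta, beta_raw = beta_full_raw, se = se,
                 t = tstat, p = pval,
                 sig05 = pval < 0.05, sig01 = pval < 0.01,
                 k = k, n = n),
            class = "plsr_jackknife")
}

#' @export
print.plsr_jackknife <- function(x, ...) {
  cat(sprintf("<plsr_jackknife> n = %d, k = %d; %d/%d cells p < 0.05\n",
              x$n, x$k, sum(x$sig05), length(x$sig05)))
  invisible(x)
}
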