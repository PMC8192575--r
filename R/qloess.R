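# Quantile LOESS: locally weighted linear quantile regression, used for
# sex-specific normative 25th/50th/75th percentile curves of each artery
# measurement over age.

# smoothed pinball (check) loss and gradient; eps controls the smoothing
softplus <- function(t) ifelse(t > 30, t, log1p(exp(pmin(t, 30))))

#' Quantile LOESS curves
#'
#' At each evaluation grid point, a local linear fit minimizes the
#' tricube-weighted pinball (check) loss for each requested quantile over
#' the `span`-nearest neighbours, giving smooth conditional quantile
#' curves. The pinball loss is minimized through a lightly smoothed version
#' of the check function (analytic gradient, warm start at the weighted
#' least-squares fit), which leaves the median exact and perturbs the outer
#' quantiles by O(smoothing). Monotonicity across quantiles is enforced by
#' re-sorting the fitted values at each grid point, so curves never cross.
#' Grid points whose window holds fewer than 5 observations yield `NA`.
#'
#' @param x numeric covariate (e.g. age in years), at least 30 points.
#' @param y numeric measurement.
#' @param quantiles quantile levels (default 25th, 50th, 75th).
#' @param span fraction of points in each local window, in (0, 1].
#' @param grid evaluation points (default 100 equispaced over the observed
#'   x range).
#' @return data.frame with column `x` and one column `q<level>` per
#'   quantile (e.g. `q25`, `q50`, `q75`).
#' @export
quantile_loess <- function(x, y, quantiles = c(0.25, 0.5, 0.75),
                           span = 0.75, grid = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 30) stop("quantile LOESS needs at least 30 points")
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")
  if (any(quantiles <= 0 | quantiles >= 1)) stop("quantiles must be in (0, 1)")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)
  m <- max(2L, ceiling(span * n))
  eps <- 1e-6 * max(stats::mad(y), sd(y), 1e-12)

  fit_one <- function(g, tau) {
    d <- abs(x - g)
    idx <- order(d)[seq_len(min(m, n))]
    if (length(idx) < 5) return(NA_real_)
    h <- max(d[idx])
    w <- if (h == 0) rep(1, length(idx)) else (1 - pmin(1, d[idx] / h)^3)^3
    w[w <= 0] <- 1e-8
    xi <- x[idx] - g
    yi <- y[idx]
    # warm start: weighted least squares
    X <- cbind(1, xi)
    ab <- tryCatch(drop(solve(crossprod(X, w * X), crossprod(X, w * yi))),
                   error = function(e) c(stats::weighted.mean(yi, w), 0))
    loss <- function(par) {
      r <- yi - par[1] - par[2] * xi
      sum(w * (tau * r + eps * softplus(-r / eps)))
    }
    grad <- function(par) {
      r <- yi - par[1] - par[2] * xi
      dr <- -(tau - stats::plogis(-r / eps))
      c(sum(w * dr), sum(w * dr * xi))
    }
    res <- optim(ab, loss, grad, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12))
    res$par[1]
  }

  curves <- vapply(quantiles, function(tau)
    vapply(grid, fit_one, numeric(1), tau = tau), numeric(length(grid)))
  curves <- matrix(curves, nrow = length(grid))
  # non-crossing: isotonic re-sorting per grid point in quantile order
  ord <- order(quantiles)
  curves[, ord] <- t(apply(curves[, ord, drop = FALSE], 1,
                           function(r) if (anyNA(r)) r else sort(r)))
  out <- data.frame(x = grid)
  for (j in seq_along(quantiles))
    out[[sprintf("q%02d", round(100 * quantiles[j]))]] <- curves[, j]
  out
}

#' Sex-specific normative curves for one measurement
#'
#' Convenience wrapper running [quantile_loess()] of a measurement against
#' age separately within each level of a grouping column (default sex).
#'
#' @param data cohort data.frame.
#' @param response measurement column name.
#' @param by grouping column (default `"sex"`).
#' @param age_col age column (default `"age"`).
#' @param ... passed to [quantile_loess()].
#' @return data.frame of stacked curves with a `group` column.
#' @export
normative_curves <- function(data, response, by = "sex", age_col = "age",
                             ...) {
  parts <- lapply(split(data, data[[by]]), function(d) {
    cur <- quantile_loess(d[[age_col]], d[[response]], ...)
    cur$group <- d[[by]][1]
    cur
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$response <- response
  out
}
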