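random_problem <- function(seed, n = 60, p = 5, q = 3, noise = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * q), p, q)
  Y <- X %*% B + matrix(rnorm(n * q, sd = noise), n, q)
  list(X = X, Y = Y, B = B)
}

test_that("preprocessing centers/scales X, min-max normalizes Y, and round-trips", {
  pr <- random_problem(1)
  pp <- plsr_preprocess(pr$X, pr$Y)
  expect_equal(colMeans(pp$X), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(pp$X, 2, sd), rep(1, 5), tolerance = 1e-12)
  expect_equal(apply(pp$Y, 2, min), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(pp$Y, 2, max), rep(1, 3), tolerance = 1e-12)
  expect_equal(inverse_preprocess_y(pp, pp$Y), unname(pr$Y),
               tolerance = 1e-12)
  # transform estimated on a subset: held-out rows may leave [0, 1]
  pp2 <- plsr_preprocess(pr$X, pr$Y, fit_rows = 1:30)
  expect_true(any(pp2$Y[31:60, ] > 1 | pp2$Y[31:60, ] < 0))
  # zero-variance predictor is named
  Xc <- pr$X; Xc[, 2] <- 7; colnames(Xc) <- paste0("v", 1:5)
  expect_error(plsr_preprocess(Xc, pr$Y), "v2")
})

test_that("kernel PLSR at full rank reproduces least squares", {
  for (seed in 1:10) {
    pr <- random_problem(seed)
    fit <- fit_kernel_plsr(pr$X, pr$Y, k = 5)
    ols <- lm(pr$Y ~ pr$X)
    expect_lt(max(abs(predict(fit, pr$X) - fitted(ols))), 1e-8)
  }
})

test_that("kernel betas agree with an independent NIPALS implementation", {
  for (seed in 1:8) {
    pr <- random_problem(seed, n = 40, p = 6, q = 4)
    pp <- plsr_preprocess(pr$X, pr$Y)
    for (k in c(1, 3)) {
      kfit <- fit_kernel_plsr(pp$X, pp$Y, k = k, preprocess = FALSE)
      nfit <- nipals_pls(pp$X, pp$Y, k = k)
      expect_lt(max(abs(kfit$beta - nfit$beta)), 1e-6)
    }
  }
})

test_that("single-predictor single-response k=1 beta is the regression slope", {
  set.seed(3)
  x <- matrix(rnorm(50), 50, 1)
  y <- matrix(2.5 * x + rnorm(50, sd = 0.3), 50, 1)
  pp <- plsr_preprocess(x, y)
  fit <- fit_kernel_plsr(pp$X, pp$Y, k = 1, preprocess = FALSE)
  slope <- coef(lm(pp$Y ~ pp$X))[2]
  expect_equal(unname(fit$beta[1, 1]), unname(slope), tolerance = 1e-10)
})

test_that("responses orthogonal to the predictors give zero betas", {
  set.seed(4)
  X <- matrix(rnorm(200), 50, 4)
  raw <- matrix(rnorm(100), 50, 2)
  Y <- raw - cbind(1, X) %*% solve(crossprod(cbind(1, X)),
                                   crossprod(cbind(1, X), raw))
  Xp <- scale(X)
  fit <- fit_kernel_plsr(Xp, Y, k = 3, preprocess = FALSE)
  expect_lt(max(abs(fit$beta)), 1e-10)
})

test_that("k beyond the rank of X is rejected", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  X <- cbind(X, X[, 1] + X[, 2]) # rank 3
  Y <- matrix(rnorm(20), 20, 1)
  expect_error(fit_kernel_plsr(X, Y, k = 4), "rank")
})

test_that("scores are orthogonal and residuals orthogonal to scores", {
  pr <- random_problem(6)
  fit <- fit_kernel_plsr(pr$X, pr$Y, k = 4)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  resid <- fit$preprocess$Y - sweep(fit$preprocess$X %*% fit$beta, 2,
                                    fit$intercept, "+")
  expect_lt(max(abs(crossprod(fit$scores, resid))), 1e-8)
})

test_that("LOO CV: noiseless linear responses reach ~zero RMSE at full rank", {
  set.seed(7)
  X <- matrix(rnorm(40 * 4), 40, 4)
  Y <- X %*% matrix(rnorm(8), 4, 2)
  cv <- loo_cv(X, Y, 4)
  expect_lt(cv$rmse_avg[4], 1e-8)
  expect_equal(cv$chosen_k, 4L)
})

test_that("LOO CV is invariant to row order", {
  pr <- random_problem(8, n = 30)
  cv1 <- loo_cv(pr$X, pr$Y, 3)
  set.seed(9)
  ord <- sample(30)
  cv2 <- loo_cv(pr$X[ord, ], pr$Y[ord, ], 3)
  expect_equal(cv1$rmse, cv2$rmse, tolerance = 1e-12)
  expect_equal(cv1$chosen_k, cv2$chosen_k)
})

test_that("pure-noise responses choose few components and RMSE near the noise scale", {
  chosen <- integer(10)
  ratio <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 150
    X <- matrix(rnorm(n * 5), n, 5)
    Y <- matrix(rnorm(n), n, 1)
    cv <- loo_cv(X, Y, 5)
    chosen[s] <- cv$chosen_k
    # RMSE on the normalized scale vs the normalized noise SD
    ratio[s] <- cv$rmse_avg[cv$chosen_k] / (sd(Y) / diff(range(Y)))
  }
  expect_gte(mean(chosen == 1), 0.5)
  expect_lte(mean(chosen), 2.5)
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("jackknife betas are stable under row duplication and variances finite", {
  pr <- random_problem(10, n = 40, p = 4, q = 2, noise = 0.3)
  j1 <- jackknife_pvalues(pr$X, pr$Y, 2)
  Xd <- rbind(pr$X, pr$X[1, , drop = FALSE])
  Yd <- rbind(pr$Y, pr$Y[1, , drop = FALSE])
  j2 <- jackknife_pvalues(Xd, Yd, 2)
  expect_lt(max(abs(j1$beta_raw - j2$beta_raw)) /
              max(abs(j1$beta_raw)), 0.1)
  expect_true(all(is.finite(j2$se)))
})

test_that("a strong effect is detected while null predictors stay calm", {
  set.seed(11)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  y <- 2 * X[, 2] + rnorm(n, sd = 0.5)
  j <- jackknife_pvalues(X, matrix(y), 3)
  expect_lt(j$p[2, 1], 0.01)
  expect_gt(min(j$p[-2, 1]), 0.001) # nulls not wildly anti-conservative
})
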