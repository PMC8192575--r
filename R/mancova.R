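# Group comparison of the regional artery measurements between carriers
# and non-carriers of the fetal-PCA variant: MANCOVA (Wilks' lambda with
# age and sex as covariates), Bonferroni-corrected per-response ANCOVA
# post-hoc tests, and covariate-adjusted group means.

#' MANCOVA of regional measurements against a group factor
#'
#' Tests the group factor (e.g. fetal-PCA carrier yes/no) on the
#' multivariate response after adjusting for covariates: Wilks' lambda
#' with Rao's F approximation, the factor entered after the covariates.
#' Post-hoc, each response gets a univariate ANCOVA with the same
#' covariates; group p-values are Bonferroni-multiplied by `bonferroni_n`
#' (capped at 1) and a response is flagged significant when its raw p-value
#' is below `0.05 / bonferroni_n`. Rows with missing values are dropped
#' listwise.
#'
#' @param data data.frame holding responses, group and covariates.
#' @param responses character vector of response column names.
#' @param group name of the two-level group column.
#' @param covariates names of covariate columns (default age and sex).
#' @param bonferroni_n Bonferroni multiplier; fixed at 24 (the number of
#'   regional measurements) regardless of how many responses are tested.
#' @return An object of class `mancova_result`: `wilks` (lambda, approx F,
#'   dfs, p), `posthoc` data.frame (p_raw, p_bonferroni, significant,
#'   per-group adjusted means and SEs), `n`, `groups`.
#' @export
vessel_mancova <- function(data, responses, group = "fetal_pca",
                           covariates = c("age", "sex"),
                           bonferroni_n = 24) {
  cols <- c(responses, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  gf <- factor(d[[group]])
  if (nlevels(gf) != 2 || any(table(gf) == 0))
    stop("`group` must have exactly two nonempty levels")
  q <- length(responses)
  n <- nrow(d)
  if (n <= q + 3)
    stop(sprintf("n = %d too small for %d responses (need n > q + 3)", n, q))
  d$.group <- gf
  Ymat <- as.matrix(d[, responses, drop = FALSE])
  rhs <- paste(c(covariates, ".group"), collapse = " + ")

  if (q >= 2) {
    fit <- tryCatch(
      manova(stats::as.formula(paste("Ymat ~", rhs)), data = d),
      error = function(e) stop("MANCOVA fit failed (", conditionMessage(e),
                               "); consider reducing the response set"))
    sm <- tryCatch(summary(fit, test = "Wilks"),
                   error = function(e) stop(
                     "singular within-group covariance (",
                     conditionMessage(e),
                     "); consider reducing the response set"))
    st <- sm$stats[".group", ]
    wilks <- list(lambda = unname(st["Wilks"]),
                  f = unname(st["approx F"]),
                  df1 = unname(st["num Df"]), df2 = unname(st["den Df"]),
                  p = unname(st["Pr(>F)"]))
  } else {
    # single response: MANCOVA reduces to the ANCOVA F-test
    fit1 <- lm(stats::as.formula(paste(responses, "~", rhs)), data = d)
    an <- anova(fit1)
    f <- an[".group", "F value"]
    df1 <- an[".group", "Df"]; df2 <- an["Residuals", "Df"]
    wilks <- list(lambda = unname(1 / (1 + f * df1 / df2)), f = unname(f),
                  df1 = unname(df1), df2 = unname(df2),
                  p = unname(an[".group", "Pr(>F)"]))
  }

  post <- lapply(responses, function(r) {
    fit1 <- lm(stats::as.formula(paste("`", r, "` ~ ", rhs, sep = "")),
               data = d)
    an <- anova(fit1)
    p_raw <- an[".group", "Pr(>F)"]
    adj <- adjusted_group_means(d, r, ".group", covariates)
    data.frame(response = r, p_raw = p_raw,
               p_bonferroni = min(1, p_raw * bonferroni_n),
               significant = p_raw < 0.05 / bonferroni_n,
               mean_g1 = adj$mean[1], se_g1 = adj$se[1],
               mean_g2 = adj$mean[2], se_g2 = adj$se[2])
  })
  post <- do.call(rbind, post)
  rownames(post) <- NULL
  structure(list(wilks = wilks, posthoc = post, n = n,
                 groups = levels(gf), bonferroni_n = bonferroni_n,
                 covariates = covariates),
            class = "mancova_result")
}

#' @export
print.mancova_result <- function(x, ...) {
  cat(sprintf(
    "<mancova_result> n = %d, groups %s vs %s\n  Wilks lambda = %.4f, F(%g, %g) = %.3f, p = %.3g\n",
    x$n, x$groups[1], x$groups[2], x$wilks$lambda, x$wilks$df1, x$wilks$df2,
    x$wilks$f, x$wilks$p))
  sig <- x$posthoc$response[x$posthoc$significant]
  cat(sprintf("  post-hoc significant (raw p < 0.05/%d): %s\n",
              x$bonferroni_n,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Covariate-adjusted group means
#'
#' Least-squares means: each group's fitted response at the sample means of
#' the covariates, with standard errors from the coefficient covariance.
#' With covariates balanced across groups these equal the raw group means.
#'
#' @param data data.frame with the response, group and covariates.
#' @param response response column name.
#' @param group group column name (two-level factor or coercible).
#' @param covariates covariate column names.
#' @return data.frame with one row per group level: `group`, `mean`, `se`.
#' @export
adjusted_group_means <- function(data, response, group,
                                 covariates = c("age", "sex")) {
  d <- data[stats::complete.cases(data[, c(response, group, covariates)]),
            , drop = FALSE]
  gf <- factor(d[[group]])
  d$.g <- gf
  rhs <- paste(c(covariates, ".g"), collapse = " + ")
  fit <- lm(stats::as.formula(paste("`", response, "` ~ ", rhs, sep = "")),
            data = d)
  newd <- do.call(rbind, lapply(levels(gf), function(g) {
    row <- as.data.frame(lapply(d[, covariates, drop = FALSE], mean))
    row$.g <- g
    row
  }))
  newd$.g <- factor(newd$.g, levels = levels(gf))
  Xn <- model.matrix(stats::delete.response(stats::terms(fit)), newd)
  est <- drop(Xn %*% coef(fit))
  se <- sqrt(rowSums((Xn %*% vcov(fit)) * Xn))
  data.frame(group = levels(gf), mean = est, se = se)
}
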