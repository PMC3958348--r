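#' Ordinary least squares with classical inference
#'
#' Complete-case least squares of \code{y} on an intercept, the focal
#' predictor and optional covariates, with classical homoskedastic standard
#' errors and t-based p-values and 95\% confidence intervals.
#'
#' @param y numeric outcome.
#' @param x numeric focal predictor.
#' @param covariates optional numeric vector/matrix.
#'
#' @return A \linkS4class{RegressionResult}.
#' @examples
#' fit <- olsFit(c(1, 3, 5), c(0, 1, 2))
#' estimate(fit)
#' @export
olsFit <- function(y, x, covariates = NULL) {
  X <- designMatrix(length(y), x = x, covariates = covariates)
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X)) stop("too few complete cases")
  fit <- lsSolve(X, y)
  sigma2 <- fit$rss / fit$df
  se <- sqrt(sigma2 * diag(fit$XtXinv))
  tval <- fit$coef / se
  p <- 2 * pt(-abs(tval), fit$df)
  tcrit <- qt(0.975, fit$df)
  tss <- sum((y - mean(y))^2)
  new("RegressionResult", coef = fit$coef, se = se, p = p,
      ci_low = fit$coef - tcrit * se, ci_high = fit$coef + tcrit * se,
      n = as.integer(n), sigma2 = sigma2,
      r2 = if (tss > 0) 1 - fit$rss / tss else NA_real_,
      df = fit$df, family = "gaussian")
}

#' Logistic regression (maximum likelihood via IRLS)
#'
#' Binomial logit fit through \code{stats::glm} with convergence tolerance
#' 1e-8 and at most 50 iterations. Perfect separation is detected via
#' diverging coefficients and raised as an error. Normal-theory (Wald)
#' inference; exponentiate coefficients for odds ratios.
#'
#' @param y binary (0/1) outcome; both classes must be present.
#' @param x focal predictor.
#' @param covariates optional covariates.
#' @param or_scale if TRUE, return coefficients/CIs as odds ratios.
#'
#' @return A \linkS4class{RegressionResult}.
#' @export
logisticFit <- function(y, x, covariates = NULL, or_scale = FALSE) {
  X <- designMatrix(length(y), x = x, covariates = covariates)
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 50L)))
  cf <- fit$coefficients
  if (any(abs(cf[-1L]) > 15) || !fit$converged)
    stop("perfect separation (diverging coefficients) or non-convergence")
  # Wald covariance from the final IRLS weights
  W <- fit$weights
  XtWXinv <- chol2inv(chol(crossprod(X * sqrt(W))))
  se <- sqrt(diag(XtWXinv))
  names(se) <- names(cf)
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  lo <- cf - qnorm(0.975) * se
  hi <- cf + qnorm(0.975) * se
  if (or_scale) { cf <- exp(cf); lo <- exp(lo); hi <- exp(hi) }
  new("RegressionResult", coef = cf, se = se, p = p, ci_low = lo,
      ci_high = hi, n = as.integer(length(y)), sigma2 = NA_real_,
      r2 = NA_real_, df = length(y) - ncol(X), family = "binomial")
}

#' @importFrom stats glm.fit
NULL

#' Two-stage least squares instrumental-variable estimation
#'
#' Stage 1 regresses the exposure on the instrument(s) and covariates; stage
#' 2 regresses the outcome on the fitted exposure and covariates. Standard
#' errors use the structural residuals \eqn{y - x\beta - W\gamma} (not the
#' second-stage residuals), with normal-theory confidence intervals and
#' p-values (large-sample IV inference). First-stage diagnostics (nested F
#' and partial R-squared) and the Durbin form of the Durbin-Wu-Hausman
#' endogeneity test are filled in.
#'
#' @param y numeric outcome.
#' @param x numeric exposure (single endogenous regressor).
#' @param z numeric instrument vector or matrix (>= 1 column).
#' @param covariates optional covariates.
#' @param instrument_label label recorded in the result.
#'
#' @return An \linkS4class{IVFitResult}.
#' @examples
#' set.seed(1)
#' z <- rnorm(500); x <- 0.5 * z + rnorm(500); y <- 0.3 * x + rnorm(500)
#' tslsFit(y, x, z)
#' @export
tslsFit <- function(y, x, z, covariates = NULL,
                    instrument_label = "instrument") {
  z <- as.matrix(z)
  X <- designMatrix(length(y), x = x, covariates = covariates)
  keep <- !is.na(y) & complete.cases(X) & complete.cases(z)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  z <- z[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + ncol(z) + 2L) stop("too few complete cases")
  W <- X[, colnames(X) != "x", drop = FALSE]   # intercept + covariates
  xv <- X[, "x"]
  Zfull <- cbind(W, z)
  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull))
    stop("instrument collinear with covariates")
  xhat <- qr.fitted(qz, xv)
  Shat <- X
  Shat[, "x"] <- xhat
  fit2 <- lsSolve(Shat, y)
  beta <- fit2$coef
  # structural residuals with the observed (not fitted) exposure
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (n - ncol(X))
  se <- sqrt(sigma2 * diag(fit2$XtXinv))
  b <- beta[["x"]]
  sb <- se[["x"]]
  zc <- qnorm(0.975)
  diag1 <- firstStageDiagnostics(xv, z, covariates = W[, -1L, drop = FALSE])
  dwh <- durbinWuHausman(y, xv, z, covariates = W[, -1L, drop = FALSE])
  new("IVFitResult", beta = b, se = sb, ci_low = b - zc * sb,
      ci_high = b + zc * sb, p = 2 * pnorm(-abs(b / sb)),
      first_stage_F = diag1[["F"]], partial_r2 = diag1[["partial_r2"]],
      dwh_statistic = dwh[["statistic"]], dwh_p = dwh[["p"]],
      n = as.integer(n), instrument = instrument_label)
}

#' First-stage instrument-strength diagnostics
#'
#' Compares first-stage fits of the exposure with and without the
#' instrument(s): partial R-squared is (RSS_reduced - RSS_full)/RSS_reduced
#' and F is the nested-model statistic
#' [(RSS_r - RSS_f)/q] / [RSS_f/(n - k_f)] with q instruments.
#'
#' @param x exposure; @param z instrument vector/matrix;
#' @param covariates optional covariates.
#' @return named numeric: F, partial_r2.
#' @export
firstStageDiagnostics <- function(x, z, covariates = NULL) {
  z <- as.matrix(z)
  W <- designMatrix(length(x), covariates = covariates)
  keep <- !is.na(x) & complete.cases(W) & complete.cases(z)
  x <- x[keep]; W <- W[keep, , drop = FALSE]; z <- z[keep, , drop = FALSE]
  reduced <- lsSolve(W, x)
  full <- lsSolve(cbind(W, z), x)
  q <- ncol(z)
  Fstat <- ((reduced$rss - full$rss) / q) / (full$rss / full$df)
  c(F = max(Fstat, 0), partial_r2 = (reduced$rss - full$rss) / reduced$rss)
}

#' Durbin-Wu-Hausman endogeneity test (Durbin / control-function form)
#'
#' Augments the outcome regression with the first-stage residual: regress
#' the exposure on instrument(s) and covariates, keep the residual, then
#' regress the outcome on exposure, covariates and that residual. The test
#' statistic is the squared t of the residual's coefficient, referred to
#' chi-squared with 1 df.
#'
#' @inheritParams tslsFit
#' @return named numeric: statistic, p. Both are NA when the instrument
#'   reproduces the exposure exactly (zero first-stage residual), where the
#'   test is undefined.
#' @export
durbinWuHausman <- function(y, x, z, covariates = NULL) {
  z <- as.matrix(z)
  X <- designMatrix(length(y), x = x, covariates = covariates)
  keep <- !is.na(y) & complete.cases(X) & complete.cases(z)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; z <- z[keep, , drop = FALSE]
  W <- X[, colnames(X) != "x", drop = FALSE]
  xv <- X[, "x"]
  v <- lsSolve(cbind(W, z), xv)$residuals
  # perfect instrument: zero first-stage residual carries no endogeneity
  # information and would make the augmented design singular
  if (sum(v^2) <= 1e-10 * max(sum(xv^2), 1))
    return(c(statistic = NA_real_, p = NA_real_))
  aug <- cbind(X, vhat = v)
  fit <- lsSolve(aug, y)
  sigma2 <- fit$rss / fit$df
  tstat <- fit$coef[["vhat"]] / sqrt(sigma2 * fit$XtXinv["vhat", "vhat"])
  stat <- tstat^2
  c(statistic = stat, p = pchisq(stat, 1L, lower.tail = FALSE))
}

## ---- accessors and show methods ----

#' @rdname estimate
setMethod("estimate", "RegressionResult", function(x) x@coef)
#' @rdname stdError
setMethod("stdError", "RegressionResult", function(x) x@se)
#' @rdname pValue
setMethod("pValue", "RegressionResult", function(x) x@p)
#' @rdname confInt
setMethod("confInt", "RegressionResult", function(x)
  cbind(low = x@ci_low, high = x@ci_high))

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult (%s), n = %d\n", object@family, object@n))
  print(data.frame(estimate = object@coef, se = object@se,
                   ci_low = object@ci_low, ci_high = object@ci_high,
                   p = object@p))
})

#' @rdname estimate
setMethod("estimate", "IVFitResult", function(x) x@beta)
#' @rdname stdError
setMethod("stdError", "IVFitResult", function(x) x@se)
#' @rdname pValue
setMethod("pValue", "IVFitResult", function(x) x@p)
#' @rdname confInt
setMethod("confInt", "IVFitResult", function(x)
  c(low = x@ci_low, high = x@ci_high))
#' @rdname IVFitResult-class
setMethod("firstStageF", "IVFitResult", function(x) x@first_stage_F)
#' @rdname IVFitResult-class
setMethod("partialR2", "IVFitResult", function(x) x@partial_r2)
#' @rdname IVFitResult-class
setMethod("dwhP", "IVFitResult", function(x) x@dwh_p)

setMethod("show", "IVFitResult", function(object) {
  cat("IVFitResult (2SLS),", object@instrument, "\n")
  cat(sprintf("  beta = %.4f (95%% CI %.4f, %.4f), p = %.3g, n = %d\n",
              object@beta, object@ci_low, object@ci_high, object@p, object@n))
  cat(sprintf("  first-stage F = %.2f, partial R2 = %.4f, DWH p = %.3g\n",
              object@first_stage_F, object@partial_r2, object@dwh_p))
})

#' Serialize fitted results as a tidy table
#'
#' One row per term: term, estimate, se, ci_low, ci_high, p.
#'
#' @param fit a \linkS4class{RegressionResult} or \linkS4class{IVFitResult}.
#' @return data.frame.
#' @export
tidyFit <- function(fit) {
  if (is(fit, "IVFitResult"))
    return(data.frame(term = "exposure", estimate = fit@beta, se = fit@se,
                      ci_low = fit@ci_low, ci_high = fit@ci_high, p = fit@p,
                      stringsAsFactors = FALSE))
  data.frame(term = names(fit@coef), estimate = unname(fit@coef),
             se = unname(fit@se), ci_low = unname(fit@ci_low),
             ci_high = unname(fit@ci_high), p = unname(fit@p),
             stringsAsFactors = FALSE)
}
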