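#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Pools estimates with weights \eqn{w_k = 1/SE_k^2}: pooled estimate
#' \eqn{\sum w_k \beta_k / \sum w_k}, pooled SE \eqn{(\sum w_k)^{-1/2}},
#' normal-theory CI and p-value. Heterogeneity (Cochran's Q) is attached via
#' \code{\link{cochranQ}}.
#'
#' @param betas numeric estimates (k >= 2).
#' @param ses positive standard errors.
#'
#' @return A \linkS4class{MetaResult}.
#' @examples
#' ivwFixed(c(0.2, 0.5), c(0.1, 0.2))
#' @export
ivwFixed <- function(betas, ses) {
  k <- length(betas)
  stopifnot(length(ses) == k)
  if (k < 2L) stop("at least two estimates required")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("SEs must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- cochranQ(betas, ses)
  zc <- qnorm(0.975)
  new("MetaResult", beta = pooled, se = se,
      ci_low = pooled - zc * se, ci_high = pooled + zc * se,
      p = 2 * pnorm(-abs(pooled / se)),
      Q = q[["Q"]], df = as.integer(q[["df"]]),
      p_heterogeneity = q[["p"]], k = as.integer(k))
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum w_k (\beta_k - \bar\beta_{IVW})^2} with
#' \eqn{w_k = 1/SE_k^2}, referred to the upper tail of chi-squared with
#' k - 1 df.
#'
#' @inheritParams ivwFixed
#' @return named numeric: Q, df, p.
#' @examples
#' cochranQ(c(0.2, 0.5), c(0.1, 0.2))
#' @export
cochranQ <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("at least two estimates required")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("SEs must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  c(Q = Q, df = k - 1, p = pchisq(Q, k - 1, lower.tail = FALSE))
}

#' @rdname estimate
setMethod("estimate", "MetaResult", function(x) x@beta)
#' @rdname stdError
setMethod("stdError", "MetaResult", function(x) x@se)
#' @rdname pValue
setMethod("pValue", "MetaResult", function(x) x@p)
#' @rdname confInt
setMethod("confInt", "MetaResult", function(x)
  c(low = x@ci_low, high = x@ci_high))
#' @rdname MetaResult-class
setMethod("cochranQStat", "MetaResult", function(x)
  c(Q = x@Q, df = x@df, p = x@p_heterogeneity))

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("IVW fixed-effects pooling of %d estimates\n", object@k))
  cat(sprintf("  pooled beta = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
              object@beta, object@ci_low, object@ci_high, object@p))
  cat(sprintf("  Cochran's Q = %.3f on %d df, p_het = %.3g\n",
              object@Q, object@df, object@p_heterogeneity))
})
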