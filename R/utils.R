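# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so simulation helpers do not perturb
# user-level randomness.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up rounding to `digits` decimal places (the convention behind the
# reported participant-flow percentages); base round() is half-to-even.
roundHalfUp <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Build a design matrix: intercept, focal columns, covariates. Covariates may
# be NULL, a vector or a matrix. Returns a plain numeric matrix with named
# columns.
designMatrix <- function(n, ..., covariates = NULL) {
  parts <- list(...)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in names(parts)) {
    v <- parts[[nm]]
    if (is.null(v)) next
    v <- as.matrix(v)
    if (is.null(colnames(v)))
      colnames(v) <- if (ncol(v) == 1L) nm else paste0(nm, seq_len(ncol(v)))
    X <- cbind(X, v)
  }
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (ncol(C) > 0L) {
      if (is.null(colnames(C)))
        colnames(C) <- paste0("covar", seq_len(ncol(C)))
      X <- cbind(X, C)
    }
  }
  X
}

# Least squares by QR with an explicit rank check. Returns coef, fitted,
# residuals, RSS, df and the unscaled covariance (X'X)^-1.
lsSolve <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix (collinear columns)")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  R <- qr.R(qrX)
  XtXinv <- chol2inv(R)
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  list(coef = beta, fitted = fitted, residuals = res,
       rss = sum(res^2), df = length(y) - ncol(X), XtXinv = XtXinv)
}

# Sample skewness (method-of-moments).
sampleSkewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
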