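# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: dense matrix algebra and closed forms only.

# Just-identified IV estimate as the Wald ratio cov(z, y)/cov(z, x).
waldRatio <- function(y, x, z) cov(z, y) / cov(z, x)

# Restricted log-likelihood of y = Xb + g + e, Var = s2g*A + s2e*I, by a
# direct dense evaluation: -0.5 [ (n-p) log 2pi + log|V| + log|X'V^-1 X|
# + y'Py ].
denseRemlLogLik <- function(y, X, A, s2g, s2e) {
  n <- length(y)
  p <- ncol(X)
  V <- s2g * A + s2e * diag(n)
  Vinv <- solve(V)
  XtVinvX <- t(X) %*% Vinv %*% X
  P <- Vinv - Vinv %*% X %*% solve(XtVinvX, t(X) %*% Vinv)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
             determinant(V, logarithm = TRUE)$modulus +
             determinant(XtVinvX, logarithm = TRUE)$modulus +
             drop(t(y) %*% P %*% y)))
}

# Profiled dense restricted log-likelihood at a given h2 (total variance
# profiled out by REML: s2 = y'P0y/(n-p) where P0 uses V0 = h2*A + (1-h2)*I).
denseProfileRemlLogLik <- function(y, X, A, h2) {
  n <- length(y)
  p <- ncol(X)
  V0 <- h2 * A + (1 - h2) * diag(n)
  V0inv <- solve(V0)
  XtV0X <- t(X) %*% V0inv %*% X
  P0 <- V0inv - V0inv %*% X %*% solve(XtV0X, t(X) %*% V0inv)
  s2 <- drop(t(y) %*% P0 %*% y) / (n - p)
  denseRemlLogLik(y, X, A, h2 * s2, (1 - h2) * s2)
}

# Small simulated IV system: instrument z, exposure x confounded with the
# outcome through u, true effect beta.
makeIvFixture <- function(n, beta = 0.3, gamma = 0.5, conf = 0.4,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n)
  u <- rnorm(n)
  x <- gamma * z + conf * u + rnorm(n)
  y <- beta * x + conf * u + rnorm(n)
  list(y = y, x = x, z = z, u = u)
}

# Tiny instrument panel for fast pipeline tests.
tinyPanel <- function(J = 4L) {
  SnpPanel(sprintf("rs%02d", seq_len(J)),
           rep(c("A", "G"), length.out = J),
           eaf = seq(0.25, 0.7, length.out = J),
           weight = seq(0.4, 0.1, length.out = J))
}
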