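#' Compute a genetic relationship matrix (GRM)
#'
#' Standardized-dosage GRM:
#' \deqn{A_{jk} = \frac{1}{M} \sum_m \frac{(g_{jm} - 2p_m)(g_{km} - 2p_m)}
#'   {2 p_m (1 - p_m)}}
#' with \eqn{p_m} the sample effect-allele frequency. SNPs with minor allele
#' frequency below \code{maf_floor} are excluded; the diagonal uses the same
#' standardized-product formula. Missing dosages are imputed at the SNP mean
#' (equivalently, they contribute zero after centring).
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param maf_floor minimum sample minor-allele frequency (default 0.01).
#' @param snps SNP ids to use (default: background SNPs when present,
#'   otherwise all).
#'
#' @return A \linkS4class{GRM}.
#' @examples
#' G <- simulateGenotypes(50, syntheticBmiPanel(), n_background = 100, seed = 2)
#' A <- computeGRM(G)
#' mean(diag(grmMatrix(A)))
#' @export
computeGRM <- function(G, maf_floor = 0.01, snps = NULL) {
  rd <- SummarizedExperiment::rowData(G)
  if (is.null(snps))
    snps <- if (any(!rd$instrument)) rownames(G)[!rd$instrument] else rownames(G)
  d <- t(SummarizedExperiment::assay(G, "dosage")[snps, , drop = FALSE])
  n <- nrow(d)
  if (n < 2L) stop("at least 2 individuals required")
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- pmin(p, 1 - p) >= maf_floor
  if (!any(keep)) stop("no SNPs pass the frequency floor (all monomorphic?)")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(d, 2L, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  dimnames(A) <- list(colnames(G), colnames(G))
  new("GRM", matrix = A, ids = colnames(G), n_snps = as.integer(ncol(Z)))
}

#' @rdname GRM-class
#' @param x a \linkS4class{GRM}.
#' @export
grmMatrix <- function(x) x@matrix

#' @rdname GRM-class
#' @export
grmIds <- function(x) x@ids

setMethod("show", "GRM", function(object) {
  cat("GRM:", length(object@ids), "individuals from", object@n_snps, "SNPs\n")
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(object@matrix)),
              mean(object@matrix[upper.tri(object@matrix)])))
})

#' Greedy cryptic-relatedness pruning
#'
#' While any off-diagonal relationship exceeds the threshold, removes the
#' individual participating in the most offending pairs (ties broken by
#' lowest id). No retained pair exceeds the threshold.
#'
#' @param A a \linkS4class{GRM}.
#' @param threshold relatedness cutoff (default 0.025, i.e. 2.5\%).
#'
#' @return character vector of retained ids.
#' @export
pruneRelated <- function(A, threshold = 0.025) {
  stopifnot(threshold > 0)
  m <- A@matrix
  ids <- A@ids
  keep <- rep(TRUE, length(ids))
  repeat {
    sub <- m[keep, keep, drop = FALSE]
    off <- sub > threshold
    diag(off) <- FALSE
    counts <- rowSums(off)
    if (all(counts == 0L)) break
    worst <- which(counts == max(counts))
    drop_id <- sort(rownames(sub)[worst])[1L]
    keep[match(drop_id, ids)] <- FALSE
  }
  ids[keep]
}

# Restricted log-likelihood of y = X b + g + e, Var = s2g * A + s2e * I,
# evaluated via the eigendecomposition of A (rotated coordinates). Includes
# the full constant so it is directly comparable with a dense evaluation of
# -0.5 * [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ].
remlLogLikRotated <- function(ytil, Xtil, dvals, s2g, s2e) {
  lambda <- s2g * dvals + s2e
  if (any(lambda <= 0)) return(-Inf)
  w <- 1 / lambda
  XtWX <- crossprod(Xtil * w, Xtil)
  XtWy <- crossprod(Xtil * w, ytil)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ytil - Xtil %*% beta
  yPy <- sum(w * r^2)
  n <- length(ytil); p <- ncol(Xtil)
  -0.5 * ((n - p) * log(2 * pi) + sum(log(lambda)) +
          2 * sum(log(diag(ch))) + yPy)
}

#' GREML heritability estimation by restricted maximum likelihood
#'
#' Fits \eqn{y = X\beta + g + \epsilon} with
#' \eqn{Var(y) = \sigma_g^2 A + \sigma_e^2 I} by REML. After one
#' eigendecomposition of the GRM, the restricted likelihood is profiled over
#' the total variance and maximized over \eqn{h^2 = \sigma_g^2 /
#' (\sigma_g^2 + \sigma_e^2)} on [0, 1] by boundary-respecting scalar
#' optimization (tolerance 1e-8). Standard errors come from the numerically
#' differentiated observed information in \eqn{(\sigma_g^2, \sigma_e^2)}
#' (delta method for \eqn{h^2}); the likelihood-ratio p-value against
#' \eqn{h^2 = 0} uses the boundary mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}.
#'
#' @param y numeric trait vector (typically a z-score).
#' @param A a \linkS4class{GRM} whose ids match \code{names(y)} order (or
#'   length).
#' @param covariates optional covariates; an intercept is always included.
#'
#' @return A \linkS4class{HeritabilityEstimate}.
#' @export
remlFit <- function(y, A, covariates = NULL) {
  stopifnot(is(A, "GRM"))
  n <- length(y)
  if (n != length(A@ids)) stop("GRM dimension does not match y")
  if (var(y) == 0) stop("trait variance is zero")
  X <- designMatrix(n, covariates = covariates)
  eg <- eigen(A@matrix, symmetric = TRUE)
  U <- eg$vectors
  dvals <- pmax(eg$values, 0)
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, X)
  p <- ncol(X)

  nev <- 0L
  profileLL <- function(h2) {
    nev <<- nev + 1L
    lambda <- h2 * dvals + (1 - h2)
    if (any(lambda <= 0)) return(-Inf)
    w <- 1 / lambda
    XtWX <- crossprod(Xtil * w, Xtil)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xtil * w, ytil)))
    r <- ytil - Xtil %*% beta
    q <- sum(w * r^2)
    s2 <- q / (n - p)
    -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) + sum(log(lambda)) +
            2 * sum(log(diag(ch))))
  }

  opt <- optimize(profileLL, c(0, 1), maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  ll <- opt$objective
  # snap to the boundary when it does at least as well
  for (b in c(0, 1)) {
    llb <- profileLL(b)
    if (llb >= ll - 1e-9) { h2 <- b; ll <- llb }
  }
  # recover the profiled total variance
  lambda <- h2 * dvals + (1 - h2)
  w <- 1 / lambda
  XtWX <- crossprod(Xtil * w, Xtil)
  beta <- solve(XtWX, crossprod(Xtil * w, ytil))
  s2tot <- sum(w * (ytil - Xtil %*% beta)^2) / (n - p)
  s2g <- h2 * s2tot
  s2e <- (1 - h2) * s2tot

  # observed information in (s2g, s2e) by central finite differences
  f <- function(th) remlLogLikRotated(ytil, Xtil, dvals, th[1L], th[2L])
  th <- c(s2g, s2e)
  hstep <- pmax(abs(th), s2tot * 0.01) * 1e-3
  H <- matrix(NA_real_, 2L, 2L)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- hstep[i]; ej[j] <- hstep[j]
    H[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                f(th - ei + ej) + f(th - ei - ej)) / (4 * hstep[i] * hstep[j])
  }
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 2L, 2L))
  se_g <- sqrt(pmax(V[1L, 1L], 0))
  se_e <- sqrt(pmax(V[2L, 2L], 0))
  tot <- s2g + s2e
  grad <- c(s2e, -s2g) / tot^2
  vh2 <- drop(t(grad) %*% V %*% grad)
  se_h2 <- if (is.finite(vh2) && vh2 >= 0) sqrt(vh2) else NA_real_

  ll0 <- profileLL(0)
  lrt <- max(2 * (ll - ll0), 0)
  lrt_p <- if (lrt == 0) 1 else 0.5 * pchisq(lrt, 1L, lower.tail = FALSE)

  new("HeritabilityEstimate", sigma2_g = s2g, sigma2_e = s2e, h2 = h2,
      se_h2 = se_h2, se_sigma2_g = se_g, se_sigma2_e = se_e,
      loglik = ll, lrt = lrt, lrt_p = lrt_p,
      iterations = nev, converged = TRUE)
}

#' @rdname HeritabilityEstimate-class
setMethod("heritability", "HeritabilityEstimate", function(x) x@h2)

#' @rdname HeritabilityEstimate-class
setMethod("varComponents", "HeritabilityEstimate", function(x)
  c(sigma2_g = x@sigma2_g, sigma2_e = x@sigma2_e))

#' @rdname stdError
setMethod("stdError", "HeritabilityEstimate", function(x) x@se_h2)

#' @rdname pValue
setMethod("pValue", "HeritabilityEstimate", function(x) x@lrt_p)

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf("GREML: h2 = %.3f (SE %.3f), sigma2_g = %.3f, sigma2_e = %.3f\n",
              object@h2, object@se_h2, object@sigma2_g, object@sigma2_e))
  cat(sprintf("  restricted logLik = %.3f, LRT p (h2=0) = %.3g, %d evaluations\n",
              object@loglik, object@lrt_p, object@iterations))
})

#' Write / read a GRM as gzipped lower-triangle text
#'
#' Interoperable layout: one row per pair (i >= j) with columns index_i,
#' index_j, n_snps, value, plus a companion id file (\code{<path>.id}).
#'
#' @param A a \linkS4class{GRM}; @param path output path (".gz" appended if
#'   absent).
#' @return the path, invisibly.
#' @export
writeGRM <- function(A, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  m <- A@matrix
  n <- nrow(m)
  idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.table(data.frame(index_i = idx[, 1L], index_j = idx[, 2L],
                         n_snps = A@n_snps, value = m[idx]),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writeLines(A@ids, sub("\\.gz$", ".id", path))
  invisible(path)
}

#' @rdname writeGRM
#' @export
readGRM <- function(path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  d <- read.delim(gzfile(path), header = FALSE,
                  col.names = c("index_i", "index_j", "n_snps", "value"))
  ids <- readLines(sub("\\.gz$", ".id", path))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[cbind(d$index_i, d$index_j)] <- d$value
  m[cbind(d$index_j, d$index_i)] <- d$value
  new("GRM", matrix = m, ids = ids, n_snps = as.integer(d$n_snps[1L]))
}
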