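mkGenotype <- function(d, eaf = rep(0.5, nrow(d))) {
  GenotypeMatrix(d, effect_allele = "A", other_allele = "G", eaf = eaf,
                 weight = NA_real_, instrument = FALSE)
}

test_that("GRM entries match the standardized-product formula by hand", {
  d <- matrix(c(2, 0), nrow = 1, dimnames = list("s1", c("i1", "i2")))
  A <- computeGRM(mkGenotype(d), maf_floor = 0.01)
  m <- grmMatrix(A)
  # sample p = 0.5: off-diagonal (2-1)(0-1)/(2*0.5*0.5) = -2
  expect_equal(m["i1", "i2"], -2)
  expect_equal(m["i1", "i1"], 2)
})

test_that("monomorphic SNPs are excluded without division by zero", {
  d <- rbind(s1 = c(2, 0, 1, 1), s2 = c(2, 2, 2, 2))
  colnames(d) <- paste0("i", 1:4)
  A <- computeGRM(mkGenotype(d))
  expect_identical(A@n_snps, 1L)
  expect_true(all(is.finite(grmMatrix(A))))
  d2 <- rbind(s2 = c(2, 2, 2, 2))
  colnames(d2) <- paste0("i", 1:4)
  expect_error(computeGRM(mkGenotype(d2)), "frequency floor")
})

test_that("HWE genotypes give a standardized GRM", {
  G <- simulateGenotypes(500, tinyPanel(), n_background = 1000, seed = 111)
  A <- grmMatrix(computeGRM(G))
  expect_gt(mean(diag(A)), 0.95)
  expect_lt(mean(diag(A)), 1.05)
  expect_lt(abs(mean(A[upper.tri(A)])), 0.01)
})

test_that("the GRM is invariant to SNP order", {
  G <- simulateGenotypes(60, tinyPanel(), n_background = 30, seed = 112)
  A1 <- computeGRM(G)
  snps <- rownames(G)[!SummarizedExperiment::rowData(G)$instrument]
  A2 <- computeGRM(G, snps = rev(snps))
  expect_equal(grmMatrix(A1), grmMatrix(A2), tolerance = 1e-12)
})

test_that("greedy relatedness pruning removes exactly the offending pairs", {
  n <- 6
  m <- diag(n) * 0 + diag(n)
  ids <- paste0("i", 1:n)
  dimnames(m) <- list(ids, ids)
  A0 <- new("GRM", matrix = m, ids = ids, n_snps = 10L)
  expect_identical(pruneRelated(A0), ids)            # identity: none removed
  m2 <- m
  m2["i2", "i5"] <- m2["i5", "i2"] <- 0.5            # one related pair
  A2 <- new("GRM", matrix = m2, ids = ids, n_snps = 10L)
  kept <- pruneRelated(A2, threshold = 0.025)
  expect_identical(length(kept), 5L)
  expect_identical(setdiff(ids, kept), "i2")         # tie broken by lowest id
  expect_identical(pruneRelated(A2, threshold = 0.6), ids)
  # the retained set never contains an offending pair
  set.seed(113)
  r <- matrix(runif(n * n, 0, 0.06), n)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  Ar <- new("GRM", matrix = r, ids = ids, n_snps = 10L)
  kept_r <- pruneRelated(Ar, 0.04)
  sub <- r[kept_r, kept_r]
  diag(sub) <- 0
  expect_lte(max(sub), 0.04)
})

test_that("REML log-likelihood matches a dense-matrix oracle", {
  set.seed(114)
  n <- 150
  G <- simulateGenotypes(n, tinyPanel(), n_background = 120, seed = 115)
  A <- computeGRM(G)
  Z <- sweep(t(dosage(G)), 2, colMeans(t(dosage(G))))
  g <- drop(scale(Z[, 5:40] %*% rnorm(36))) * sqrt(0.4)
  y <- g + rnorm(n, sd = sqrt(0.6))
  cv <- rnorm(n)
  fit <- remlFit(y, A, covariates = cv)
  X <- cbind(1, cv)
  # optimum log-likelihood agrees with the dense evaluation at the optimum
  expect_equal(fit@loglik,
               denseRemlLogLik(y, X, grmMatrix(A), fit@sigma2_g,
                               fit@sigma2_e),
               tolerance = 1e-6)
  # and dominates a profile grid evaluated densely
  grid <- seq(0, 1, by = 0.1)
  dense <- vapply(grid, function(h)
    denseProfileRemlLogLik(y, X, grmMatrix(A), min(h, 0.999)), numeric(1))
  expect_true(all(fit@loglik >= dense - 1e-6))
})

test_that("heritability estimates are equivariant to trait scaling", {
  set.seed(116)
  G <- simulateGenotypes(200, tinyPanel(), n_background = 150, seed = 117)
  A <- computeGRM(G)
  y <- rnorm(200)
  f1 <- remlFit(y, A)
  f2 <- remlFit(3 * y, A)
  expect_equal(heritability(f1), heritability(f2), tolerance = 1e-4)
  expect_equal(unname(varComponents(f2)), unname(varComponents(f1)) * 9,
               tolerance = 1e-3)
})

test_that("a non-heritable trait yields near-zero heritability", {
  set.seed(118)
  G <- simulateGenotypes(400, tinyPanel(), n_background = 300, seed = 119)
  A <- computeGRM(G)
  hits <- replicate(8, {
    f <- remlFit(rnorm(400), A)
    ok_h2 <- f@h2 <= 2 * max(f@se_h2, 0.05, na.rm = TRUE)
    ok_p <- f@lrt_p > 0.05
    ok_h2 && ok_p
  })
  expect_gte(mean(hits), 0.75)
})

test_that("GRM text serialisation round-trips", {
  G <- simulateGenotypes(25, tinyPanel(), n_background = 40, seed = 120)
  A <- computeGRM(G)
  path <- tempfile(fileext = ".grm.gz")
  writeGRM(A, path)
  B <- readGRM(path)
  expect_equal(grmMatrix(A), grmMatrix(B), tolerance = 1e-10)
  expect_identical(grmIds(A), grmIds(B))
  expect_identical(A@n_snps, B@n_snps)
})
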