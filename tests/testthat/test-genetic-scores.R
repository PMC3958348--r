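test_that("weighted allelic score matches hand arithmetic", {
  panel <- SnpPanel(c("s1", "s2", "s3"), c("A", "C", "G"),
                    eaf = c(0.5, 0.5, 0.5), weight = c(0.39, 0.33, 0.25))
  d <- matrix(c(2, 1, 0), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), "ind1"))
  G <- GenotypeMatrix(d, effect_allele = c("A", "C", "G"),
                      other_allele = c("G", "T", "A"),
                      eaf = c(0.5, 0.5, 0.5), weight = c(0.39, 0.33, 0.25))
  expect_equal(unname(weightedAllelicScore(G, panel, scale = "raw_sum")),
               1.11)
  expect_equal(unname(weightedAllelicScore(G, panel, scale = "allele_count")),
               1.11 * 3 / 0.97, tolerance = 1e-12)  # 3.4330
})

test_that("equal weights reduce the allele-count score to an allele count", {
  panel <- SnpPanel(c("a", "b"), c("A", "A"), c(0.3, 0.6), c(0.2, 0.2))
  G <- simulateGenotypes(100, panel, seed = 61)
  s <- weightedAllelicScore(G, panel, scale = "allele_count")
  expect_equal(unname(s), unname(colSums(dosage(G))))
  # single SNP: score equals dosage
  p1 <- SnpPanel("a", "A", 0.3, 0.7)
  G1 <- simulateGenotypes(50, p1, seed = 62)
  expect_equal(unname(weightedAllelicScore(G1, p1)),
               unname(dosage(G1)["a", ]))
})

test_that("missing dosages are imputed at twice the allele frequency", {
  panel <- SnpPanel(c("a", "b"), c("A", "A"), c(0.25, 0.5), c(1, 1))
  d <- matrix(c(NA, 2, 1, NA), nrow = 2,
              dimnames = list(c("a", "b"), c("i1", "i2")))
  G <- GenotypeMatrix(d, effect_allele = "A", other_allele = "G",
                      eaf = c(0.25, 0.5), weight = c(1, 1))
  s <- weightedAllelicScore(G, panel, scale = "raw_sum")
  expect_equal(unname(s), c(2 * 0.25 + 2, 1 + 2 * 0.5))
  dall <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "i1"))
  Gall <- GenotypeMatrix(dall, effect_allele = "A", other_allele = "G",
                         eaf = c(0.25, 0.5), weight = c(1, 1))
  expect_error(weightedAllelicScore(Gall, panel), "all panel dosages missing")
  p0 <- SnpPanel(c("a", "b"), c("A", "A"), c(0.25, 0.5), c(0, 0))
  expect_error(weightedAllelicScore(G, p0), "zero total weight")
})

test_that("the score is linear in dosage", {
  panel <- tinyPanel()
  G1 <- simulateGenotypes(80, panel, seed = 63)
  G2 <- simulateGenotypes(80, panel, seed = 64)
  davg <- (dosage(G1) + dosage(G2)) / 2
  Gavg <- GenotypeMatrix(davg, effect_allele = effectAlleles(panel),
                         other_allele = panel@other_allele,
                         eaf = eafs(panel), weight = scoreWeights(panel))
  expect_equal(weightedAllelicScore(Gavg, panel),
               (weightedAllelicScore(G1, panel) +
                weightedAllelicScore(G2, panel)) / 2, tolerance = 1e-12)
})

test_that("GWAS betas agree with a normal-equations solve", {
  set.seed(65)
  G <- simulateGenotypes(50, tinyPanel(), n_background = 5, seed = 66)
  age <- rnorm(50, 140, 3)
  y <- rnorm(50)
  gw <- gwasScan(G, y, covariates = age)
  D <- t(dosage(G))
  for (j in seq_len(nrow(gw))) {
    X <- cbind(1, age, D[, gw$snp_id[j]])
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(gw$beta[j], beta[3], tolerance = 1e-8)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (50 - 3)
    expect_equal(gw$se[j], sqrt(s2 * solve(t(X) %*% X)[3, 3]),
                 tolerance = 1e-8)
  }
})

test_that("null GWAS p-values are uniform and a planted effect is recovered", {
  set.seed(67)
  G <- simulateGenotypes(2000, tinyPanel(), n_background = 1000, seed = 68)
  y <- rnorm(2000)
  gw <- gwasScan(G, y)
  frac <- mean(gw$p <= 0.1)
  expect_gt(frac, 0.07)
  expect_lt(frac, 0.13)
  # planted single-SNP effect
  g1 <- dosage(G)["bg00001", ]
  y2 <- 0.2 * g1 + rnorm(2000)
  gw2 <- gwasScan(G, y2, snps = "bg00001")
  expect_lt(abs(gw2$beta - 0.2), 2 * gw2$se)
  expect_error(gwasScan(G, rep(1, 2000)), "constant phenotype")
})

test_that("prediction-score selection uses an inclusive threshold", {
  gw <- data.frame(snp_id = c("a", "b", "c"), effect_allele = "A",
                   eaf = 0.5, beta = c(0.2, -0.1, 0.3),
                   se = 0.1, p = c(0.1, 0.5, 0.01), n = 100)
  sc <- buildPredictionScore(gw, p_threshold = 0.1)
  expect_setequal(snpIds(sc), c("a", "c"))     # p exactly 0.1 retained
  expect_identical(length(buildPredictionScore(gw, p_threshold = 1)), 3L)
  expect_error(buildPredictionScore(gw, p_threshold = 1e-6), "no SNPs")
  # null selection rate ~ threshold
  set.seed(69)
  G <- simulateGenotypes(1500, tinyPanel(), n_background = 1000, seed = 70)
  gw2 <- gwasScan(G, rnorm(1500))
  k <- length(buildPredictionScore(gw2, 0.1))
  expect_lt(abs(k - 100), 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("score application reconciles allele orientation", {
  G <- simulateGenotypes(120, tinyPanel(), seed = 71)
  panel <- tinyPanel()
  sc <- new("ScoreDefinition", snp_id = snpIds(panel),
            effect_allele = effectAlleles(panel),
            weight = c(0.2, -0.1, 0.3, 0.15), eaf = eafs(panel),
            label = "test")
  s1 <- applyScore(G, sc)
  # flip every allele label and weight sign: identical up to a constant
  flipped <- new("ScoreDefinition", snp_id = snpIds(panel),
                 effect_allele = panel@other_allele,
                 weight = -sc@weight, eaf = 1 - sc@eaf, label = "flip")
  s2 <- applyScore(G, flipped)
  expect_equal(diff(range((s1 - s2))), 0, tolerance = 1e-12)
  bad <- new("ScoreDefinition", snp_id = snpIds(panel),
             effect_allele = rep("T", 4), weight = sc@weight,
             eaf = sc@eaf, label = "bad")
  expect_error(applyScore(G, bad), "allele mismatch|unreconcilable")
  none <- new("ScoreDefinition", snp_id = "absent", effect_allele = "A",
              weight = 1, eaf = 0.5, label = "none")
  expect_error(applyScore(G, none), "no overlap")
})

test_that("discovery-half association exceeds held-out association", {
  set.seed(72)
  overfit <- replicate(20, {
    G <- simulateGenotypes(400, tinyPanel(), n_background = 100,
                           seed = sample.int(1e6, 1))
    y <- rnorm(400)
    halves <- splitSample(colnames(G), seed = sample.int(1e6, 1))
    ia <- match(halves$A, colnames(G)); ib <- match(halves$B, colnames(G))
    gw <- gwasScan(G[, ia], y[ia])
    sc <- buildPredictionScore(gw, 0.2)
    cor(applyScore(G[, ia], sc), y[ia]) -
      cor(applyScore(G[, ib], sc), y[ib])
  })
  expect_gt(mean(overfit > 0), 0.8)
})

test_that("split-sample partitions are balanced and deterministic", {
  h <- splitSample(paste0("id", seq_len(4296)), seed = 73)
  expect_identical(length(h$A), 2148L)
  expect_identical(length(h$B), 2148L)
  expect_length(intersect(h$A, h$B), 0)
  h5 <- splitSample(letters[1:5], seed = 74)
  expect_identical(sort(c(length(h5$A), length(h5$B))), c(2L, 3L))
  expect_identical(splitSample(letters[1:5], seed = 74), h5)
})
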