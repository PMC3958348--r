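test_that("degenerate allele frequency gives fixed dosages", {
  panel <- SnpPanel("rs1", "A", eaf = 1 - 1e-12, weight = 0.3)
  G <- simulateGenotypes(50, panel, seed = 1)
  expect_true(all(dosage(G) == 2))
})

test_that("genotype simulation is deterministic given the seed", {
  panel <- tinyPanel()
  G1 <- simulateGenotypes(200, panel, n_background = 20, seed = 42)
  G2 <- simulateGenotypes(200, panel, n_background = 20, seed = 42)
  expect_identical(dosage(G1), dosage(G2))
  G3 <- simulateGenotypes(200, panel, n_background = 20, seed = 43)
  expect_false(identical(dosage(G1), dosage(G3)))
})

test_that("sample allele frequencies recover the panel frequencies", {
  n <- 10000
  G <- simulateGenotypes(n, syntheticBmiPanel(), seed = 7)
  freq <- rowMeans(dosage(G)) / 2
  p <- eafs(syntheticBmiPanel())
  bound <- 4 * sqrt(p * (1 - p) / (2 * n))
  expect_true(all(abs(freq - p) < bound))
  # single-SNP check at the tighter 3 SE bound
  p4 <- 0.4
  G4 <- simulateGenotypes(n, SnpPanel("rsA", "A", p4, 0.1), seed = 8)
  expect_lt(abs(mean(dosage(G4)) / 2 - p4), 3 * sqrt(p4 * (1 - p4) / (2 * n)))
})

test_that("invalid simulation inputs are rejected", {
  expect_error(simulateGenotypes(1, tinyPanel(), seed = 1), "at least 2")
  expect_error(SnpPanel("rs1", "A", eaf = 1.2, weight = 0.1), "eaf")
  expect_error(SnpPanel(c("rs1", "rs1"), c("A", "A"), c(0.4, 0.4),
                        c(0.1, 0.1)), "unique")
})

test_that("null structural model gives uncorrelated exposure and activity", {
  truth <- TrueParams(beta_forward = 0, conf_exposure = 0, conf_outcome = 0,
                      h2_activity = 0)
  n <- 5000
  sim <- simulateCohort(n, tinyPanel(), truth, n_background = 0, seed = 3)
  st <- sim$diagnostics$structural
  expect_lt(abs(cor(st$exposure_z, st$total_pa)), 3 / sqrt(n))
})

test_that("variance bookkeeping holds at large n", {
  sim <- simulateCohort(10000, syntheticBmiPanel(), TrueParams(),
                        n_background = 200, seed = 5)
  d <- sim$diagnostics
  expect_lt(abs(d$realized_var_exposure - 1), 0.05)
  expect_true(all(abs(d$realized_var_activity - 1) < 0.05))
})

test_that("realized instrument strength matches the planted score R2", {
  sim <- simulateCohort(4296, syntheticBmiPanel(),
                        TrueParams(score_r2 = 0.028, h2_activity = 0), n_background = 0,
                        seed = 11)
  expect_gt(sim$diagnostics$realized_score_r2, 0.015)
  expect_lt(sim$diagnostics$realized_score_r2, 0.045)
})

test_that("simulated allelic score distribution matches the emulated study", {
  sim <- simulateCohort(4296, syntheticBmiPanel(), TrueParams(h2_activity = 0),
                        n_background = 0, seed = 13)
  expect_gt(sim$diagnostics$score_mean, 28)
  expect_lt(sim$diagnostics$score_mean, 31)
  # right-skewed raw moderate-to-vigorous minutes
  expect_gt(sampleSkew <- mean((sim$phenotypes$mvpa -
    mean(sim$phenotypes$mvpa))^3) / sd(sim$phenotypes$mvpa)^3, 0.5)
})

test_that("BMI and FMI are generated with the target correlation", {
  sim <- simulateCohort(10000, tinyPanel(), TrueParams(h2_activity = 0), n_background = 0,
                        seed = 17)
  r <- cor(sim$phenotypes$bmi, sim$phenotypes$fmi)
  expect_gt(r, 0.90)
  expect_lt(r, 0.97)
})

test_that("infeasible variance bookkeeping is an error", {
  truth <- TrueParams(conf_exposure = 0.8, score_r2 = 0.5, h2_activity = 0)
  expect_error(simulateCohort(200, tinyPanel(), truth, n_background = 0,
                              seed = 1), "infeasible")
})

test_that("cohort simulation is deterministic given the seed", {
  a <- simulateCohort(150, tinyPanel(), TrueParams(), n_background = 10,
                      seed = 9)
  b <- simulateCohort(150, tinyPanel(), TrueParams(), n_background = 10,
                      seed = 9)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
})

test_that("reverse mode plants an activity-to-adiposity effect", {
  truth <- TrueParams(beta_forward = 0, beta_reverse = 0.3, h2_activity = 0)
  sim <- simulateCohort(20000, tinyPanel(), truth, n_background = 0,
                        seed = 21)
  st <- sim$diagnostics$structural
  ybar <- scale(rowMeans(st[, c("total_pa", "mvpa", "sedentary")]))
  # OLS of exposure on the latent activity mean shows effect + confounding
  expect_gt(coef(lm(st$exposure_z ~ ybar))[2], 0.2)
  expect_error(TrueParams(beta_forward = -0.1, beta_reverse = 0.2),
               "one causal direction")
})

test_that("minute-count traces honour the requested band structure", {
  # all-sedentary day
  tr <- simulateMinuteCounts(50, 0, 1, n_days = 2, wear_minutes = 300,
                             seed = 1)
  expect_true(all(tr$counts < 199))
  # zero wear minutes -> empty trace
  expect_identical(nrow(simulateMinuteCounts(600, 0.1, 0.5, 3, 0, seed = 1)),
                   0L)
  # requested minutes reproduced exactly after summarisation
  tr <- simulateMinuteCounts(600, 30 / 600, 400 / 600, n_days = 3,
                             wear_minutes = 600, seed = 4)
  s <- summarizeActigraphy(tr)
  expect_equal(s$mvpa, 30)
  expect_equal(s$sedentary, 400)
  # determinism
  tr2 <- simulateMinuteCounts(600, 30 / 600, 400 / 600, n_days = 3,
                              wear_minutes = 600, seed = 4)
  expect_identical(tr, tr2)
  expect_error(simulateMinuteCounts(600, 0.7, 0.5, 1, 100, seed = 1),
               "inconsistent")
})
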