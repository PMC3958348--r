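#' Construct the planted truth of a synthetic cohort
#'
#' Defaults reflect the study this generator emulates: a forward causal
#' effect of adiposity of -0.18 SD/SD on total and moderate-to-vigorous
#' activity and +0.20 SD/SD on sedentary time, no reverse effect, a shared
#' confounder loading 0.3 on both sides, activity SNP heritability 0.21
#' (midpoint of the reported 17\%-25\% range) and an instrument score
#' explaining 2.8\% of exposure variance.
#'
#' @param beta_forward numeric: causal effect of the adiposity z-score on
#'   each activity z-score (SD/SD). A scalar is recycled to the three traits;
#'   otherwise supply a named vector (total_pa, mvpa, sedentary).
#' @param beta_reverse numeric scalar: causal effect of the latent activity
#'   level on adiposity; requires beta_forward = 0.
#' @param conf_exposure,conf_outcome confounder loadings (SD units).
#' @param h2_activity additive heritability of each activity trait in [0, 1].
#' @param score_r2 exposure variance explained by the allelic score in [0, 1].
#'
#' @return A \linkS4class{TrueParams}.
#' @export
TrueParams <- function(beta_forward = c(total_pa = -0.18, mvpa = -0.18,
                                        sedentary = 0.20),
                       beta_reverse = 0,
                       conf_exposure = 0.3, conf_outcome = 0.3,
                       h2_activity = 0.21, score_r2 = 0.028) {
  if (length(beta_forward) == 1L && is.null(names(beta_forward)))
    beta_forward <- c(total_pa = beta_forward, mvpa = beta_forward,
                      sedentary = beta_forward)
  beta_forward <- beta_forward[c("total_pa", "mvpa", "sedentary")]
  names(beta_forward) <- c("total_pa", "mvpa", "sedentary")
  new("TrueParams", beta_forward = beta_forward,
      beta_reverse = as.numeric(beta_reverse),
      conf_exposure = as.numeric(conf_exposure),
      conf_outcome = as.numeric(conf_outcome),
      h2_activity = as.numeric(h2_activity),
      score_r2 = as.numeric(score_r2))
}

setMethod("show", "TrueParams", function(object) {
  cat("TrueParams\n")
  cat("  beta_forward:", paste(names(object@beta_forward),
      sprintf("%+.3f", object@beta_forward), collapse = ", "), "\n")
  cat("  beta_reverse:", object@beta_reverse,
      " confounder loadings:", object@conf_exposure, "/", object@conf_outcome, "\n")
  cat("  h2_activity:", object@h2_activity, " score_r2:", object@score_r2, "\n")
})

# Unseeded genotype generation core shared by simulateGenotypes and
# simulateCohort so that a single seed governs one coherent RNG stream.
simulateGenotypesCore <- function(n, panel, n_background = 0L) {
  stopifnot(is(panel, "SnpPanel"))
  if (n < 2) stop("n must be at least 2")
  validObject(panel)
  J <- length(panel)
  freqs <- panel@eaf
  ea <- panel@effect_allele
  oa <- panel@other_allele
  ids <- panel@snp_id
  inst <- rep(TRUE, J)
  wts <- panel@weight
  if (n_background > 0L) {
    bf <- runif(n_background, 0.05, 0.95)
    freqs <- c(freqs, bf)
    bases <- c("A", "C", "G", "T")
    bea <- sample(bases, n_background, replace = TRUE)
    boa <- vapply(bea, function(a) sample(setdiff(bases, a), 1L), character(1))
    ea <- c(ea, bea)
    oa <- c(oa, unname(boa))
    ids <- c(ids, sprintf("bg%05d", seq_len(n_background)))
    inst <- c(inst, rep(FALSE, n_background))
    wts <- c(wts, rep(NA_real_, n_background))
  }
  M <- length(freqs)
  # each dosage ~ Binomial(2, p): Hardy-Weinberg, linkage equilibrium
  # (SNP-major fill: each column is one individual's dosages)
  d <- matrix(rbinom(M * n, 2L, rep(freqs, n)), nrow = M)
  dimnames(d) <- list(ids, sprintf("id%05d", seq_len(n)))
  GenotypeMatrix(d, effect_allele = ea, other_allele = oa, eaf = freqs,
                 weight = wts, instrument = inst)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each dosage is drawn Binomial(2, eaf) independently across SNPs and
#' individuals (Hardy-Weinberg and linkage equilibrium). Background SNPs,
#' used for polygenic backgrounds, GWAS scans and the genetic relationship
#' matrix, get frequencies drawn uniformly on [0.05, 0.95].
#'
#' @param n number of individuals (>= 2).
#' @param panel a \linkS4class{SnpPanel} of instrument SNPs.
#' @param n_background number of extra background SNPs (default 0).
#' @param seed integer seed; identical seeds give identical matrices.
#'
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' G <- simulateGenotypes(100, syntheticBmiPanel(), seed = 1)
#' dim(dosage(G))
#' @export
simulateGenotypes <- function(n, panel, n_background = 0L, seed) {
  withSeed(seed, simulateGenotypesCore(n, panel, n_background))
}

#' Simulate a full synthetic cohort with a planted causal structure
#'
#' Generative model (all structural variables on the z scale):
#' \deqn{x = a s + c_x U + e_x, \quad y_t = \beta_t x + c_y U + g_t + e_t}
#' where \eqn{s} is the centred/scaled weighted allelic score with
#' \eqn{a = \sqrt{score\_r2}}, \eqn{U} a latent standard-normal confounder,
#' and \eqn{g_t} a per-trait polygenic component built from the background
#' SNP dosages and scaled to variance \code{h2_activity}. Residual variances
#' are chosen so each structural variable has unit variance; infeasible
#' bookkeeping (components summing above 1) is an error. When
#' \code{beta_reverse} is non-zero, the activity traits are generated with no
#' forward effect and adiposity receives \code{beta_reverse} times the
#' standardized mean of the three activity traits instead.
#'
#' Raw-scale phenotype columns are produced by sex-specific affine transforms
#' to the emulated study's means/SDs (BMI 18.9/3.3, FMI 5.0/2.7, total
#' activity 607.2/178.4 counts/min, sedentary 427.3/66.6 min/d overall);
#' moderate-to-vigorous activity is generated on the log scale and
#' exponentiated, reproducing its right skew. FMI is generated conditionally
#' on BMI with correlation \code{fmi_cor}. Confounder columns (maternal BMI,
#' birth weight, maternal smoking) load on \eqn{U} and are independent of
#' genotype.
#'
#' @param n cohort size (>= 100); the emulated study has n = 4,296.
#' @param panel instrument \linkS4class{SnpPanel}.
#' @param truth a \linkS4class{TrueParams}.
#' @param n_background background SNP count (default 2,000, a desk-scale
#'   stand-in for a genome-wide set).
#' @param seed integer seed.
#' @param fmi_cor target BMI-FMI correlation (default 0.94).
#'
#' @return A list with elements \code{genotypes}
#'   (\linkS4class{GenotypeMatrix}), \code{phenotypes} (data.frame: id, sex,
#'   age, bmi, fmi, total_pa, mvpa, sedentary, maternal_bmi, birth_weight,
#'   maternal_smoking) and \code{diagnostics} (realized score R-squared,
#'   realized per-trait heritability, confounder correlations, structural
#'   z-values).
#' @examples
#' sim <- simulateCohort(500, syntheticBmiPanel(), TrueParams(),
#'                       n_background = 50, seed = 7)
#' head(sim$phenotypes)
#' sim$diagnostics$realized_score_r2
#' @export
simulateCohort <- function(n, panel, truth = TrueParams(),
                           n_background = 2000L, seed, fmi_cor = 0.94) {
  stopifnot(is(truth, "TrueParams"))
  validObject(truth)
  if (n < 100) stop("n must be at least 100")
  if (truth@h2_activity > 0 && n_background < 1)
    stop("h2_activity > 0 requires background SNPs")
  withSeed(seed, {
    G <- simulateGenotypesCore(n, panel, n_background)
    S <- weightedAllelicScore(G, scale = "allele_count")
    s <- as.numeric(scale(S))
    U <- rnorm(n)
    a <- sqrt(truth@score_r2)
    cx <- truth@conf_exposure
    cy <- truth@conf_outcome
    h2 <- truth@h2_activity
    traits <- c("total_pa", "mvpa", "sedentary")

    # per-trait polygenic components from standardized background dosages
    gcomp <- matrix(0, n, 3L, dimnames = list(NULL, traits))
    if (h2 > 0) {
      rd <- SummarizedExperiment::rowData(G)
      bg <- rownames(G)[!rd$instrument]
      p <- rd$eaf[!rd$instrument]
      Z <- sweep(imputedDosage(G, bg), 2L, 2 * p, "-")
      Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
      for (t in traits) {
        graw <- drop(Z %*% rnorm(length(bg), sd = 1 / sqrt(length(bg))))
        gcomp[, t] <- graw * sqrt(h2 / var(graw))
      }
    }

    reverse <- truth@beta_reverse != 0
    if (reverse) {
      y <- matrix(NA_real_, n, 3L, dimnames = list(NULL, traits))
      vey <- 1 - cy^2 - h2
      if (vey < 0) stop("variance bookkeeping infeasible: outcome components sum above 1")
      for (t in traits)
        y[, t] <- cy * U + gcomp[, t] + rnorm(n, sd = sqrt(vey))
      ybar <- as.numeric(scale(rowMeans(y)))
      br <- truth@beta_reverse
      covyU <- cov(ybar, U)
      vex <- 1 - a^2 - cx^2 - br^2 - 2 * br * cx * covyU
      if (vex < 0) stop("variance bookkeeping infeasible: exposure components sum above 1")
      x <- a * s + cx * U + br * ybar + rnorm(n, sd = sqrt(vex))
    } else {
      vex <- 1 - a^2 - cx^2
      if (vex < 0) stop("variance bookkeeping infeasible: exposure components sum above 1")
      x <- a * s + cx * U + rnorm(n, sd = sqrt(vex))
      y <- matrix(NA_real_, n, 3L, dimnames = list(NULL, traits))
      for (t in traits) {
        bt <- truth@beta_forward[[t]]
        vey <- 1 - bt^2 - cy^2 - 2 * bt * cx * cy - h2
        if (vey < 0) stop("variance bookkeeping infeasible: outcome components sum above 1")
        y[, t] <- bt * x + cy * U + gcomp[, t] + rnorm(n, sd = sqrt(vey))
      }
    }

    fmi_z <- fmi_cor * x + sqrt(1 - fmi_cor^2) * rnorm(n)

    sex <- factor(ifelse(rbinom(n, 1L, 2252 / 4296) == 1L, "F", "M"),
                  levels = c("F", "M"))
    f <- sex == "F"
    age <- rnorm(n, 140.8, 2.8)
    raw <- function(z, mF, sF, mM, sM) ifelse(f, mF + sF * z, mM + sM * z)
    sdlogF <- log(24.9 / 9.9) / (2 * qnorm(0.75))
    sdlogM <- log(38.5 / 15.9) / (2 * qnorm(0.75))
    pheno <- data.frame(
      id = colnames(G),
      sex = sex,
      age = age,
      bmi = raw(x, 19.1, 3.4, 18.7, 3.2),
      fmi = raw(fmi_z, 5.5, 2.6, 4.5, 2.6),
      total_pa = raw(y[, "total_pa"], 555.1, 151.7, 664.6, 187.9),
      mvpa = exp(ifelse(f, log(16.0) + sdlogF * y[, "mvpa"],
                        log(25.8) + sdlogM * y[, "mvpa"])),
      sedentary = raw(y[, "sedentary"], 435.6, 63.7, 418.2, 68.5),
      maternal_bmi = 22.9 + 3.7 * (0.4 * U + sqrt(1 - 0.16) * rnorm(n)),
      birth_weight = 3433.8 + 526.7 * (0.2 * U + sqrt(1 - 0.04) * rnorm(n)),
      maternal_smoking = rbinom(n, 1L, plogis(qlogis(0.199) + 0.5 * U)),
      stringsAsFactors = FALSE
    )

    diagnostics <- list(
      realized_score_r2 = cor(x, s)^2,
      realized_h2 = apply(gcomp, 2L, var) / apply(y, 2L, var),
      realized_var_exposure = var(x),
      realized_var_activity = apply(y, 2L, var),
      conf_cor_exposure = cor(x, U),
      conf_cor_activity = cor(y[, "total_pa"], U),
      score_mean = mean(S), score_sd = sd(S),
      structural = data.frame(id = colnames(G), exposure_z = x,
                              fmi_z = fmi_z, y, confounder = U,
                              score = S, stringsAsFactors = FALSE)
    )
    list(genotypes = G, phenotypes = pheno, diagnostics = diagnostics)
  })
}

#' @importFrom stats plogis qlogis cov
NULL

#' Simulate a minute-level accelerometer count trace
#'
#' Emits integer counts per minute such that each day contains exactly the
#' requested number of minutes above the moderate-to-vigorous cut-point and
#' below the sedentary cut-point; remaining minutes fall in the middle band
#' and are adjusted towards the requested per-day mean counts (within the
#' band's limits). Minute order within a day is random.
#'
#' @param mean_counts target mean counts/minute per day.
#' @param mvpa_frac,sedentary_frac fractions of wear minutes in the
#'   moderate-to-vigorous and sedentary bands; must lie in [0, 1] and sum to
#'   at most 1.
#' @param n_days number of days.
#' @param wear_minutes wear minutes per day (0 gives an empty trace).
#' @param seed integer seed.
#' @param id individual identifier for the output.
#' @param mvpa_cut,sedentary_cut intensity cut-points (counts/min).
#'
#' @return data.frame with columns id, day, minute, counts.
#' @examples
#' tr <- simulateMinuteCounts(600, 0.05, 0.6, n_days = 3,
#'                            wear_minutes = 600, seed = 1)
#' summarizeActigraphy(tr)
#' @export
simulateMinuteCounts <- function(mean_counts, mvpa_frac, sedentary_frac,
                                 n_days, wear_minutes, seed, id = "ind1",
                                 mvpa_cut = 3600L, sedentary_cut = 199L) {
  if (mvpa_frac < 0 || mvpa_frac > 1 || sedentary_frac < 0 ||
      sedentary_frac > 1 || mvpa_frac + sedentary_frac > 1)
    stop("inconsistent band fractions: each in [0, 1] and summing to at most 1")
  if (wear_minutes < 0) stop("wear_minutes must be non-negative")
  empty <- data.frame(id = character(), day = integer(), minute = integer(),
                      counts = integer(), stringsAsFactors = FALSE)
  if (wear_minutes == 0 || n_days == 0) return(empty)
  withSeed(seed, {
    m <- as.integer(wear_minutes)
    n_mvpa <- round(mvpa_frac * m)
    n_sed <- min(round(sedentary_frac * m), m - n_mvpa)
    n_mid <- m - n_mvpa - n_sed
    days <- lapply(seq_len(n_days), function(d) {
      sed <- sample(0:(sedentary_cut - 1L), n_sed, replace = TRUE)
      mvpa <- mvpa_cut + 1L + rpois(n_mvpa, 800)
      mid <- sample(sedentary_cut:mvpa_cut, n_mid, replace = TRUE)
      if (n_mid > 0L) {
        # nudge the middle band towards the requested daily mean
        delta <- round(mean_counts * m) - (sum(sed) + sum(mvpa) + sum(mid))
        per <- delta %/% n_mid
        mid <- pmin(pmax(mid + per, sedentary_cut), mvpa_cut)
      }
      counts <- sample(c(sed, mvpa, mid))
      data.frame(id = id, day = d, minute = seq_len(m),
                 counts = as.integer(counts), stringsAsFactors = FALSE)
    })
    do.call(rbind, days)
  })
}
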