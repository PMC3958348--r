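#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef pchisq pnorm pt qnorm qt rbinom rnorm runif sd var
#'   lm.fit glm binomial optimize quantile rpois setNames complete.cases
#'   approx cor
#' @importFrom utils read.delim write.table combn head
NULL

#' SnpPanel: a weighted instrument SNP panel
#'
#' Holds the SNP set used to build a weighted allelic score: identifiers,
#' effect (trait-increasing) alleles, effect-allele frequencies and per-allele
#' weights taken from an external genome-wide association meta-analysis.
#' Weights are oriented to the trait-increasing allele, so all weights are
#' non-negative.
#'
#' @slot snp_id character, unique SNP identifiers.
#' @slot effect_allele character, one of A/C/G/T per SNP.
#' @slot other_allele character, the non-effect allele.
#' @slot eaf numeric, effect-allele frequencies strictly in (0, 1).
#' @slot weight numeric, non-negative per-allele effects on the exposure
#'   (exposure units per allele).
#'
#' @export
setClass("SnpPanel",
  representation(
    snp_id = "character",
    effect_allele = "character",
    other_allele = "character",
    eaf = "numeric",
    weight = "numeric"
  )
)

setValidity("SnpPanel", function(object) {
  msg <- character()
  n <- length(object@snp_id)
  if (n == 0L) msg <- c(msg, "panel must contain at least one SNP")
  if (anyDuplicated(object@snp_id)) msg <- c(msg, "snp_id values must be unique")
  lens <- c(length(object@effect_allele), length(object@other_allele),
            length(object@eaf), length(object@weight))
  if (any(lens != n)) msg <- c(msg, "all slots must have equal length")
  if (any(!object@effect_allele %in% c("A", "C", "G", "T")))
    msg <- c(msg, "effect_allele must be one of A/C/G/T")
  if (any(!is.finite(object@eaf)) || any(object@eaf <= 0) || any(object@eaf >= 1))
    msg <- c(msg, "eaf must lie strictly in (0, 1)")
  if (any(!is.finite(object@weight)) || any(object@weight < 0))
    msg <- c(msg, "weights must be finite and non-negative (orient to the trait-increasing allele)")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: effect-allele dosages with SNP metadata
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"dosage"} assay
#' holding effect-allele dosages in [0, 2] (fractional values permitted for
#' imputed SNPs; missing values allowed), SNPs in rows and individuals in
#' columns. \code{rowData} carries \code{effect_allele}, \code{other_allele},
#' \code{eaf}, \code{weight} and an \code{instrument} flag separating the
#' instrument panel from background (polygenic/null) SNPs.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (any(d < 0 | d > 2, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("effect_allele", "other_allele", "eaf", "weight", "instrument")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique SNP rownames are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique individual ids (colnames) are required")
  if (length(msg)) msg else TRUE
})

#' TrueParams: the planted causal structure of a synthetic cohort
#'
#' Simulation truth for the generative model behind
#' \code{\link{simulateCohort}}. Exactly one causal direction is active:
#' either adiposity affects activity (\code{beta_forward}) or activity
#' affects adiposity (\code{beta_reverse}).
#'
#' @slot beta_forward named numeric of length 3 (total_pa, mvpa, sedentary):
#'   causal effect of the adiposity z-score on each activity z-score (SD/SD).
#' @slot beta_reverse numeric scalar: causal effect of each activity z-score
#'   on adiposity (SD/SD); must be 0 unless beta_forward is all zero.
#' @slot conf_exposure,conf_outcome numeric: loadings of the shared latent
#'   standard-normal confounder on exposure and outcomes (SD units).
#' @slot h2_activity numeric in [0, 1]: additive (SNP) heritability of each
#'   activity trait.
#' @slot score_r2 numeric in [0, 1]: variance in the adiposity z-score
#'   explained by the weighted allelic score.
#'
#' @export
setClass("TrueParams",
  representation(
    beta_forward = "numeric",
    beta_reverse = "numeric",
    conf_exposure = "numeric",
    conf_outcome = "numeric",
    h2_activity = "numeric",
    score_r2 = "numeric"
  )
)

setValidity("TrueParams", function(object) {
  msg <- character()
  if (length(object@beta_forward) != 3L ||
      !identical(names(object@beta_forward), c("total_pa", "mvpa", "sedentary")))
    msg <- c(msg, "beta_forward must be named numeric: total_pa, mvpa, sedentary")
  for (s in c("beta_forward", "beta_reverse", "conf_exposure", "conf_outcome",
              "h2_activity", "score_r2"))
    if (any(!is.finite(slot(object, s))))
      msg <- c(msg, paste(s, "must be finite"))
  if (object@h2_activity < 0 || object@h2_activity > 1)
    msg <- c(msg, "h2_activity must lie in [0, 1]")
  if (object@score_r2 < 0 || object@score_r2 > 1)
    msg <- c(msg, "score_r2 must lie in [0, 1]")
  if (object@beta_reverse != 0 && any(object@beta_forward != 0))
    msg <- c(msg, "only one causal direction may be active (beta_forward or beta_reverse)")
  if (length(msg)) msg else TRUE
})

#' ScoreDefinition: a portable allelic/prediction score
#'
#' SNP set, effect alleles and signed weights defining a score that can be
#' applied to any \linkS4class{GenotypeMatrix} via \code{\link{applyScore}}.
#' For the weighted allelic score the weights come from an external
#' meta-analysis; for genome-wide prediction scores they are discovery-GWAS
#' betas. Missing dosages are imputed as twice the effect-allele frequency.
#'
#' @slot snp_id,effect_allele character.
#' @slot weight numeric, signed per-allele weights.
#' @slot eaf numeric, effect-allele frequencies used for missing-dosage
#'   imputation.
#' @slot label character scalar description of the score.
#'
#' @export
setClass("ScoreDefinition",
  representation(
    snp_id = "character",
    effect_allele = "character",
    weight = "numeric",
    eaf = "numeric",
    label = "character"
  )
)

setValidity("ScoreDefinition", function(object) {
  msg <- character()
  n <- length(object@snp_id)
  if (n == 0L) msg <- c(msg, "score must contain at least one SNP")
  if (anyDuplicated(object@snp_id)) msg <- c(msg, "snp_id values must be unique")
  if (any(!is.finite(object@weight))) msg <- c(msg, "weights must be finite")
  if (length(object@effect_allele) != n || length(object@weight) != n ||
      length(object@eaf) != n)
    msg <- c(msg, "slot lengths must agree")
  if (length(msg)) msg else TRUE
})

#' RegressionResult: a fitted linear or logistic regression
#'
#' @slot coef,se,p,ci_low,ci_high named numeric vectors over model terms.
#' @slot n integer, complete cases used.
#' @slot sigma2 numeric, residual variance (Gaussian fits; NA otherwise).
#' @slot r2 numeric, coefficient of determination (Gaussian fits).
#' @slot df numeric, residual degrees of freedom.
#' @slot family character, "gaussian" or "binomial".
#'
#' @export
setClass("RegressionResult",
  representation(
    coef = "numeric", se = "numeric", p = "numeric",
    ci_low = "numeric", ci_high = "numeric",
    n = "integer", sigma2 = "numeric", r2 = "numeric",
    df = "numeric", family = "character"
  )
)

#' IVFitResult: a two-stage least squares fit with diagnostics
#'
#' @slot beta numeric, the causal estimate (outcome SD per exposure SD when
#'   both variables are standardized).
#' @slot se,ci_low,ci_high,p numeric, normal-theory inference on beta.
#' @slot first_stage_F numeric, nested-model F for the instrument(s) in the
#'   first stage.
#' @slot partial_r2 numeric, incremental first-stage variance explained by
#'   the instrument(s) beyond the covariates.
#' @slot dwh_statistic,dwh_p numeric, the Durbin (control-function) form of
#'   the Durbin-Wu-Hausman endogeneity test, referred to chi-squared(1).
#' @slot n integer; @slot instrument character label.
#'
#' @export
setClass("IVFitResult",
  representation(
    beta = "numeric", se = "numeric", ci_low = "numeric", ci_high = "numeric",
    p = "numeric", first_stage_F = "numeric", partial_r2 = "numeric",
    dwh_statistic = "numeric", dwh_p = "numeric",
    n = "integer", instrument = "character"
  )
)

setValidity("IVFitResult", function(object) {
  msg <- character()
  if (is.finite(object@first_stage_F) && object@first_stage_F < 0)
    msg <- c(msg, "first_stage_F must be non-negative")
  if (is.finite(object@partial_r2) &&
      (object@partial_r2 < 0 || object@partial_r2 > 1))
    msg <- c(msg, "partial_r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GRM: a genetic relationship matrix
#'
#' @slot matrix symmetric n x n numeric matrix of standardized genome-wide
#'   genetic similarity.
#' @slot ids character, individual identifiers.
#' @slot n_snps integer, SNPs used after the frequency floor.
#'
#' @export
setClass("GRM",
  representation(matrix = "matrix", ids = "character", n_snps = "integer")
)

setValidity("GRM", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (length(object@ids) != nrow(m)) msg <- c(msg, "ids must match matrix dimension")
  if (any(!is.finite(m))) msg <- c(msg, "entries must be finite")
  if (nrow(m) > 0 && max(abs(m - t(m))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' HeritabilityEstimate: GREML variance components
#'
#' @slot sigma2_g,sigma2_e numeric, additive-genetic and residual variance
#'   components (trait-variance units).
#' @slot h2 numeric in [0, 1], sigma2_g / (sigma2_g + sigma2_e).
#' @slot se_h2,se_sigma2_g,se_sigma2_e numeric standard errors.
#' @slot loglik numeric, maximized restricted log-likelihood.
#' @slot lrt,lrt_p numeric, likelihood-ratio test of h2 = 0 against the
#'   boundary mixture 0.5*chi2(0) + 0.5*chi2(1).
#' @slot iterations integer, likelihood evaluations used; @slot converged logical.
#'
#' @export
setClass("HeritabilityEstimate",
  representation(
    sigma2_g = "numeric", sigma2_e = "numeric", h2 = "numeric",
    se_h2 = "numeric", se_sigma2_g = "numeric", se_sigma2_e = "numeric",
    loglik = "numeric", lrt = "numeric", lrt_p = "numeric",
    iterations = "integer", converged = "logical"
  )
)

setValidity("HeritabilityEstimate", function(object) {
  msg <- character()
  if (object@sigma2_g < -1e-10 || object@sigma2_e < -1e-10)
    msg <- c(msg, "variance components must be non-negative")
  if (object@h2 < -1e-10 || object@h2 > 1 + 1e-10)
    msg <- c(msg, "h2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MetaResult: inverse-variance-weighted fixed-effects pooling
#'
#' @slot beta,se,ci_low,ci_high,p numeric, the pooled estimate with
#'   normal-theory inference.
#' @slot Q numeric, Cochran's heterogeneity statistic; @slot df integer,
#'   k - 1; @slot p_heterogeneity numeric.
#' @slot k integer, studies pooled.
#'
#' @export
setClass("MetaResult",
  representation(
    beta = "numeric", se = "numeric", ci_low = "numeric", ci_high = "numeric",
    p = "numeric", Q = "numeric", df = "integer",
    p_heterogeneity = "numeric", k = "integer"
  )
)

setValidity("MetaResult", function(object) {
  msg <- character()
  if (object@Q < -1e-10) msg <- c(msg, "Q must be non-negative")
  if (object@df != object@k - 1L) msg <- c(msg, "df must equal k - 1")
  if (length(msg)) msg else TRUE
})
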