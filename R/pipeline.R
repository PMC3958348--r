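#' Derive the standardised analysis variables
#'
#' Adds sex-specific z-score columns for the adiposity exposures and
#' activity outcomes (moderate-to-vigorous activity is log-transformed
#' first, with a +1 min/d offset only if zeros are present) and records the
#' raw-scale SD of each outcome for raw-unit reporting.
#'
#' @param phenotypes data.frame with columns sex, age, bmi, fmi, total_pa,
#'   mvpa, sedentary (missing columns are skipped).
#' @return list: \code{phenotypes} with added \code{*_z} columns,
#'   \code{raw_sd} named vector of raw-scale outcome SDs.
#' @export
prepareAnalysisVariables <- function(phenotypes) {
  ph <- phenotypes
  raw_sd <- c()
  for (v in intersect(c("bmi", "fmi", "total_pa", "mvpa", "sedentary"),
                      names(ph))) {
    vals <- ph[[v]]
    if (v == "mvpa") {
      offset <- if (any(vals == 0, na.rm = TRUE)) 1 else 0
      zsrc <- logTransform(vals, offset = offset)
    } else zsrc <- vals
    ph[[paste0(v, "_z")]] <- zscoreBySex(zsrc, ph$sex)
    raw_sd[v] <- sd(vals, na.rm = TRUE)
  }
  list(phenotypes = ph, raw_sd = raw_sd)
}

mrRow <- function(exposure, outcome, sex, ols, iv, raw_sd, instrument) {
  data.frame(
    exposure = exposure, outcome = outcome, sex = sex, n = iv@n,
    ols_beta = estimate(ols)[["x"]], ols_se = stdError(ols)[["x"]],
    ols_ci_low = ols@ci_low[["x"]], ols_ci_high = ols@ci_high[["x"]],
    ols_p = pValue(ols)[["x"]],
    ols_raw = estimate(ols)[["x"]] * raw_sd,
    ols_raw_ci_low = ols@ci_low[["x"]] * raw_sd,
    ols_raw_ci_high = ols@ci_high[["x"]] * raw_sd,
    first_stage_F = iv@first_stage_F, partial_r2 = iv@partial_r2,
    iv_beta = iv@beta, iv_se = iv@se,
    iv_ci_low = iv@ci_low, iv_ci_high = iv@ci_high, iv_p = iv@p,
    iv_raw = iv@beta * raw_sd,
    iv_raw_ci_low = iv@ci_low * raw_sd,
    iv_raw_ci_high = iv@ci_high * raw_sd,
    dwh_p = iv@dwh_p, instrument = instrument,
    weak_instrument = iv@first_stage_F < 10,
    stringsAsFactors = FALSE
  )
}

#' Forward Mendelian randomization: adiposity on activity
#'
#' For each exposure x outcome pair, fits the age-adjusted observational
#' regression and the two-stage least squares fit instrumented by the
#' weighted allelic score, both on sex-specific z-scores, and reports
#' first-stage diagnostics, the Durbin-Wu-Hausman p-value and raw-unit
#' conversions (z coefficient times the raw outcome SD, computed from the
#' unrounded coefficient).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} carrying the instrument
#'   panel.
#' @param phenotypes phenotype data.frame (see
#'   \code{\link{prepareAnalysisVariables}}).
#' @param exposures,outcomes variable names (defaults: bmi/fmi and the three
#'   activity traits).
#' @param covariates covariate column names (default "age").
#' @param by_sex also run sex-stratified fits (separate models per sex).
#'
#' @return data.frame, one row per exposure x outcome (x sex stratum).
#' @export
runForwardMR <- function(genotypes, phenotypes,
                         exposures = c("bmi", "fmi"),
                         outcomes = c("total_pa", "mvpa", "sedentary"),
                         covariates = "age", by_sex = FALSE) {
  prep <- prepareAnalysisVariables(phenotypes)
  ph <- prep$phenotypes
  score <- weightedAllelicScore(genotypes)
  ph <- ph[match(colnames(genotypes), ph$id), ]
  strata <- list(all = rep(TRUE, nrow(ph)))
  if (by_sex)
    for (lev in levels(ph$sex)) strata[[lev]] <- ph$sex == lev
  rows <- list()
  for (sname in names(strata)) {
    sel <- strata[[sname]]
    for (ex in exposures) for (out in outcomes) {
      xz <- ph[[paste0(ex, "_z")]][sel]
      yz <- ph[[paste0(out, "_z")]][sel]
      cv <- as.matrix(ph[sel, covariates, drop = FALSE])
      sc <- score[sel]
      ols <- olsFit(yz, xz, covariates = cv)
      iv <- tslsFit(yz, xz, sc, covariates = cv,
                    instrument_label = "weighted allelic score")
      keep <- !is.na(yz) & !is.na(xz) & complete.cases(cv) & !is.na(sc)
      raw_sd <- sd(phenotypes[[out]][sel][keep], na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        mrRow(ex, out, sname, ols, iv, raw_sd, "weighted allelic score")
    }
  }
  do.call(rbind, rows)
}

#' Instrument sensitivity: single strongest SNP vs remainder score vs full score
#'
#' Selects the single SNP with the largest first-stage F for the exposure,
#' then fits three instruments per outcome (that SNP alone; the weighted
#' score of the remaining SNPs; the full score) and tests heterogeneity of
#' the single-SNP vs remainder-score estimates with Cochran's Q. All
#' C(J, 2) SNP pairs are additionally fitted (each pair as a 2-SNP weighted
#' score) for \code{pair_outcome}, yielding the z-statistic distribution and
#' its median coefficient, with pairs containing the strongest SNP flagged.
#'
#' @inheritParams runForwardMR
#' @param exposure single exposure name (default "bmi").
#' @param pair_outcome outcome used for the pairwise distribution (default
#'   the first outcome).
#'
#' @return list: \code{top_snp}, \code{comparison} (per outcome x
#'   instrument), \code{heterogeneity} (per outcome Q between single-SNP and
#'   remainder-score estimates), \code{pairs} (per-pair beta, se, z,
#'   has_top).
#' @export
runInstrumentSensitivity <- function(genotypes, phenotypes,
                                     exposure = "bmi",
                                     outcomes = c("total_pa", "mvpa",
                                                  "sedentary"),
                                     covariates = "age",
                                     pair_outcome = outcomes[1L]) {
  panel <- snpPanel(genotypes)
  if (length(panel) < 3L) stop("at least 3 panel SNPs required")
  prep <- prepareAnalysisVariables(phenotypes)
  ph <- prep$phenotypes[match(colnames(genotypes), prep$phenotypes$id), ]
  xz <- ph[[paste0(exposure, "_z")]]
  cv <- as.matrix(ph[, covariates, drop = FALSE])
  D <- imputedDosage(genotypes, panel@snp_id, eaf = panel@eaf)

  fs <- vapply(seq_len(length(panel)), function(j)
    firstStageDiagnostics(xz, D[, j], covariates = cv)[["F"]], numeric(1))
  top <- which.max(fs)
  top_id <- panel@snp_id[top]

  subPanel <- function(idx) SnpPanel(panel@snp_id[idx],
                                     panel@effect_allele[idx],
                                     panel@eaf[idx], panel@weight[idx],
                                     other_allele = panel@other_allele[idx])
  rest_score <- weightedAllelicScore(genotypes, subPanel(-top))
  full_score <- weightedAllelicScore(genotypes, panel)

  comparison <- list(); het <- list()
  for (out in outcomes) {
    yz <- ph[[paste0(out, "_z")]]
    fits <- list(
      single = tslsFit(yz, xz, D[, top], covariates = cv,
                       instrument_label = paste("single SNP", top_id)),
      remainder = tslsFit(yz, xz, rest_score, covariates = cv,
                          instrument_label = "remainder score"),
      full = tslsFit(yz, xz, full_score, covariates = cv,
                     instrument_label = "full score")
    )
    for (nm in names(fits)) {
      f <- fits[[nm]]
      comparison[[length(comparison) + 1L]] <- data.frame(
        outcome = out, instrument = nm, beta = f@beta, se = f@se,
        ci_low = f@ci_low, ci_high = f@ci_high, p = f@p,
        first_stage_F = f@first_stage_F, partial_r2 = f@partial_r2,
        dwh_p = f@dwh_p, stringsAsFactors = FALSE)
    }
    q <- cochranQ(c(fits$single@beta, fits$remainder@beta),
                  c(fits$single@se, fits$remainder@se))
    het[[length(het) + 1L]] <- data.frame(
      outcome = out, Q = q[["Q"]], df = q[["df"]], p_het = q[["p"]],
      stringsAsFactors = FALSE)
  }

  yz <- ph[[paste0(pair_outcome, "_z")]]
  prs <- combn(length(panel), 2L)
  w <- panel@weight
  pair_rows <- lapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1L, k]; j <- prs[2L, k]
    inst <- w[i] * D[, i] + w[j] * D[, j]
    f <- tslsFit(yz, xz, inst, covariates = cv,
                 instrument_label = "pair")
    data.frame(snp1 = panel@snp_id[i], snp2 = panel@snp_id[j],
               beta = f@beta, se = f@se, z = f@beta / f@se,
               has_top = i == top || j == top, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  list(top_snp = top_id,
       comparison = do.call(rbind, comparison),
       heterogeneity = do.call(rbind, het),
       pairs = pairs,
       median_pair_beta = stats::median(pairs$beta))
}

#' Instrument-validity confounder checks
#'
#' Each confounder is regressed on the allelic score (linear for continuous,
#' logistic for binary confounders), age-adjusted, alongside the parallel
#' confounder-exposure association for contrast: under valid randomization
#' at conception the score-confounder p-values are uniform while true
#' confounders associate with the exposure.
#'
#' @inheritParams runForwardMR
#' @param confounders confounder column names; binary columns (two unique
#'   non-missing values) get logistic fits.
#' @param exposure exposure used for the contrast column (default "bmi").
#'
#' @return data.frame: confounder, type, score_beta, score_se, score_p,
#'   exposure_beta, exposure_se, exposure_p (betas on the odds-ratio log
#'   scale for binary confounders).
#' @export
confounderChecks <- function(genotypes, phenotypes,
                             confounders = c("maternal_bmi", "birth_weight",
                                             "maternal_smoking"),
                             exposure = "bmi", covariates = "age") {
  prep <- prepareAnalysisVariables(phenotypes)
  ph <- prep$phenotypes[match(colnames(genotypes), prep$phenotypes$id), ]
  score <- weightedAllelicScore(genotypes)
  xz <- ph[[paste0(exposure, "_z")]]
  cv <- as.matrix(ph[, covariates, drop = FALSE])
  rows <- lapply(confounders, function(cf) {
    v <- ph[[cf]]
    binary <- length(unique(v[!is.na(v)])) == 2L
    fitfun <- if (binary) logisticFit else olsFit
    fs <- fitfun(v, score, covariates = cv)
    fx <- fitfun(v, xz, covariates = cv)
    data.frame(confounder = cf,
               type = if (binary) "binary" else "continuous",
               score_beta = estimate(fs)[["x"]],
               score_se = stdError(fs)[["x"]], score_p = pValue(fs)[["x"]],
               exposure_beta = estimate(fx)[["x"]],
               exposure_se = stdError(fx)[["x"]],
               exposure_p = pValue(fx)[["x"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reverse Mendelian randomization via split-sample prediction scores
#'
#' Splits the cohort into random halves; within each half (optionally)
#' estimates the GREML heritability of each activity trait from the
#' background SNPs (after greedy relatedness pruning), runs an age-adjusted
#' GWAS on the trait, builds a prediction score from SNPs at the inclusive
#' discovery p-value threshold, applies that score to the other half and
#' fits two-stage least squares of adiposity on the activity trait. The two
#' half-sample estimates are pooled by inverse-variance-weighted
#' fixed-effects meta-analysis with Cochran's Q; prediction-score
#' instruments with first-stage F below 10 trigger a weak-instrument
#' warning and a machine-readable flag.
#'
#' @inheritParams runForwardMR
#' @param adiposity the outcome-side adiposity variable (default "bmi").
#' @param p_threshold inclusive discovery p-value threshold (default 0.1).
#' @param relatedness_threshold GRM pruning cutoff (default 0.025, i.e.
#'   2.5\%). The effective cutoff is floored at 4/sqrt(M) for an M-SNP GRM,
#'   because smaller off-diagonal entries are sampling noise rather than
#'   relatedness; with genome-wide marker counts the floor is far below
#'   0.025 and the requested cutoff governs.
#' @param seed integer seed for the split.
#' @param greml report GREML heritability per half (default TRUE; the
#'   expensive step at full cohort size).
#' @param maf_floor GRM frequency floor.
#'
#' @return data.frame, one row per activity trait: half-specific estimates,
#'   SEs, first-stage Fs, score sizes, heritability estimates (NA when
#'   \code{greml = FALSE}), pooled beta/se/CI/p, Q, p_het and
#'   weak_instrument flag. Traits whose prediction score is empty get NA
#'   estimates rather than failing the run.
#' @export
runReverseMR <- function(genotypes, phenotypes, adiposity = "bmi",
                         outcomes = c("total_pa", "mvpa", "sedentary"),
                         covariates = "age", p_threshold = 0.1,
                         relatedness_threshold = 0.025, seed,
                         greml = TRUE, maf_floor = 0.01) {
  rd <- SummarizedExperiment::rowData(genotypes)
  if (!any(!rd$instrument)) stop("background SNPs required for prediction scores")
  prep <- prepareAnalysisVariables(phenotypes)
  ph <- prep$phenotypes[match(colnames(genotypes), prep$phenotypes$id), ]
  halves <- splitSample(colnames(genotypes), seed = seed)

  half_data <- lapply(halves, function(ids) {
    sel <- match(ids, colnames(genotypes))
    list(G = genotypes[, sel], ph = ph[sel, ])
  })

  h2 <- lapply(half_data, function(h) {
    if (!greml) return(setNames(rep(NA_real_, length(outcomes)), outcomes))
    A <- computeGRM(h$G, maf_floor = maf_floor)
    # below ~4/sqrt(M) an off-diagonal GRM entry is indistinguishable from
    # sampling noise, so the relatedness cutoff is floored there; with a
    # genome-wide marker set the requested cutoff governs unchanged
    eff_threshold <- max(relatedness_threshold, 4 / sqrt(A@n_snps))
    kept <- pruneRelated(A, threshold = eff_threshold)
    sel <- match(kept, A@ids)
    Ak <- new("GRM", matrix = A@matrix[sel, sel], ids = kept,
              n_snps = A@n_snps)
    vapply(outcomes, function(out) {
      yy <- h$ph[[paste0(out, "_z")]][sel]
      cvk <- as.matrix(h$ph[sel, covariates, drop = FALSE])
      ok <- !is.na(yy) & complete.cases(cvk)
      sub <- new("GRM", matrix = Ak@matrix[ok, ok], ids = Ak@ids[ok],
                 n_snps = Ak@n_snps)
      heritability(remlFit(yy[ok], sub, covariates = cvk[ok, , drop = FALSE]))
    }, numeric(1))
  })

  rows <- list()
  for (out in outcomes) {
    est <- list()
    for (disc in c(1L, 2L)) {
      app <- 3L - disc
      hd <- half_data[[disc]]; ha <- half_data[[app]]
      cvd <- as.matrix(hd$ph[, covariates, drop = FALSE])
      res <- tryCatch({
        gw <- gwasScan(hd$G, hd$ph[[paste0(out, "_z")]], covariates = cvd)
        sc_def <- buildPredictionScore(gw, p_threshold = p_threshold,
                                       label = paste(out, "half", disc))
        sc <- applyScore(ha$G, sc_def)
        cva <- as.matrix(ha$ph[, covariates, drop = FALSE])
        iv <- tslsFit(ha$ph[[paste0(adiposity, "_z")]],
                      ha$ph[[paste0(out, "_z")]], sc, covariates = cva,
                      instrument_label = paste("prediction score", out))
        list(beta = iv@beta, se = iv@se, F = iv@first_stage_F,
             n_snps = length(sc_def), n = iv@n)
      }, error = function(e) {
        message("reverse MR for ", out, " (half ", disc, "): ",
                conditionMessage(e))
        list(beta = NA_real_, se = NA_real_, F = NA_real_,
             n_snps = 0L, n = NA_integer_)
      })
      est[[disc]] <- res
    }
    ok <- is.finite(est[[1L]]$beta) && is.finite(est[[2L]]$beta)
    if (ok) {
      pooled <- ivwFixed(c(est[[1L]]$beta, est[[2L]]$beta),
                         c(est[[1L]]$se, est[[2L]]$se))
      pb <- pooled@beta; pse <- pooled@se
      plo <- pooled@ci_low; phi <- pooled@ci_high; pp <- pooled@p
      Q <- pooled@Q; phet <- pooled@p_heterogeneity
    } else pb <- pse <- plo <- phi <- pp <- Q <- phet <- NA_real_
    weak <- any(c(est[[1L]]$F, est[[2L]]$F) < 10, na.rm = TRUE)
    if (weak)
      warning("weak prediction-score instrument (F < 10) for ", out,
              call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = out,
      beta_A = est[[1L]]$beta, se_A = est[[1L]]$se, F_A = est[[1L]]$F,
      n_snps_A = est[[1L]]$n_snps, h2_A = h2[[1L]][[out]],
      beta_B = est[[2L]]$beta, se_B = est[[2L]]$se, F_B = est[[2L]]$F,
      n_snps_B = est[[2L]]$n_snps, h2_B = h2[[2L]][[out]],
      pooled_beta = pb, pooled_se = pse, pooled_ci_low = plo,
      pooled_ci_high = phi, pooled_p = pp, Q = Q, p_het = phet,
      weak_instrument = weak, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @importFrom graphics hist
NULL

#' Histogram of an allelic score (score-distribution figure)
#'
#' @param score numeric score vector.
#' @param ... passed to \code{graphics::hist}.
#' @export
plotScoreHistogram <- function(score, ...) {
  graphics::hist(score, breaks = 30,
                 main = "Weighted allelic score",
                 xlab = "score (allele-count scale)", ...)
}

#' Histogram of pairwise-instrument z-statistics
#'
#' Overlays the subset of SNP pairs containing the strongest instrument.
#'
#' @param pairs the \code{pairs} element of
#'   \code{\link{runInstrumentSensitivity}}.
#' @export
plotPairZHistogram <- function(pairs) {
  graphics::hist(pairs$z, breaks = 30,
                 main = "Pairwise-instrument z-statistics",
                 xlab = "z statistic", col = "grey80")
  graphics::hist(pairs$z[pairs$has_top], breaks = 30, add = TRUE,
                 col = "firebrick")
}

#' Write a report table as tidy TSV
#'
#' @param table data.frame; @param path file path.
#' @return the path, invisibly. Tables round-trip unchanged through
#'   \code{\link{readReportTable}}.
#' @export
writeReportTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReportTable
#' @export
readReportTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
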