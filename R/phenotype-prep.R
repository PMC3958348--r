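#' Sex-specific standardisation (z-scores)
#'
#' Centers and scales within each sex using the analysis sample's own
#' within-sex mean and SD (denominator n - 1). Missing values propagate and
#' are excluded from the normalisation.
#'
#' @param values numeric vector.
#' @param sex factor (or coercible) with the same length; two levels typical
#'   but any number of groups is standardised group-wise.
#'
#' @return numeric z-score vector with within-sex mean 0 and SD 1.
#' @examples
#' zscoreBySex(c(1, 2, 3), factor(c("F", "F", "F")))
#' @export
zscoreBySex <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  sex <- as.factor(sex)
  z <- rep(NA_real_, length(values))
  for (lev in levels(sex)) {
    idx <- which(sex == lev & !is.na(values))
    if (length(idx) < 2L)
      stop("need at least 2 non-missing values per sex: ", lev)
    s <- sd(values[idx])
    if (!is.finite(s) || s == 0)
      stop("zero within-sex variance for sex: ", lev)
    z[idx] <- (values[idx] - mean(values[idx])) / s
  }
  z
}

#' Natural-log transform for right-skewed outcomes
#'
#' @param values numeric vector, strictly positive unless an \code{offset}
#'   is supplied (the conventional +1 min/d offset handles zero
#'   moderate-to-vigorous minutes; off by default).
#' @param offset added before logging (default 0).
#'
#' @return log(values + offset).
#' @examples
#' logTransform(c(1, 10, 100))
#' logTransform(0, offset = 1)
#' @export
logTransform <- function(values, offset = 0) {
  v <- values + offset
  if (any(v <= 0, na.rm = TRUE))
    stop("non-positive values; supply a positive offset to log-transform them")
  log(v)
}

#' Convert a z-score coefficient to raw units
#'
#' Multiplies a standardised regression coefficient (and, applied to each
#' endpoint, its confidence limits) by the outcome's raw-scale SD.
#'
#' @param z_coefficient coefficient in outcome-SD units.
#' @param outcome_sd raw-scale SD (> 0).
#' @return raw-unit difference.
#' @examples
#' rawUnitConversion(-0.12, 178.4)
#' @export
rawUnitConversion <- function(z_coefficient, outcome_sd) {
  if (any(outcome_sd <= 0)) stop("outcome_sd must be positive")
  z_coefficient * outcome_sd
}

#' Classify weight status from BMI against an age/sex cut-off table
#'
#' Thresholds are linearly interpolated in age within sex from a
#' user-supplied cut-off table (e.g. the International Obesity Task Force
#' reference). Both category boundaries are inclusive: BMI exactly at the
#' overweight (or obese) threshold is classified overweight (or obese).
#'
#' @param bmi,age,sex vectors of equal length (age in months).
#' @param cutoff_table data.frame with columns sex, age_months,
#'   overweight_bmi, obese_bmi covering the (age, sex) range.
#' @return factor with levels normal, overweight, obese.
#' @export
classifyWeightStatus <- function(bmi, age, sex, cutoff_table) {
  stopifnot(all(c("sex", "age_months", "overweight_bmi", "obese_bmi") %in%
                names(cutoff_table)))
  if (any(cutoff_table$obese_bmi < cutoff_table$overweight_bmi))
    stop("obese threshold must be at least the overweight threshold")
  sex <- as.character(sex)
  out <- character(length(bmi))
  for (lev in unique(sex)) {
    tab <- cutoff_table[cutoff_table$sex == lev, ]
    if (nrow(tab) == 0L) stop("cut-off table does not cover sex: ", lev)
    idx <- which(sex == lev)
    a <- age[idx]
    if (any(a < min(tab$age_months) | a > max(tab$age_months)))
      stop("age outside cut-off table range")
    ow <- approx(tab$age_months, tab$overweight_bmi, xout = a,
                 rule = 1)$y
    ob <- approx(tab$age_months, tab$obese_bmi, xout = a, rule = 1)$y
    out[idx] <- ifelse(bmi[idx] >= ob, "obese",
                       ifelse(bmi[idx] >= ow, "overweight", "normal"))
  }
  factor(out, levels = c("normal", "overweight", "obese"))
}

#' Participant-flow percentages
#'
#' Computes per-stage percentages 100 * numerator / denominator, rounded
#' half-up to one decimal place (the convention of reported participant-flow
#' figures).
#'
#' @param flow data.frame with columns label, numerator, denominator
#'   (non-negative integers, numerator <= denominator > 0).
#' @return the flow with an added \code{percent} column.
#' @examples
#' participantFlow(data.frame(label = "attended clinic",
#'                            numerator = 7159, denominator = 11952))
#' @export
participantFlow <- function(flow) {
  stopifnot(all(c("label", "numerator", "denominator") %in% names(flow)))
  if (any(flow$numerator < 0 | flow$denominator <= 0))
    stop("counts must be non-negative with positive denominators")
  if (any(flow$numerator > flow$denominator))
    stop("numerator exceeds denominator")
  flow$percent <- roundHalfUp(100 * flow$numerator / flow$denominator, 1L)
  flow
}

#' Read an age/sex BMI cut-off table (TSV)
#'
#' Four columns: sex, age_months, overweight_bmi, obese_bmi.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCutoffTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write a phenotype table (TSV)
#'
#' @param path file path.
#' @return \code{readPhenotypeTable} returns a data.frame with \code{sex}
#'   as a factor.
#' @export
readPhenotypeTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(d)) d$sex <- factor(d$sex)
  d
}

#' @rdname readPhenotypeTable
#' @param phenotypes a phenotype data.frame.
#' @export
writePhenotypeTable <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
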