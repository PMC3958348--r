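#' Construct a SnpPanel
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param effect_allele character vector (A/C/G/T), the trait-increasing
#'   allele per SNP.
#' @param eaf numeric vector of effect-allele frequencies in (0, 1).
#' @param weight numeric vector of non-negative per-allele weights (exposure
#'   units per effect allele, as estimated in an external meta-analysis).
#' @param other_allele optional character vector of non-effect alleles; if
#'   missing, an arbitrary different base is assigned.
#'
#' @return A \linkS4class{SnpPanel}.
#' @examples
#' SnpPanel(c("rs1", "rs2"), c("A", "G"), eaf = c(0.4, 0.6),
#'          weight = c(0.39, 0.1))
#' @export
SnpPanel <- function(snp_id, effect_allele, eaf, weight, other_allele = NULL) {
  if (is.null(other_allele)) {
    bases <- c("A", "C", "G", "T")
    other_allele <- vapply(effect_allele,
                           function(a) setdiff(bases, a)[1L], character(1))
    names(other_allele) <- NULL
  }
  new("SnpPanel", snp_id = as.character(snp_id),
      effect_allele = as.character(effect_allele),
      other_allele = as.character(other_allele),
      eaf = as.numeric(eaf), weight = as.numeric(weight))
}

#' @rdname SnpPanel-class
#' @aliases snpIds,SnpPanel-method
setMethod("snpIds", "SnpPanel", function(x) x@snp_id)

#' @rdname SnpPanel-class
setMethod("effectAlleles", "SnpPanel", function(x) x@effect_allele)

#' @rdname SnpPanel-class
setMethod("eafs", "SnpPanel", function(x) x@eaf)

#' @rdname SnpPanel-class
setMethod("scoreWeights", "SnpPanel", function(x) x@weight)

#' @rdname SnpPanel-class
setMethod("length", "SnpPanel", function(x) length(x@snp_id))

setMethod("show", "SnpPanel", function(object) {
  cat("SnpPanel with", length(object), "SNPs\n")
  cat("  eaf range:", sprintf("%.3f-%.3f", min(object@eaf), max(object@eaf)), "\n")
  cat("  weight range:", sprintf("%.3f-%.3f", min(object@weight), max(object@weight)), "\n")
})

#' Coerce a SnpPanel to a data.frame
#'
#' @param x a \linkS4class{SnpPanel}.
#' @param ... ignored.
#' @export
as.data.frame.SnpPanel <- function(x, ...) {
  data.frame(snp_id = x@snp_id, effect_allele = x@effect_allele,
             other_allele = x@other_allele, eaf = x@eaf, weight = x@weight,
             stringsAsFactors = FALSE)
}

#' Synthetic 32-SNP adiposity instrument panel
#'
#' A synthetic stand-in for the 32-locus BMI instrument panel used in
#' childhood adiposity Mendelian-randomization work (the published panel's
#' per-SNP weights and frequencies are supplementary material not shipped
#' here). Weights mimic the magnitude profile of genome-wide significant BMI
#' loci, with a single dominant FTO-like locus (weight 0.39); effect-allele
#' frequencies were calibrated once so that the allele-count-scaled weighted
#' score of a Hardy-Weinberg population has mean near 29.6 and SD near 3.9
#' on the 0-64 allele scale.
#'
#' @return A \linkS4class{SnpPanel} of 32 SNPs.
#' @examples
#' panel <- syntheticBmiPanel()
#' length(panel)
#' @export
syntheticBmiPanel <- function() {
  weight <- c(0.39, 0.31, 0.26, 0.23, 0.22, 0.19, 0.18, 0.18, 0.17, 0.17,
              0.16, 0.15, 0.15, 0.14, 0.14, 0.13, 0.13, 0.13, 0.12, 0.12,
              0.11, 0.11, 0.10, 0.10, 0.09, 0.09, 0.08, 0.08, 0.07, 0.07,
              0.06, 0.06)
  eaf <- c(0.671, 0.688, 0.194, 0.607, 0.464, 0.371, 0.536, 0.079, 0.475,
           0.512, 0.324, 0.523, 0.687, 0.170, 0.328, 0.691, 0.720, 0.065,
           0.337, 0.402, 0.663, 0.082, 0.728, 0.696, 0.050, 0.367, 0.273,
           0.665, 0.316, 0.612, 0.537, 0.593)
  ea <- rep(c("A", "C", "G", "T"), 8L)
  oa <- rep(c("G", "T", "A", "C"), 8L)
  SnpPanel(sprintf("snp%02d", seq_len(32L)), ea, eaf, weight,
           other_allele = oa)
}

#' Read / write a SNP panel as TSV
#'
#' Tab-delimited with columns snp_id, effect_allele, other_allele, eaf,
#' weight (PLINK-score-file compatible ordering of the first columns).
#'
#' @param path file path.
#' @return \code{readSnpPanel} returns a \linkS4class{SnpPanel}.
#' @export
readSnpPanel <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  SnpPanel(d$snp_id, d$effect_allele, d$eaf, d$weight,
           other_allele = d$other_allele)
}

#' @rdname readSnpPanel
#' @param panel a \linkS4class{SnpPanel}.
#' @export
writeSnpPanel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
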