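#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of effect-allele dosages in [0, 2] (NA for
#'   missing), SNPs in rows, individuals in columns; dimnames required.
#' @param effect_allele,other_allele,eaf,weight per-SNP metadata vectors
#'   (weight may be NA for background SNPs).
#' @param instrument logical per-SNP flag: TRUE for instrument-panel SNPs,
#'   FALSE for background/polygenic SNPs.
#'
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, effect_allele, other_allele, eaf,
                           weight = NA_real_, instrument = TRUE) {
  m <- nrow(dosage)
  rd <- S4Vectors::DataFrame(
    effect_allele = rep_len(effect_allele, m),
    other_allele = rep_len(other_allele, m),
    eaf = rep_len(eaf, m),
    weight = rep_len(weight, m),
    instrument = rep_len(instrument, m)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd)
  new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix-class
#' @aliases dosage,GenotypeMatrix-method
setMethod("dosage", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeMatrix-class
#' @details \code{snpPanel} extracts the instrument SNPs (with their weights
#'   and frequencies) as a \linkS4class{SnpPanel}.
setMethod("snpPanel", "GenotypeMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  keep <- rd$instrument
  if (!any(keep)) stop("no instrument SNPs in this GenotypeMatrix")
  SnpPanel(rownames(x)[keep], rd$effect_allele[keep], rd$eaf[keep],
           rd$weight[keep], other_allele = rd$other_allele[keep])
})

setMethod("show", "GenotypeMatrix", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("GenotypeMatrix:", nrow(object), "SNPs x", ncol(object), "individuals\n")
  cat("  instrument SNPs:", sum(rd$instrument),
      " background SNPs:", sum(!rd$instrument), "\n")
  d <- SummarizedExperiment::assay(object, "dosage")
  cat("  missing dosages:", sum(is.na(d)), "\n")
})

# Individuals-in-rows dosage submatrix for a set of SNP ids, with missing
# entries imputed as 2*eaf (frequency expectation). Internal workhorse for
# scoring, GWAS and the GRM.
imputedDosage <- function(x, snps = rownames(x), eaf = NULL) {
  d <- t(SummarizedExperiment::assay(x, "dosage")[snps, , drop = FALSE])
  if (is.null(eaf))
    eaf <- SummarizedExperiment::rowData(x)[snps, "eaf"]
  if (anyNA(d)) {
    fill <- matrix(2 * eaf, nrow(d), ncol(d), byrow = TRUE)
    d[is.na(d)] <- fill[is.na(d)]
  }
  d
}
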