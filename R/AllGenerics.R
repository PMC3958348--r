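#' @rdname SnpPanel-class
#' @param x an object.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname SnpPanel-class
#' @export
setGeneric("effectAlleles", function(x) standardGeneric("effectAlleles"))

#' @rdname SnpPanel-class
#' @export
setGeneric("eafs", function(x) standardGeneric("eafs"))

#' @rdname SnpPanel-class
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' @rdname GenotypeMatrix-class
#' @param x an object.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpPanel", function(x) standardGeneric("snpPanel"))

#' Point estimate of a fitted result
#' @param x a fitted result object.
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' Standard error of a fitted result
#' @param x a fitted result object.
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' Two-sided p-value of a fitted result
#' @param x a fitted result object.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' 95\% confidence interval of a fitted result
#' @param x a fitted result object.
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname IVFitResult-class
#' @param x an IVFitResult.
#' @export
setGeneric("firstStageF", function(x) standardGeneric("firstStageF"))

#' @rdname IVFitResult-class
#' @export
setGeneric("partialR2", function(x) standardGeneric("partialR2"))

#' @rdname IVFitResult-class
#' @export
setGeneric("dwhP", function(x) standardGeneric("dwhP"))

#' @rdname HeritabilityEstimate-class
#' @param x a HeritabilityEstimate.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname HeritabilityEstimate-class
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname MetaResult-class
#' @param x a MetaResult.
#' @export
setGeneric("cochranQStat", function(x) standardGeneric("cochranQStat"))
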