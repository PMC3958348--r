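#' Weighted allelic score
#'
#' Per-individual sum of effect-allele dosages weighted by external
#' per-allele effect sizes. Two scales are available: \code{"raw_sum"}
#' returns \eqn{\sum_j w_j g_{ij}}; \code{"allele_count"} (default) rescales
#' by \eqn{J / \sum_j w_j} so the score lives on the 0..2J allele scale and
#' reads as the average number of trait-increasing alleles carried. Missing
#' dosages are imputed as twice the effect-allele frequency before summing.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param panel a \linkS4class{SnpPanel}; defaults to the instrument SNPs of
#'   \code{G}.
#' @param scale "allele_count" or "raw_sum".
#'
#' @return named numeric vector of scores (one per individual).
#' @examples
#' G <- simulateGenotypes(200, syntheticBmiPanel(), seed = 1)
#' s <- weightedAllelicScore(G)
#' mean(s)
#' @export
weightedAllelicScore <- function(G, panel = NULL,
                                 scale = c("allele_count", "raw_sum")) {
  scale <- match.arg(scale)
  if (is.null(panel)) panel <- snpPanel(G)
  missing_snps <- setdiff(panel@snp_id, rownames(G))
  if (length(missing_snps))
    stop("panel SNPs absent from genotypes: ",
         paste(head(missing_snps, 5L), collapse = ", "))
  w <- panel@weight
  if (sum(w) == 0) stop("zero total weight")
  draw <- t(SummarizedExperiment::assay(G, "dosage")[panel@snp_id, ,
                                                     drop = FALSE])
  if (any(rowSums(!is.na(draw)) == 0L))
    stop("individual(s) with all panel dosages missing")
  d <- draw
  if (anyNA(d)) {
    fill <- matrix(2 * panel@eaf, nrow(d), ncol(d), byrow = TRUE)
    d[is.na(d)] <- fill[is.na(d)]
  }
  s <- drop(d %*% w)
  if (scale == "allele_count") s <- s * length(panel) / sum(w)
  names(s) <- colnames(G)
  s
}

#' Per-SNP association scan (GWAS)
#'
#' Ordinary least squares of the outcome on each SNP's dosage plus
#' covariates; per SNP, complete cases are used, and beta, SE and a
#' two-sided p-value from the t distribution are reported. SNPs with
#' (effectively) constant dosage are skipped with a warning.
#'
#' @param G a \linkS4class{GenotypeMatrix}; by default all SNPs are scanned
#'   (restrict with \code{snps}).
#' @param y numeric outcome vector aligned with \code{colnames(G)}.
#' @param covariates optional numeric vector/matrix of covariates (the
#'   standard scan adjusts for age only).
#' @param snps SNP ids to scan (default: all background SNPs if any exist,
#'   otherwise all SNPs).
#'
#' @return data.frame: snp_id, effect_allele, eaf, beta, se, p, n.
#' @export
gwasScan <- function(G, y, covariates = NULL, snps = NULL) {
  rd <- SummarizedExperiment::rowData(G)
  if (is.null(snps))
    snps <- if (any(!rd$instrument)) rownames(G)[!rd$instrument] else rownames(G)
  if (sd(y, na.rm = TRUE) == 0 || all(is.na(y)))
    stop("constant phenotype")
  D <- t(SummarizedExperiment::assay(G, "dosage")[snps, , drop = FALSE])
  W <- designMatrix(length(y), covariates = covariates)
  keep_base <- !is.na(y) & complete.cases(W)
  if (sum(keep_base) <= ncol(W) + 2L)
    stop("too few complete cases for the covariate model")
  out <- data.frame(snp_id = snps,
                    effect_allele = rd[snps, "effect_allele"],
                    eaf = rd[snps, "eaf"],
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = NA_integer_, stringsAsFactors = FALSE)
  if (!anyNA(D[keep_base, , drop = FALSE])) {
    # fast path: residualize y and dosages on covariates (Frisch-Waugh-Lovell)
    Wk <- W[keep_base, , drop = FALSE]
    yk <- y[keep_base]
    Dk <- D[keep_base, , drop = FALSE]
    qw <- qr(Wk)
    yt <- qr.resid(qw, yk)
    Dt <- qr.resid(qw, Dk)
    gss <- colSums(Dt^2)
    const <- gss < 1e-10
    if (any(const))
      warning(sum(const), " SNP(s) with constant dosage skipped")
    beta <- colSums(Dt * yt) / gss
    rss <- sum(yt^2) - beta^2 * gss
    df <- sum(keep_base) - ncol(Wk) - 1L
    se <- sqrt(rss / df / gss)
    tval <- beta / se
    out$beta <- ifelse(const, NA, beta)
    out$se <- ifelse(const, NA, se)
    out$p <- ifelse(const, NA, 2 * pt(-abs(tval), df))
    out$n <- sum(keep_base)
  } else {
    for (j in seq_along(snps)) {
      keep <- keep_base & !is.na(D[, j])
      g <- D[keep, j]
      if (sd(g) < 1e-10) {
        warning("constant dosage for ", snps[j], "; skipped")
        next
      }
      fit <- lsSolve(cbind(W[keep, , drop = FALSE], g = g), y[keep])
      s2 <- fit$rss / fit$df
      se <- sqrt(s2 * fit$XtXinv["g", "g"])
      out$beta[j] <- fit$coef[["g"]]
      out$se[j] <- se
      out$p[j] <- 2 * pt(-abs(out$beta[j] / se), fit$df)
      out$n[j] <- sum(keep)
    }
  }
  out
}

#' Build a genome-wide prediction score from discovery-GWAS results
#'
#' Retains SNPs reaching the (inclusive) discovery p-value threshold and
#' weights each by its signed discovery beta.
#'
#' @param gwas output of \code{\link{gwasScan}}.
#' @param p_threshold inclusive p-value threshold (default 0.1).
#' @param label description carried by the score.
#'
#' @return A \linkS4class{ScoreDefinition}.
#' @export
buildPredictionScore <- function(gwas, p_threshold = 0.1,
                                 label = "prediction score") {
  stopifnot(nrow(gwas) > 0L)
  keep <- !is.na(gwas$p) & gwas$p <= p_threshold
  if (!any(keep)) stop("no SNPs pass the p-value threshold")
  g <- gwas[keep, ]
  new("ScoreDefinition", snp_id = g$snp_id, effect_allele = g$effect_allele,
      weight = g$beta, eaf = g$eaf, label = label)
}

#' Apply a score definition to a genotype matrix
#'
#' Reconciles allele orientation per SNP: when the score's effect allele is
#' the genotype matrix's other allele, the dosage is flipped (2 - g).
#' Missing dosages are imputed as twice the score's effect-allele frequency.
#' Weights are summed (not averaged) across the score's SNPs.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param score a \linkS4class{ScoreDefinition}.
#'
#' @return named numeric vector of scores.
#' @export
applyScore <- function(G, score) {
  stopifnot(is(score, "ScoreDefinition"))
  common <- intersect(score@snp_id, rownames(G))
  if (length(common) == 0L) stop("no overlap between score SNPs and genotypes")
  idx <- match(common, score@snp_id)
  rd <- SummarizedExperiment::rowData(G)[common, ]
  same <- score@effect_allele[idx] == rd$effect_allele
  flipped <- score@effect_allele[idx] == rd$other_allele
  if (any(!same & !flipped))
    stop("unreconcilable allele mismatch for: ",
         paste(head(common[!same & !flipped], 5L), collapse = ", "))
  d <- t(SummarizedExperiment::assay(G, "dosage")[common, , drop = FALSE])
  d[, flipped] <- 2 - d[, flipped]
  if (anyNA(d)) {
    fill <- matrix(2 * score@eaf[idx], nrow(d), ncol(d), byrow = TRUE)
    d[is.na(d)] <- fill[is.na(d)]
  }
  s <- drop(d %*% score@weight[idx])
  names(s) <- colnames(G)
  s
}

setMethod("show", "ScoreDefinition", function(object) {
  cat("ScoreDefinition:", object@label, "\n")
  cat(" ", length(object@snp_id), "SNPs; weight range",
      sprintf("%.4f to %.4f", min(object@weight), max(object@weight)), "\n")
})

#' @rdname SnpPanel-class
setMethod("snpIds", "ScoreDefinition", function(x) x@snp_id)

#' @rdname SnpPanel-class
setMethod("scoreWeights", "ScoreDefinition", function(x) x@weight)

#' @rdname SnpPanel-class
setMethod("length", "ScoreDefinition", function(x) length(x@snp_id))

#' Random split-sample partition
#'
#' Randomly partitions ids into two halves whose sizes differ by at most
#' one (the first half gets the extra id when n is odd).
#'
#' @param ids identifier vector (length >= 2).
#' @param seed integer seed; identical seeds give identical partitions.
#'
#' @return list with elements \code{A} and \code{B}.
#' @examples
#' splitSample(paste0("id", 1:5), seed = 3)
#' @export
splitSample <- function(ids, seed) {
  stopifnot(length(ids) >= 2L)
  withSeed(seed, {
    perm <- sample(ids)
    nA <- ceiling(length(ids) / 2)
    list(A = perm[seq_len(nA)], B = perm[-seq_len(nA)])
  })
}

#' Read / write a score definition as TSV
#'
#' Columns: snp_id, effect_allele, weight, eaf (PLINK-style score file plus
#' a frequency column for missing-dosage imputation).
#'
#' @param path file path.
#' @param label score label used on read.
#' @return \code{readScoreDefinition} returns a
#'   \linkS4class{ScoreDefinition}.
#' @export
readScoreDefinition <- function(path, label = basename(path)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  new("ScoreDefinition", snp_id = d$snp_id,
      effect_allele = d$effect_allele, weight = d$weight, eaf = d$eaf,
      label = label)
}

#' @rdname readScoreDefinition
#' @param score a \linkS4class{ScoreDefinition}.
#' @export
writeScoreDefinition <- function(score, path) {
  write.table(data.frame(snp_id = score@snp_id,
                         effect_allele = score@effect_allele,
                         weight = score@weight, eaf = score@eaf),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom stats pt
NULL
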