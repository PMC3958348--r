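#' Write / read genotype dosages as PLINK-.raw-style text
#'
#' Tab-delimited with columns FID, IID, PAT, MAT, SEX, PHENOTYPE followed by
#' one dosage column per SNP named \code{<snp_id>_<effect_allele>}.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @export
writeGenotypeRaw <- function(G, path) {
  d <- t(SummarizedExperiment::assay(G, "dosage"))
  rd <- SummarizedExperiment::rowData(G)
  colnames(d) <- paste0(rownames(G), "_", rd$effect_allele)
  out <- data.frame(FID = colnames(G), IID = colnames(G), PAT = 0L, MAT = 0L,
                    SEX = 0L, PHENOTYPE = -9L, check.names = FALSE)
  out <- cbind(out, d)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeRaw
#' @param panel optional \linkS4class{SnpPanel} supplying effect-allele
#'   frequencies, weights and the instrument flag; SNPs not in the panel are
#'   treated as background with sample-frequency eaf.
#' @return \code{readGenotypeRaw} returns a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeRaw <- function(path, panel = NULL) {
  d <- read.delim(path, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp_cols <- setdiff(names(d), meta)
  ids <- as.character(d$IID)
  m <- t(as.matrix(d[, snp_cols, drop = FALSE]))
  snp_id <- sub("_[ACGT]$", "", snp_cols)
  ea <- sub("^.*_", "", snp_cols)
  rownames(m) <- snp_id
  colnames(m) <- ids
  eaf <- rowMeans(m, na.rm = TRUE) / 2
  weight <- rep(NA_real_, length(snp_id))
  inst <- rep(FALSE, length(snp_id))
  bases <- c("A", "C", "G", "T")
  oa <- vapply(ea, function(a) setdiff(bases, a)[1L], character(1))
  if (!is.null(panel)) {
    hit <- match(snp_id, panel@snp_id)
    ok <- !is.na(hit)
    eaf[ok] <- panel@eaf[hit[ok]]
    weight[ok] <- panel@weight[hit[ok]]
    oa[ok] <- panel@other_allele[hit[ok]]
    inst[ok] <- TRUE
  }
  eaf <- pmin(pmax(eaf, 1e-6), 1 - 1e-6)
  GenotypeMatrix(m, effect_allele = ea, other_allele = unname(oa),
                 eaf = unname(eaf), weight = weight, instrument = inst)
}

#' Write a minimal dosage VCF
#'
#' Single-sample-block VCFv4.2 with GT (rounded dosage) and DS (dosage)
#' fields; placeholder chromosome/position coordinates in row order.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @export
writeGenotypeVcf <- function(G, path) {
  d <- SummarizedExperiment::assay(G, "dosage")
  rd <- SummarizedExperiment::rowData(G)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(G)), collapse = "\t")), con)
  gt_of <- function(x) {
    r <- round(x)
    out <- c("0/0", "0/1", "1/1")[r + 1L]
    out[is.na(x)] <- "./."
    out
  }
  for (i in seq_len(nrow(d))) {
    gt <- gt_of(d[i, ])
    ds <- ifelse(is.na(d[i, ]), ".", format(d[i, ], trim = TRUE))
    writeLines(paste(c("1", i, rownames(G)[i], rd$other_allele[i],
                       rd$effect_allele[i], ".", "PASS", ".", "GT:DS",
                       paste(gt, ds, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the DS field when present, otherwise ALT-allele counts from GT.
#' Requires the vcfR package.
#'
#' @param path VCF path.
#' @param panel optional \linkS4class{SnpPanel} (as in
#'   \code{\link{readGenotypeRaw}}).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path, panel = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- matrix(vapply(gt, function(g) {
      if (is.na(g) || g %in% c("./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1L]]))
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  rownames(m) <- fix[, "ID"]
  ea <- fix[, "ALT"]
  oa <- fix[, "REF"]
  eaf <- pmin(pmax(rowMeans(m, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
  weight <- rep(NA_real_, nrow(m))
  inst <- rep(FALSE, nrow(m))
  if (!is.null(panel)) {
    hit <- match(rownames(m), panel@snp_id)
    ok <- !is.na(hit)
    eaf[ok] <- panel@eaf[hit[ok]]
    weight[ok] <- panel@weight[hit[ok]]
    inst[ok] <- TRUE
  }
  GenotypeMatrix(m, effect_allele = unname(ea), other_allele = unname(oa),
                 eaf = unname(eaf), weight = weight, instrument = inst)
}

#' Read an analysis configuration (YAML)
#'
#' A single YAML file holding the simulation truth, seed, thresholds and
#' variable lists; missing entries take package defaults.
#'
#' @param path YAML path.
#' @return a named list (see \code{\link{defaultAnalysisConfig}}).
#' @export
readAnalysisConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the yaml package")
  user <- yaml::read_yaml(path)
  cfg <- defaultAnalysisConfig()
  cfg[names(user)] <- user
  validateAnalysisConfig(cfg)
  cfg
}

#' Default analysis configuration
#'
#' @return named list: exposures, outcomes, covariates, p_threshold,
#'   relatedness_threshold, accelerometry thresholds, simulation block
#'   (n, n_background, truth parameters) and seed.
#' @export
defaultAnalysisConfig <- function() {
  list(
    exposures = c("bmi", "fmi"),
    outcomes = c("total_pa", "mvpa", "sedentary"),
    covariates = "age",
    p_threshold = 0.1,
    relatedness_threshold = 0.025,
    min_wear_hours = 10, min_valid_days = 3,
    mvpa_cut = 3600, sedentary_cut = 199,
    by_sex = FALSE,
    simulation = list(n = 4296L, n_background = 2000L,
                      beta_forward = c(total_pa = -0.18, mvpa = -0.18,
                                       sedentary = 0.20),
                      beta_reverse = 0, conf_exposure = 0.3,
                      conf_outcome = 0.3, h2_activity = 0.21,
                      score_r2 = 0.028),
    seed = 1L
  )
}

validateAnalysisConfig <- function(cfg) {
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$relatedness_threshold > 0,
            cfg$min_wear_hours >= 0, cfg$min_valid_days >= 1,
            cfg$mvpa_cut > cfg$sedentary_cut)
  invisible(cfg)
}
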