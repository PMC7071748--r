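#' Write a variant panel to a tab-delimited dosage file
#'
#' One row per variant: `variant_id`, `chromosome`, `position`,
#' `coded_allele`, `other_allele`, `CAF`, `imputation_quality`, then one
#' dosage column per sample. Positions are 1-based.
#'
#' @param panel A `variant_panel`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dosage <- function(panel, path) {
  meta <- panel$variant_meta
  dos <- t(panel$dosages)                       # variants x samples
  df <- data.frame(variant_id = meta$variant_id,
                   chromosome = meta$chromosome,
                   position = meta$position,
                   coded_allele = meta$coded_allele,
                   other_allele = meta$other_allele,
                   CAF = meta$CAF,
                   imputation_quality = meta$imputation_quality,
                   stringsAsFactors = FALSE)
  if (ncol(dos) > 0) df <- cbind(df, as.data.frame(dos))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited dosage file into a variant panel
#'
#' @param path Dosage file written by [write_dosage()].
#' @param subgroup_id Label to attach to the panel.
#' @return A `variant_panel`.
#' @export
read_dosage <- function(path, subgroup_id = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  fixed <- c("variant_id", "chromosome", "position", "coded_allele",
             "other_allele", "CAF", "imputation_quality")
  missing_cols <- setdiff(fixed, names(df))
  if (length(missing_cols))
    stop("malformed dosage file, missing columns: ",
         paste(missing_cols, collapse = ", "))
  sample_cols <- setdiff(names(df), fixed)
  dos <- t(as.matrix(df[, sample_cols, drop = FALSE]))
  colnames(dos) <- df$variant_id
  rownames(dos) <- sample_cols
  meta <- df[, fixed]
  meta$chromosome <- as.character(meta$chromosome)
  meta$monomorphic <- meta$CAF == 0 | meta$CAF == 1
  structure(list(subgroup_id = subgroup_id, variant_meta = meta,
                 dosages = dos),
            class = "variant_panel")
}

#' Read a phenotype/covariate table
#'
#' @param path Tab-delimited file with a `sample_id` column followed by
#'   trait and covariate columns.
#' @param traits Character vector naming the trait columns; the remaining
#'   non-id columns are treated as covariates.
#' @return A `phenotype_table`.
#' @export
read_phenotypes <- function(path, traits) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype file lacks sample_id")
  missing_tr <- setdiff(traits, names(df))
  if (length(missing_tr))
    stop("phenotype file lacks trait columns: ",
         paste(missing_tr, collapse = ", "))
  covs <- setdiff(names(df), c("sample_id", traits))
  attr(df, "trait_names") <- traits
  attr(df, "covariate_names") <- covs
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write association or meta-analysis summary statistics
#'
#' METAL-style tab-delimited layout: MarkerName, Chromosome, Position,
#' Allele1 (coded), Allele2 (other), Freq1, ImpQuality, Effect, StdErr,
#' Zscore, P-value, N, Trait, Subgroup, plus any extra columns present
#' (QStat, QDf, QPval, NStudies for meta output).
#'
#' @param tab A data.frame of association records (see [run_univariate()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary-statistics file written by [write_summary()]
#'
#' @param path Input file path.
#' @return A data.frame; a header-only file yields zero rows.
#' @export
read_summary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(Chromosome = "character"))
}

#' Import a VCF file as a variant panel
#'
#' Per-sample dosages are taken from the given genotype FORMAT field
#' (default `DS`, values in [0, 2]); when that field is absent, hard
#' dosages are derived from the GT calls and the panel is flagged
#' (`hard_calls = TRUE`). Imputation quality is read from the INFO field
#' named by `quality_key` (default `R2`); variants lacking it get quality 1.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param dosage_field FORMAT key holding the dosage (default "DS").
#' @param quality_key INFO key holding imputation quality (default "R2").
#' @param subgroup_id Label for the panel.
#' @return A `variant_panel` with an extra `hard_calls` element.
#' @export
read_vcf <- function(path, dosage_field = "DS", quality_key = "R2",
                     subgroup_id = basename(path)) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  hard_calls <- FALSE
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (dosage_field %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = dosage_field, as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(gsub("\\|", "/", g), "/")[[1]] == "1")
    }
    ds <- apply(gt, c(1, 2), count_alt)
    hard_calls <- TRUE
    warning("dosage field '", dosage_field,
            "' absent; falling back to hard calls from GT")
  }
  info <- vcfR::extract.info(v, element = quality_key, as.numeric = TRUE)
  if (all(is.na(info))) info <- rep(1, nrow(fix))
  info[is.na(info)] <- 1
  dos <- t(ds)                                   # samples x variants
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  caf <- colMeans(dos, na.rm = TRUE) / 2
  meta <- data.frame(
    chromosome = as.character(fix[, "CHROM"]),
    position = as.integer(fix[, "POS"]),
    variant_id = ids,
    coded_allele = fix[, "ALT"],
    other_allele = fix[, "REF"],
    CAF = caf,
    imputation_quality = info,
    monomorphic = caf == 0 | caf == 1,
    stringsAsFactors = FALSE
  )
  structure(list(subgroup_id = subgroup_id, variant_meta = meta,
                 dosages = dos, hard_calls = hard_calls),
            class = "variant_panel")
}

#' Read a previously-reported-regions file
#'
#' Tab-delimited with columns `chromosome`, `position`, `variant_id`,
#' `trait`, `source`.
#'
#' @param path Input file path.
#' @return A data.frame.
#' @export
read_known_regions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}
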