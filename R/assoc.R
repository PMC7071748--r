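#' Phenotype quality control: 4-standard-deviation outlier exclusion
#'
#' Per trait, values farther than `n_sd` standard deviations from the mean
#' of the trait over the pooled study population (computed before any
#' exclusion) are set missing. The default mirrors the common GWAS
#' convention of excluding values exceeding four standard deviations.
#'
#' @param phenos A `phenotype_table` (or list of per-subgroup tables, in
#'   which case pooled means/SDs are used and the list is returned).
#' @param traits Trait column names to screen.
#' @param n_sd Exclusion threshold in standard deviations (default 4).
#' @return The table(s) with outliers set to `NA`; attribute
#'   `exclusion_log` is a data.frame recording each excluded value.
#' @export
qc_phenotypes <- function(phenos, traits, n_sd = 4) {
  single <- !is.data.frame(phenos[[1]])
  tables <- if (single) list(phenos) else phenos
  log <- data.frame(subgroup = integer(0), sample_id = character(0),
                    trait = character(0), value = numeric(0),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    pooled <- unlist(lapply(tables, function(t) t[[tr]]))
    if (sum(!is.na(pooled)) < 2)
      stop("trait ", tr, " has fewer than 2 non-missing values")
    mu <- mean(pooled, na.rm = TRUE)
    sdev <- stats::sd(pooled, na.rm = TRUE)
    if (!is.finite(sdev) || sdev == 0) {
      warning("trait ", tr, " has zero variance; no exclusions applied")
      next
    }
    for (s in seq_along(tables)) {
      bad <- !is.na(tables[[s]][[tr]]) &
        abs(tables[[s]][[tr]] - mu) > n_sd * sdev
      if (any(bad)) {
        log <- rbind(log, data.frame(
          subgroup = s, sample_id = tables[[s]]$sample_id[bad],
          trait = tr, value = tables[[s]][[tr]][bad],
          stringsAsFactors = FALSE))
        tables[[s]][[tr]][bad] <- NA
      }
    }
  }
  out <- if (single) tables[[1]] else tables
  attr(out, "exclusion_log") <- log
  out
}

#' Variant inclusion filter: imputation quality and effective heterozygosity
#'
#' A variant is retained when its imputation quality is at least
#' `min_quality` and its effective heterozygosity
#' `2 * CAF * (1 - CAF) * N * quality` is at least `min_effhet`. The
#' heterozygosity boundary is inclusive: exactly `min_effhet` is retained.
#' Monomorphic variants (CAF 0 or 1) have effective heterozygosity 0 and
#' fail the second rule.
#'
#' @param panel A `variant_panel`.
#' @param n Sample size used in the effective-heterozygosity formula
#'   (defaults to the panel's sample count).
#' @param min_quality Imputation-quality cutoff (default 0.4; values below
#'   are excluded).
#' @param min_effhet Effective-heterozygosity cutoff (default 35; values
#'   below are excluded).
#' @return A data.frame with `variant_id`, `effective_heterozygosity`,
#'   `imputation_quality`, `retained` and `reason` ("ok",
#'   "low_imputation_quality" or "low_effective_heterozygosity").
#' @export
filter_variants <- function(panel, n = nrow(panel$dosages),
                            min_quality = 0.4, min_effhet = 35) {
  meta <- panel$variant_meta
  effhet <- 2 * meta$CAF * (1 - meta$CAF) * n * meta$imputation_quality
  low_q <- meta$imputation_quality < min_quality
  low_h <- effhet < min_effhet
  reason <- ifelse(low_q, "low_imputation_quality",
                   ifelse(low_h, "low_effective_heterozygosity", "ok"))
  data.frame(variant_id = meta$variant_id,
             effective_heterozygosity = effhet,
             imputation_quality = meta$imputation_quality,
             retained = !low_q & !low_h,
             reason = reason,
             stringsAsFactors = FALSE)
}

# Residualize y and every dosage column on the covariate design, then run
# the per-variant simple regressions in one matrix pass. Equivalent to the
# full OLS fit by Frisch-Waugh-Lovell; degrees of freedom account for the
# covariates.
.massoc <- function(G, y, X) {
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    cols <- colnames(X)[qrX$pivot[seq_len(qrX$rank)]]
    bad <- setdiff(colnames(X), cols)
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, G)
  gss <- colSums(RG^2)
  df <- n - ncol(X) - 1L
  beta <- se <- rep(NA_real_, ncol(G))
  ok <- gss > 1e-12
  beta[ok] <- colSums(RG[, ok, drop = FALSE] * ry) / gss[ok]
  rss <- sum(ry^2) - beta[ok]^2 * gss[ok]
  rss[rss < 0] <- 0
  sigma2 <- rss / df
  se[ok] <- sqrt(sigma2 / gss[ok])
  list(beta = beta, se = se, ok = ok, n = n)
}

#' Univariate additive-model association for one trait
#'
#' Ordinary-least-squares regression of the trait on each variant's dosage,
#' adjusting for the given covariates (age, sex, site, ancestral principal
#' components, and any conditioning dosages), under complete-case analysis
#' for the trait. P-values come from the normal approximation to the Wald
#' z statistic, the standard behavior of GWAS software at these sample
#' sizes. Variants with zero dosage variance among complete cases are
#' emitted with missing beta/se, p = 1 and a `zero_variance` flag.
#'
#' @param panel A `variant_panel` (already filtered).
#' @param phenos A QC'd `phenotype_table` with matching `sample_id`s.
#' @param trait Trait column name.
#' @param covariates Covariate column names in `phenos` (may be empty).
#' @param extra_covariates Optional numeric matrix of additional covariate
#'   columns aligned with the panel's samples (e.g. lead-SNP dosages for
#'   conditional analysis).
#' @param variants Optional character vector restricting the variants tested.
#' @param p_floor Lower bound applied to p-values to avoid underflow
#'   (default 1e-300).
#' @return A data.frame of association records: MarkerName, Chromosome,
#'   Position, Allele1, Allele2, Freq1, ImpQuality, Effect, StdErr, Zscore,
#'   P-value (`P`), N, Trait, Subgroup, zero_variance.
#' @export
run_univariate <- function(panel, phenos, trait, covariates = character(0),
                           extra_covariates = NULL, variants = NULL,
                           p_floor = 1e-300) {
  meta <- panel$variant_meta
  dos <- panel$dosages
  if (!is.null(variants)) {
    keep <- match(variants, meta$variant_id)
    meta <- meta[keep, , drop = FALSE]
    dos <- dos[, keep, drop = FALSE]
  }
  idx <- match(rownames(dos), phenos$sample_id)
  if (anyNA(idx)) stop("panel samples missing from phenotype table")
  y <- phenos[[trait]][idx]
  if (is.null(y)) stop("trait column not found: ", trait)
  X <- matrix(1, nrow = length(y), ncol = 1, dimnames = list(NULL, "intercept"))
  if (length(covariates)) {
    Xc <- as.matrix(phenos[idx, covariates, drop = FALSE])
    storage.mode(Xc) <- "double"
    X <- cbind(X, Xc)
  }
  if (!is.null(extra_covariates)) {
    ec <- as.matrix(extra_covariates)
    # drop conditioning columns collinear with the existing design
    keep_ec <- rep(TRUE, ncol(ec))
    for (j in seq_len(ncol(ec))) {
      trial <- cbind(X, ec[, which(keep_ec[seq_len(j - 1)]), drop = FALSE],
                     ec[, j])
      if (qr(trial)$rank < ncol(trial)) {
        keep_ec[j] <- FALSE
        warning("conditioning covariate ", colnames(ec)[j],
                " is collinear with the design; dropped")
      }
    }
    if (any(keep_ec)) X <- cbind(X, ec[, keep_ec, drop = FALSE])
  }
  cc <- !is.na(y) & stats::complete.cases(X)
  y <- y[cc]
  X <- X[cc, , drop = FALSE]
  G <- dos[cc, , drop = FALSE]
  fit <- .massoc(G, y, X)
  z <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  p[!fit$ok] <- 1
  p <- pmax(p, p_floor)
  data.frame(
    MarkerName = meta$variant_id,
    Chromosome = meta$chromosome,
    Position = meta$position,
    Allele1 = meta$coded_allele,
    Allele2 = meta$other_allele,
    Freq1 = colMeans(G) / 2,
    ImpQuality = meta$imputation_quality,
    Effect = fit$beta,
    StdErr = fit$se,
    Zscore = z,
    P = p,
    N = fit$n,
    Trait = trait,
    Subgroup = panel$subgroup_id,
    zero_variance = !fit$ok,
    stringsAsFactors = FALSE
  )
}

#' Covariate-adjusted pairwise partial correlations between traits
#'
#' Each trait is residualized on the covariates (with intercept) by OLS;
#' the partial correlation matrix is the Pearson correlation of the
#' residuals, computed over samples complete for all traits and covariates.
#'
#' @param phenos A `phenotype_table`.
#' @param traits Trait column names.
#' @param covariates Covariate column names (may be empty).
#' @return A symmetric K x K correlation matrix with unit diagonal.
#' @export
partial_correlations <- function(phenos, traits, covariates = character(0)) {
  df <- as.data.frame(phenos)[, c(traits, covariates), drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < length(traits) + length(covariates) + 2)
    stop("insufficient complete cases for partial correlations")
  X <- matrix(1, nrow = nrow(df), ncol = 1)
  if (length(covariates))
    X <- cbind(X, as.matrix(df[, covariates, drop = FALSE]))
  qrX <- qr(X)
  res <- apply(as.matrix(df[, traits, drop = FALSE]), 2,
               function(y) qr.resid(qrX, y))
  R <- stats::cor(res)
  dimnames(R) <- list(traits, traits)
  R
}
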