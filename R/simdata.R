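#' Default residual correlation matrix for the seven red-blood-cell traits
#'
#' A fixed 7 x 7 positive-definite correlation matrix for the traits HCT,
#' HGB, MCH, MCHC, MCV, RBCC and RDW, used as the default residual
#' correlation of the phenotype simulator. The strongly determined pairs
#' reflect the physiology of the indices: HCT and HGB are almost collinear
#' (0.94), HGB and RBCC are moderately correlated (0.68), and HCT and MCHC
#' are essentially uncorrelated (-0.02). The remaining entries were chosen
#' once to be physiologically plausible while keeping the matrix positive
#' definite (smallest eigenvalue ~0.034).
#'
#' @return A named 7 x 7 correlation matrix.
#' @export
rbc_trait_corr <- function() {
  traits <- c("HCT", "HGB", "MCH", "MCHC", "MCV", "RBCC", "RDW")
  R <- diag(7)
  dimnames(R) <- list(traits, traits)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set2("HCT", "HGB", 0.94); set2("HCT", "MCH", 0.20)
  set2("HCT", "MCHC", -0.02); set2("HCT", "MCV", 0.32)
  set2("HCT", "RBCC", 0.72); set2("HCT", "RDW", -0.10)
  set2("HGB", "MCH", 0.28); set2("HGB", "MCHC", 0.20)
  set2("HGB", "MCV", 0.32); set2("HGB", "RBCC", 0.68)
  set2("HGB", "RDW", -0.15)
  set2("MCH", "MCHC", 0.45); set2("MCH", "MCV", 0.82)
  set2("MCH", "RBCC", -0.25); set2("MCH", "RDW", -0.28)
  set2("MCHC", "MCV", 0.08); set2("MCHC", "RBCC", -0.10)
  set2("MCHC", "RDW", -0.22)
  set2("MCV", "RBCC", -0.30); set2("MCV", "RDW", -0.22)
  set2("RBCC", "RDW", 0.08)
  R
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [generate_genotypes()] and [generate_phenotypes()]. The defaults emulate
#' a multi-ethnic GWAS design: several analytic subgroups with their own
#' allele-frequency spectra (possibly monomorphic at some variants), seven
#' quantitative traits with a fixed residual correlation matrix, local
#' linkage disequilibrium in blocks, sparse planted genetic effects, and
#' linear covariate effects.
#'
#' @param n_subgroups Number of analytic subgroups.
#' @param n_samples Integer vector of per-subgroup sample sizes (recycled to
#'   `n_subgroups`).
#' @param n_variants Number of variants on the panel.
#' @param n_traits Number of quantitative traits (default 7).
#' @param trait_corr K x K residual correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite). Defaults to [rbc_trait_corr()] when
#'   `n_traits == 7`, otherwise the identity.
#' @param allele_freq_ranges A list of length `n_subgroups` of `c(min, max)`
#'   coded-allele-frequency ranges in (0, 1).
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Latent (copula) correlation between adjacent variants within
#'   a block, in [0, 1).
#' @param causal_effects A data.frame with columns `variant` (1-based index),
#'   `trait` (1-based index) and `beta` (standardized per-allele effect), or
#'   `NULL` for a fully null panel.
#' @param n_covariates Number of simulated linear covariates. The first is a
#'   binary sex indicator; the rest are standard-normal scores (age, site,
#'   principal components are all of this form once standardized).
#' @param covariate_effects Effect sizes of the covariates on every trait
#'   (recycled to `n_covariates`).
#' @param imputation_quality_range `c(min, max)` range in (0, 1] from which
#'   per-variant imputation-quality values are drawn.
#' @param monomorphic_fraction Per-subgroup fraction of variants forced to be
#'   monomorphic (frequency 0) in that subgroup (recycled).
#' @param monomorphic_variants Optional list (one element per subgroup) of
#'   variant indices forced monomorphic in that subgroup, in addition to the
#'   random `monomorphic_fraction` draw; use it to plant ancestry-specific
#'   variants at known positions.
#' @param chromosome Chromosome label assigned to the simulated panel.
#' @param position_step Base-pair spacing between consecutive variants.
#' @param seed Integer master seed.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subgroups = 2,
                       n_samples = 1000,
                       n_variants = 100,
                       n_traits = 7,
                       trait_corr = NULL,
                       allele_freq_ranges = NULL,
                       ld_block_size = 10,
                       ld_rho = 0.5,
                       causal_effects = NULL,
                       n_covariates = 4,
                       covariate_effects = 0.1,
                       imputation_quality_range = c(0.7, 1),
                       monomorphic_fraction = 0,
                       monomorphic_variants = NULL,
                       chromosome = "1",
                       position_step = 50000L,
                       seed = 1L) {
  n_samples <- rep_len(as.integer(n_samples), n_subgroups)
  monomorphic_fraction <- rep_len(monomorphic_fraction, n_subgroups)
  if (is.null(trait_corr)) {
    trait_corr <- if (n_traits == 7) rbc_trait_corr() else diag(n_traits)
  }
  trait_corr <- as.matrix(trait_corr)
  if (nrow(trait_corr) != n_traits || ncol(trait_corr) != n_traits)
    stop("trait_corr must be ", n_traits, " x ", n_traits)
  if (max(abs(trait_corr - t(trait_corr))) > 1e-8)
    stop("trait_corr must be symmetric")
  if (max(abs(diag(trait_corr) - 1)) > 1e-8)
    stop("trait_corr must have unit diagonal")
  if (min(eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    stop("trait_corr is not positive semi-definite")
  if (is.null(allele_freq_ranges))
    allele_freq_ranges <- rep(list(c(0.05, 0.5)), n_subgroups)
  if (length(allele_freq_ranges) != n_subgroups)
    stop("allele_freq_ranges must have one (min, max) pair per subgroup")
  for (r in allele_freq_ranges)
    if (r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
      stop("allele frequency ranges must lie strictly inside (0, 1)")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (any(monomorphic_fraction < 0 | monomorphic_fraction > 1))
    stop("monomorphic_fraction must be in [0, 1]")
  q <- imputation_quality_range
  if (q[1] <= 0 || q[2] > 1 || q[1] > q[2])
    stop("imputation_quality_range must lie in (0, 1]")
  if (!is.null(monomorphic_variants)) {
    if (length(monomorphic_variants) != n_subgroups)
      stop("monomorphic_variants must have one element per subgroup")
    for (ix in monomorphic_variants)
      if (length(ix) && (min(ix) < 1 || max(ix) > n_variants))
        stop("monomorphic variant index out of range")
  }
  if (!is.null(causal_effects)) {
    causal_effects <- as.data.frame(causal_effects)
    stopifnot(all(c("variant", "trait", "beta") %in% names(causal_effects)))
    if (any(causal_effects$variant < 1 | causal_effects$variant > n_variants))
      stop("causal variant index out of range")
    if (any(causal_effects$trait < 1 | causal_effects$trait > n_traits))
      stop("causal trait index out of range")
  }
  trait_names <- colnames(trait_corr)
  if (is.null(trait_names))
    trait_names <- paste0("trait", seq_len(n_traits))
  structure(list(
    n_subgroups = n_subgroups,
    n_samples = n_samples,
    n_variants = as.integer(n_variants),
    n_traits = as.integer(n_traits),
    trait_names = trait_names,
    trait_corr = trait_corr,
    allele_freq_ranges = allele_freq_ranges,
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho,
    causal_effects = causal_effects,
    n_covariates = as.integer(n_covariates),
    covariate_effects = rep_len(covariate_effects, n_covariates),
    imputation_quality_range = q,
    monomorphic_fraction = monomorphic_fraction,
    monomorphic_variants = monomorphic_variants,
    chromosome = as.character(chromosome),
    position_step = as.integer(position_step),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic per-(subgroup, purpose) substream seed derived from the
# master seed; keeps subgroups independent yet reproducible.
.sub_seed <- function(seed, subgroup, offset) {
  (as.integer(seed) * 1009L + as.integer(subgroup) * 101L + offset) %%
    .Machine$integer.max
}

# Panel-level quantities shared by all subgroups: positions, alleles,
# per-variant imputation quality, and per-subgroup allele frequencies and
# monomorphic masks. Drawn from the master seed only.
.panel_frame <- function(config) {
  set.seed(.sub_seed(config$seed, 0L, 7L))
  m <- config$n_variants
  alleles <- c("A", "C", "G", "T")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  coded <- sample(alleles, m, replace = TRUE)
  # avoid palindromic (complementary) pairs: strand-ambiguous variants are
  # dropped by meta-analysis harmonization and would silently thin the panel
  other <- vapply(coded, function(a)
    sample(setdiff(alleles, c(a, comp[[a]])), 1L), "")
  qual <- stats::runif(m, config$imputation_quality_range[1],
                       config$imputation_quality_range[2])
  freqs <- vector("list", config$n_subgroups)
  mono <- vector("list", config$n_subgroups)
  for (s in seq_len(config$n_subgroups)) {
    r <- config$allele_freq_ranges[[s]]
    freqs[[s]] <- stats::runif(m, r[1], r[2])
    n_mono <- round(config$monomorphic_fraction[s] * m)
    mask <- rep(FALSE, m)
    if (n_mono > 0) {
      # never silence a planted causal variant in every subgroup: skip causal
      # indices when choosing the monomorphic set for subgroup 1
      candidates <- seq_len(m)
      if (s == 1L && !is.null(config$causal_effects))
        candidates <- setdiff(candidates, config$causal_effects$variant)
      mask[sample(candidates, min(n_mono, length(candidates)))] <- TRUE
    }
    if (!is.null(config$monomorphic_variants))
      mask[config$monomorphic_variants[[s]]] <- TRUE
    mono[[s]] <- mask
    freqs[[s]][mask] <- 0
  }
  list(
    variant_id = sprintf("var%04d", seq_len(m)),
    chromosome = rep(config$chromosome, m),
    position = seq_len(m) * config$position_step,
    coded_allele = coded,
    other_allele = other,
    imputation_quality = qual,
    freqs = freqs,
    monomorphic = mono
  )
}

#' Simulate genotype dosages for one analytic subgroup
#'
#' Draws two haploid alleles per sample under Hardy-Weinberg equilibrium at
#' subgroup-specific coded-allele frequencies. Local LD is induced by a
#' Gaussian copula: latent haplotype scores follow an AR(1) process with
#' adjacent-variant correlation `ld_rho` within blocks of `ld_block_size`
#' variants and are independent across blocks; an allele is coded when its
#' latent score falls below the frequency quantile. Imputation uncertainty
#' is emulated by deterministic shrinkage of each dosage toward its
#' expectation `2 * CAF`: deviations are scaled by `sqrt(quality)`, so that
#' the dosage variance is `quality * 2p(1-p)`, matching the variance-ratio
#' definition of imputation quality that the effective-heterozygosity filter
#' assumes. Variants flagged monomorphic for the subgroup have constant
#' dosage 0.
#'
#' @param config A [sim_config()] object.
#' @param subgroup Subgroup index in `1:n_subgroups`.
#' @return An object of class `variant_panel`: a list with `subgroup_id`,
#'   `variant_meta` (data.frame with chromosome, position, variant_id,
#'   coded/other allele, CAF, imputation_quality, monomorphic flag) and
#'   `dosages` (samples x variants matrix with values in [0, 2]).
#' @export
generate_genotypes <- function(config, subgroup = 1L) {
  stopifnot(inherits(config, "sim_config"),
            subgroup >= 1, subgroup <= config$n_subgroups)
  frame <- .panel_frame(config)
  n <- config$n_samples[subgroup]
  m <- config$n_variants
  p <- frame$freqs[[subgroup]]
  set.seed(.sub_seed(config$seed, subgroup, 11L))

  # latent AR(1) scores for 2n haplotypes
  latent <- matrix(stats::rnorm(2L * n * m), nrow = 2L * n, ncol = m)
  if (config$ld_rho > 0 && m > 1) {
    rho <- config$ld_rho
    w <- sqrt(1 - rho^2)
    for (j in 2:m) {
      same_block <- ((j - 1L) %% config$ld_block_size) != 0L
      if (same_block)
        latent[, j] <- rho * latent[, j - 1L] + w * latent[, j]
    }
  }
  thresh <- stats::qnorm(p)          # p = 0 gives -Inf: no coded alleles
  alleles <- sweep(latent, 2L, thresh, "<")
  dos <- alleles[seq_len(n), , drop = FALSE] +
    alleles[n + seq_len(n), , drop = FALSE]
  storage.mode(dos) <- "double"

  # shrink toward 2p by sqrt(quality): dosage variance = quality * 2p(1-p)
  shrink <- sqrt(frame$imputation_quality)
  dos <- sweep(sweep(dos, 2L, 2 * p, "-"), 2L, shrink, "*")
  dos <- sweep(dos, 2L, 2 * p, "+")
  dos[dos < 0] <- 0
  dos[dos > 2] <- 2

  meta <- data.frame(
    chromosome = frame$chromosome,
    position = frame$position,
    variant_id = frame$variant_id,
    coded_allele = frame$coded_allele,
    other_allele = frame$other_allele,
    CAF = p,
    imputation_quality = frame$imputation_quality,
    monomorphic = frame$monomorphic[[subgroup]],
    stringsAsFactors = FALSE
  )
  rownames(dos) <- sprintf("sg%d_s%05d", subgroup, seq_len(n))
  colnames(dos) <- frame$variant_id
  structure(list(subgroup_id = paste0("subgroup", subgroup),
                 variant_meta = meta, dosages = dos),
            class = "variant_panel")
}

#' Simulate phenotypes for one subgroup's genotype panel
#'
#' Each trait is the sum of the planted genetic effects (standardized effect
#' sizes applied to centered, scaled dosages), linear covariate effects, and
#' a multivariate-normal residual with correlation `trait_corr`. All traits
#' are simulated on the standardized scale (residual variance 1); physical
#' units are irrelevant to every downstream statistic. The ground-truth
#' effect table is attached to the result.
#'
#' @param panel A `variant_panel` from [generate_genotypes()].
#' @param config The same [sim_config()] used to build `panel`.
#' @param subgroup Subgroup index matching `panel`.
#' @return An object of class `phenotype_table`: a data.frame with
#'   `sample_id`, one column per trait and one per covariate, plus
#'   attributes `truth` (causal-effect table) and `trait_names`,
#'   `covariate_names`.
#' @export
generate_phenotypes <- function(panel, config, subgroup = 1L) {
  stopifnot(inherits(panel, "variant_panel"), inherits(config, "sim_config"))
  n <- nrow(panel$dosages)
  if (n != config$n_samples[subgroup])
    stop("panel and config disagree on the subgroup sample size")
  if (ncol(panel$dosages) != config$n_variants)
    stop("panel and config disagree on the number of variants")
  K <- config$n_traits
  set.seed(.sub_seed(config$seed, subgroup, 23L))

  covnames <- character(0)
  X <- NULL
  if (config$n_covariates > 0) {
    covnames <- c("sex", paste0("cov", seq_len(config$n_covariates - 1L)))
    covnames <- covnames[seq_len(config$n_covariates)]
    X <- cbind(stats::rbinom(n, 1L, 0.5))
    if (config$n_covariates > 1)
      X <- cbind(X, matrix(stats::rnorm(n * (config$n_covariates - 1L)),
                           nrow = n))
    colnames(X) <- covnames
  }

  Y <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = config$trait_corr)
  if (!is.null(X))
    Y <- Y + (X %*% matrix(config$covariate_effects, ncol = 1)) %*%
      matrix(1, nrow = 1, ncol = K)

  ce <- config$causal_effects
  if (!is.null(ce) && nrow(ce) > 0) {
    for (i in seq_len(nrow(ce))) {
      g <- panel$dosages[, ce$variant[i]]
      sdg <- stats::sd(g)
      if (sdg > 0)
        Y[, ce$trait[i]] <- Y[, ce$trait[i]] + ce$beta[i] * (g - mean(g)) / sdg
      # monomorphic in this subgroup: the variant contributes nothing here
    }
  }
  colnames(Y) <- config$trait_names
  out <- data.frame(sample_id = rownames(panel$dosages), Y,
                    stringsAsFactors = FALSE)
  if (!is.null(X)) out <- cbind(out, as.data.frame(X))
  attr(out, "truth") <- ce
  attr(out, "trait_names") <- config$trait_names
  attr(out, "covariate_names") <- covnames
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate the full multi-subgroup dataset
#'
#' Convenience wrapper running [generate_genotypes()] and
#' [generate_phenotypes()] for every subgroup.
#'
#' @param config A [sim_config()] object.
#' @return A list with `panels` and `phenotypes` (one per subgroup) and the
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  panels <- lapply(seq_len(config$n_subgroups),
                   function(s) generate_genotypes(config, s))
  phenos <- lapply(seq_len(config$n_subgroups), function(s)
    generate_phenotypes(panels[[s]], config, s))
  list(panels = panels, phenotypes = phenos, config = config)
}

#' Write a simulated dataset to tab-delimited files
#'
#' Emits, per subgroup, a dosage file (one row per variant: variant_id,
#' chromosome, position, coded_allele, other_allele, CAF,
#' imputation_quality, then one dosage column per sample) and a phenotype
#' file (sample_id, trait columns, covariate columns), plus a key-value
#' manifest recording the seed, the configuration echo, and the
#' ground-truth causal-effect table.
#'
#' @param dataset A list as returned by [simulate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in seq_along(dataset$panels)) {
    panel <- dataset$panels[[s]]
    f <- file.path(out_dir, sprintf("dosages_subgroup%d.tsv", s))
    write_dosage(panel, f)
    files <- c(files, f)
    f <- file.path(out_dir, sprintf("phenotypes_subgroup%d.tsv", s))
    utils::write.table(as.data.frame(dataset$phenotypes[[s]]), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- dataset$config
  mf <- file.path(out_dir, "manifest.txt")
  con <- file(mf, "w")
  writeLines(c(
    paste0("seed\t", cfg$seed),
    paste0("n_subgroups\t", cfg$n_subgroups),
    paste0("n_samples\t", paste(cfg$n_samples, collapse = ",")),
    paste0("n_variants\t", cfg$n_variants),
    paste0("n_traits\t", cfg$n_traits),
    paste0("ld_block_size\t", cfg$ld_block_size),
    paste0("ld_rho\t", cfg$ld_rho),
    paste0("monomorphic_fraction\t",
           paste(cfg$monomorphic_fraction, collapse = ",")),
    "causal_effects\tvariant,trait,beta"
  ), con)
  ce <- cfg$causal_effects
  if (!is.null(ce) && nrow(ce) > 0)
    writeLines(sprintf("causal\t%d,%d,%g", ce$variant, ce$trait, ce$beta), con)
  close(con)
  files <- c(files, mf)
  invisible(files)
}
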