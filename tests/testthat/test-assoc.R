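test_that("phenotype QC excludes values beyond 4 SD of the pooled mean", {
  set.seed(42)
  n <- 10000
  tab <- data.frame(sample_id = paste0("s", 1:n), HCT = stats::rnorm(n),
                    stringsAsFactors = FALSE)
  class(tab) <- c("phenotype_table", "data.frame")
  mu <- mean(tab$HCT); sdev <- stats::sd(tab$HCT)

  # plant one value at the mean and one at mean + 4.5 SD
  tab$HCT[1] <- mu
  tab$HCT[2] <- mu + 4.5 * sdev
  out <- qc_phenotypes(tab, "HCT")
  expect_false(is.na(out$HCT[1]))
  expect_true(is.na(out$HCT[2]))

  # for a standard normal sample the expected count is 2*pnorm(-4)*n ~ 0.6;
  # a binomial tail bound keeps the observed count below 6
  log <- attr(out, "exclusion_log")
  expect_true(nrow(log) >= 1 && nrow(log) <= 6)
  expect_true(all(log$trait == "HCT"))
})

test_that("phenotype QC warns and skips constant traits", {
  tab <- data.frame(sample_id = c("a", "b", "c"), flat = c(1, 1, 1))
  class(tab) <- c("phenotype_table", "data.frame")
  expect_warning(out <- qc_phenotypes(tab, "flat"), "zero variance")
  expect_false(anyNA(out$flat))
})

test_that("variant filter applies the quality and heterozygosity rules", {
  # 20-variant fixture spanning both rules and the inclusive boundary
  caf <- c(0.5, 0.5, 0.5, 0, 1, 0.1, 0.3, 0.05, 0.5, 0.25,
           0.4, 0.02, 0.5, 0.15, 0.45, 0.35, 0.01, 0.5, 0.2, 0.5)
  q <- c(0.7, 0.39, 1, 1, 1, 1, 0.45, 0.8, 0.4, 0.9,
         0.39, 1, 0.2, 0.95, 0.85, 0.5, 1, 0.41, 0.6, 0.05)
  n <- 100
  panel <- list(
    subgroup_id = "fixture",
    variant_meta = data.frame(
      chromosome = "1", position = seq_len(20) * 1000,
      variant_id = sprintf("v%02d", 1:20),
      coded_allele = "A", other_allele = "C",
      CAF = caf, imputation_quality = q, stringsAsFactors = FALSE),
    dosages = matrix(1, nrow = n, ncol = 20))
  class(panel) <- "variant_panel"

  rep <- filter_variants(panel, n = n)
  expect_equal(rep$effective_heterozygosity,
               2 * caf * (1 - caf) * n * q, tolerance = 1e-8)
  # retained iff quality >= 0.4 AND effhet >= 35, boundary inclusive
  expect_identical(rep$retained, q >= 0.4 & 2 * caf * (1 - caf) * n * q >= 35)
  # v01 sits exactly on the boundary: 2*.5*.5*100*.7 = 35, retained
  expect_true(rep$retained[1])
  # quality below 0.4 always excludes, regardless of heterozygosity
  expect_false(rep$retained[2])
  expect_equal(rep$reason[2], "low_imputation_quality")
  # monomorphic variants fail the heterozygosity rule
  expect_false(rep$retained[4]); expect_false(rep$retained[5])
  expect_equal(rep$reason[4], "low_effective_heterozygosity")
  # purity: identical inputs give an identical report
  expect_identical(rep, filter_variants(panel, n = n))
})

test_that("null p-values are uniform and planted effects are recovered", {
  cfg <- sim_config(n_subgroups = 1, n_samples = 800, n_variants = 2000,
                    ld_rho = 0, seed = 77)
  ds <- simulate_dataset(cfg)
  a <- run_univariate(ds$panels[[1]], ds$phenotypes[[1]], "HCT", std_covs)
  ks <- stats::ks.test(a$P, "punif")
  expect_gt(ks$p.value, 0.001)

  cfg2 <- sim_config(n_subgroups = 1, n_samples = 5000, n_variants = 20,
                     causal_effects = data.frame(variant = 5, trait = 1,
                                                 beta = 0.5),
                     seed = 78)
  ds2 <- simulate_dataset(cfg2)
  a2 <- run_univariate(ds2$panels[[1]], ds2$phenotypes[[1]], "HCT", std_covs)
  rec <- a2[a2$MarkerName == "var0005", ]
  # planted effect is on the standardized dosage scale
  sd_g <- stats::sd(ds2$panels[[1]]$dosages[, 5])
  expect_lt(abs(rec$Effect - 0.5 / sd_g), 3 * rec$StdErr)
  expect_equal(rec$Zscore, rec$Effect / rec$StdErr, tolerance = 1e-8)
  expect_equal(rec$P, 2 * stats::pnorm(-abs(rec$Zscore)), tolerance = 1e-12)
})

test_that("degenerate fits are handled: exact copies, zero variance, collinearity", {
  cfg <- sim_config(n_subgroups = 1, n_samples = 300, n_variants = 6,
                    imputation_quality_range = c(1, 1), seed = 5)
  ds <- simulate_dataset(cfg)
  ph <- ds$phenotypes[[1]]

  # trait equal to the dosage: beta 1, p at the floor
  ph$copy <- ds$panels[[1]]$dosages[, 2]
  a <- run_univariate(ds$panels[[1]], ph, "copy", character(0))
  rec <- a[a$MarkerName == "var0002", ]
  expect_equal(rec$Effect, 1, tolerance = 1e-10)
  expect_equal(rec$P, 1e-300)

  # constant dosage column: flagged, p = 1
  ds$panels[[1]]$dosages[, 3] <- 0
  a2 <- run_univariate(ds$panels[[1]], ph, "HCT", std_covs)
  expect_true(a2$zero_variance[3])
  expect_true(is.na(a2$Effect[3]))
  expect_equal(a2$P[3], 1)

  # duplicated covariate column names the collinear offender
  ph$sex2 <- ph$sex
  expect_error(run_univariate(ds$panels[[1]], ph, "HCT", c("sex", "sex2")),
               "sex2")
})

test_that("the mass-regression path matches a normal-equations solve", {
  set.seed(9)
  n <- 20
  X <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.5))
  g <- stats::rbinom(n, 2, 0.3)
  y <- 0.4 * g + X %*% c(0, 0.2, -0.1) + stats::rnorm(n)
  panel <- list(subgroup_id = "tiny",
                variant_meta = data.frame(
                  chromosome = "1", position = 100, variant_id = "v1",
                  coded_allele = "A", other_allele = "C", CAF = 0.3,
                  imputation_quality = 1, stringsAsFactors = FALSE),
                dosages = matrix(g, ncol = 1,
                                 dimnames = list(paste0("s", 1:n), "v1")))
  class(panel) <- "variant_panel"
  ph <- data.frame(sample_id = paste0("s", 1:n), y = as.vector(y),
                   c1 = X[, 2], c2 = X[, 3], stringsAsFactors = FALSE)

  a <- run_univariate(panel, ph, "y", c("c1", "c2"))

  # oracle: full design normal equations
  D <- cbind(X, g)
  bhat <- solve(t(D) %*% D, t(D) %*% y)
  resid <- y - D %*% bhat
  s2 <- sum(resid^2) / (n - ncol(D))
  se <- sqrt(s2 * solve(t(D) %*% D)[4, 4])
  expect_equal(a$Effect, bhat[4], tolerance = 1e-10)
  expect_equal(a$StdErr, se, tolerance = 1e-10)
})

test_that("confidence intervals for planted betas achieve nominal coverage", {
  cfg <- sim_config(n_subgroups = 1, n_samples = 400, n_variants = 500,
                    ld_rho = 0, imputation_quality_range = c(1, 1),
                    allele_freq_ranges = list(c(0.2, 0.5)),
                    causal_effects = data.frame(variant = 1:500, trait = 1,
                                                beta = 0.2),
                    seed = 303)
  ds <- simulate_dataset(cfg)
  a <- run_univariate(ds$panels[[1]], ds$phenotypes[[1]], "HCT", std_covs)
  sd_g <- apply(ds$panels[[1]]$dosages, 2, stats::sd)
  truth <- 0.2 / sd_g
  covered <- abs(a$Effect - truth) <= 1.96 * a$StdErr
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("partial correlations residualize covariates correctly", {
  ds <- make_dataset(seed = 55, n = 5000, m = 2, n_subgroups = 1)
  ph <- ds$phenotypes[[1]]

  # null-effect covariate: matches the plain Pearson correlation
  ph$noise_cov <- stats::rnorm(nrow(ph))
  plain <- stats::cor(ph$MCH, ph$MCV)
  adj <- partial_correlations(ph, c("MCH", "MCV"), "noise_cov")
  expect_lt(abs(adj["MCH", "MCV"] - plain), 0.01)

  # duplicated trait column
  ph$MCH2 <- ph$MCH
  dup <- partial_correlations(ph, c("MCH", "MCH2"), std_covs)
  expect_equal(dup["MCH", "MCH2"], 1, tolerance = 1e-12)

  # the HGB-RBCC pair is simulated at 0.68; recovered within its
  # Fisher-z 99% interval
  pc <- partial_correlations(ph, c("HGB", "RBCC"), std_covs)
  band <- 2.576 / sqrt(5000 - 3 - length(std_covs))
  expect_lt(abs(atanh(pc["HGB", "RBCC"]) - atanh(0.68)), band)

  expect_error(partial_correlations(ph[1:4, ], c("HGB", "RBCC"), std_covs),
               "insufficient")
})
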