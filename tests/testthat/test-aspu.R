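test_that("SPU statistics follow their definition", {
  z1 <- c(1, 0, 0, 0, 0, 0, 0)
  expect_equal(spu_stat(z1, 1), 1)
  expect_equal(spu_stat(z1, 2), 1)
  expect_equal(spu_stat(z1, Inf), 1)

  z2 <- c(2, -2, 0, 0, 0, 0, 0)
  expect_equal(spu_stat(z2, 1), 0)   # odd powers cancel opposing effects
  expect_equal(spu_stat(z2, 2), 8)
  expect_equal(spu_stat(z2, 3), 0)
  expect_equal(spu_stat(z2, Inf), 2)

  z0 <- rep(0, 7)
  for (g in 1:8) expect_equal(spu_stat(z0, g), 0)
  expect_equal(spu_stat(z0, Inf), 0)
  expect_equal(spu_stat(z0, 0), 7)   # SPU(0) is the constant K
})

test_that("the null z-score correlation estimate recovers the truth", {
  set.seed(61)
  z <- matrix(stats::rnorm(10000 * 4), ncol = 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  zp <- structure(list(variant_id = paste0("v", 1:10000),
                       chromosome = rep("1", 10000),
                       position = 1:10000, z = z, traits = paste0("t", 1:4),
                       missing = matrix(FALSE, 10000, 4)),
                  class = "zpanel")
  nc <- estimate_null_corr(zp)
  expect_lt(max(abs(nc$sigma - diag(4))), 0.05)
  expect_equal(nc$selection_rule, "null_z")

  # duplicated trait column
  z2 <- cbind(z[, 1:3], dup = z[, 3])
  zp2 <- zp; zp2$z <- z2; zp2$traits <- colnames(z2)
  nc2 <- estimate_null_corr(zp2)
  expect_equal(nc2$sigma[3, 4], 1, tolerance = 1e-12)

  # oracle: under selection = "all" the estimate is exactly the Pearson
  # correlation of the z columns, computed here independently
  nc3 <- estimate_null_corr(zp, selection = "all")
  byhand <- stats::cor(z)
  expect_equal(unname(nc3$sigma), unname(byhand), tolerance = 1e-12)
  expect_equal(nc3$n_snps_used, 10000)

  expect_error(estimate_null_corr(structure(list(z = z[1, , drop = FALSE],
                                                 traits = paste0("t", 1:4)),
                                            class = "zpanel"),
                                  selection = "all"),
               "fewer than 2")
})

test_that("shared-sample z correlation matches the trait residual correlation", {
  # with no genetic effects, z-scores across traits computed on the same
  # samples are correlated like the trait residuals; validate against the
  # brute-force correlation of the same z columns
  ds <- make_dataset(seed = 71, n = 900, m = 400, n_subgroups = 1, ld_rho = 0)
  zp <- meta_zpanel(ds)
  direct <- stats::cor(zp$z)
  nc <- suppressWarnings(estimate_null_corr(zp, selection = "all"))
  expect_equal(unname(nc$sigma), unname(direct), tolerance = 1e-10)
  # and both approximate the generating residual correlation
  expect_lt(max(abs(direct - ds$config$trait_corr)), 0.2)
  expect_gt(direct["HCT", "HGB"], 0.8)
})

test_that("the Monte-Carlo reference is reproducible and correctly sized", {
  sig <- rbc_trait_corr()
  r1 <- build_reference(sig, b = 100, seed = 5)
  r2 <- build_reference(sig, b = 100, seed = 5)
  expect_identical(r1$sorted_abs_spu, r2$sorted_abs_spu)
  expect_identical(r1$sorted_minp, r2$sorted_minp)
  expect_true(all(lengths(r1$sorted_abs_spu) == 100))
  expect_equal(length(r1$sorted_minp), 100)

  r3 <- build_reference(sig, b = 100, seed = 6)
  expect_false(identical(r1$sorted_abs_spu, r3$sorted_abs_spu))

  expect_error(build_reference(sig, b = 1e9), "memory budget")
})

test_that("null SPU(2) under the identity matches its chi-square law", {
  ref <- build_reference(diag(7), b = 1e6, gamma_set = 2, seed = 9)
  # SPU(2) = sum of 7 squared independent normals ~ chi-square with 7 df
  expect_equal(mean(ref$sorted_abs_spu[[1]]), 7, tolerance = 0.01)
  expect_equal(stats::median(ref$sorted_abs_spu[[1]]),
               stats::qchisq(0.5, 7), tolerance = 0.02)
})

test_that("aspu_test agrees exactly with the brute-force double-loop oracle", {
  set.seed(17)
  sig <- rbc_trait_corr()
  ref <- build_reference(sig, b = 200, seed = 23)
  Z_null <- reference_draws(ref)
  for (i in 1:50) {
    z <- stats::rnorm(7, sd = sample(c(0.5, 1, 2), 1))
    fast <- aspu_test(z, ref)
    slow <- aspu_oracle(z, Z_null)
    expect_identical(unname(fast$per_gamma_p), slow$per_gamma_p)
    expect_identical(fast$p_aspu, slow$p_aspu)
  }
})

test_that("null z-vectors score p near one and the floor is attainable", {
  ref <- build_reference(diag(7), b = 1000, seed = 31)
  res0 <- aspu_test(rep(0, 7), ref)
  expect_true(all(res0$per_gamma_p > 0.99))
  expect_gt(res0$p_aspu, 0.99)

  # one component at z = 8: no null draw can beat it, so the adaptive p
  # sits at the floor 1/(b+1)
  res8 <- aspu_test(c(8, rep(0, 6)), ref)
  expect_equal(res8$p_aspu, 1 / 1001)
  oracle <- aspu_oracle(c(8, rep(0, 6)), reference_draws(ref))
  expect_identical(res8$p_aspu, oracle$p_aspu)
})

test_that("the adaptive p-value respects its bounds on random input", {
  set.seed(41)
  ref <- build_reference(rbc_trait_corr(), b = 1000, seed = 43)
  for (i in 1:10000) {
    z <- stats::rnorm(7, sd = stats::runif(1, 0.1, 3))
    r <- aspu_test(z, ref)
    if (r$p_aspu < 1 / 1001 || r$p_aspu > 1 ||
        r$p_aspu < min(r$per_gamma_p) - 1 / 1001)
      fail(sprintf("bound violated at iteration %d: p = %g", i, r$p_aspu))
  }
  succeed()
})

test_that("missing trait z-scores are zero-substituted and flagged", {
  tabs <- list(
    HCT = data.frame(MarkerName = c("v1", "v2"), Chromosome = "1",
                     Position = c(100, 200), Zscore = c(1.5, -0.5),
                     Trait = "HCT", NStudies = 2, stringsAsFactors = FALSE),
    HGB = data.frame(MarkerName = "v1", Chromosome = "1",
                     Position = 100, Zscore = 2.0,
                     Trait = "HGB", NStudies = 1, stringsAsFactors = FALSE))
  zp <- build_zpanel(tabs)
  expect_equal(zp$z["v2", "HGB"], 0)
  expect_true(zp$missing["v2", "HGB"])
  expect_false(zp$missing["v1", "HGB"])
  expect_equal(zp$z["v1", ], c(HCT = 1.5, HGB = 2.0))
})

test_that("staged escalation promotes only near-floor variants", {
  set.seed(53)
  K <- 7
  z <- rbind(matrix(stats::rnorm(50 * K), ncol = K),      # null variants
             matrix(stats::rnorm(3 * K, mean = 4), ncol = K))  # strong
  zp <- structure(list(variant_id = paste0("v", seq_len(nrow(z))),
                       chromosome = rep("1", nrow(z)),
                       position = seq_len(nrow(z)) * 1000,
                       z = z, traits = paste0("t", 1:K),
                       missing = matrix(FALSE, nrow(z), K)),
                  class = "zpanel")
  sched <- c(1e3, 1e4)
  res <- staged_aspu(zp, diag(K), b_schedule = sched, seed = 3)

  strong <- 51:53
  expect_true(all(res$Bused[strong] == 1e4))
  # a variant with p ~ 0.5 is never promoted
  mild <- which(res$Paspu > 0.2)
  expect_true(all(res$Bused[mild] == 1e3))

  # promoted variants carry the same p they would get from a single run
  # at the final stage (same seed stream)
  ref_final <- build_reference(diag(K), b = 1e4, seed = 3 + 1)
  for (i in strong) {
    single <- aspu_test(z[i, ], ref_final)
    expect_identical(res$Paspu[i], single$p_aspu)
  }

  # promotion is a superset of final-stage significance: everything
  # significant at the end was evaluated at b_max
  alpha <- 10 / sched[1]
  expect_true(all(res$Bused[res$Paspu <= alpha / 10] == sched[2]))
})

test_that("aSPU is at least as powerful as Bonferroni when all traits carry effect", {
  set.seed(67)
  K <- 7
  m <- 400
  mu <- 2.2
  z <- matrix(stats::rnorm(m * K, mean = mu), ncol = K)
  ref <- build_reference(diag(K), b = 1e4, seed = 68)
  p_aspu <- apply(z, 1, function(v) aspu_test(v, ref)$p_aspu)
  p_bonf <- apply(z, 1, function(v) min(1, K * 2 * stats::pnorm(-max(abs(v)))))
  pow_aspu <- mean(p_aspu < 0.05)
  pow_bonf <- mean(p_bonf < 0.05)
  # equal effects on every trait favor the sum-type members of the family
  expect_gte(pow_aspu, pow_bonf - 0.02)
})
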