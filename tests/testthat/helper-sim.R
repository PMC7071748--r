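# Shared fixtures built in code.

std_covs <- c("sex", "cov1", "cov2", "cov3")

# A small two-subgroup dataset with optional planted effects.
make_dataset <- function(seed = 11, n = 1200, m = 60, causal = NULL,
                         mono = 0, n_subgroups = 2, ...) {
  cfg <- sim_config(n_subgroups = n_subgroups, n_samples = n, n_variants = m,
                    causal_effects = causal, monomorphic_fraction = mono,
                    seed = seed, ...)
  simulate_dataset(cfg)
}

# Univariate association for every trait and subgroup, meta-analyzed and
# joined into a z-panel.
meta_zpanel <- function(ds, traits = ds$config$trait_names,
                        covs = std_covs) {
  tabs <- lapply(traits, function(tr) {
    aa <- lapply(seq_along(ds$panels), function(s)
      run_univariate(ds$panels[[s]], ds$phenotypes[[s]], tr, covs))
    ivw_meta(do.call(rbind, aa))
  })
  names(tabs) <- traits
  build_zpanel(tabs)
}

# Brute-force O(b^2) adaptive SPU oracle: recomputes every null draw's
# leave-one-out minimum p directly, never touching the package's
# rank/sort path.
aspu_oracle <- function(z, Z_null, gamma_set = c(1:8, Inf)) {
  b <- nrow(Z_null)
  spu <- function(v, g) if (is.infinite(g)) max(abs(v)) else sum(v^g)
  null_spu <- sapply(gamma_set, function(g)
    abs(apply(Z_null, 1, spu, g = g)))
  obs_spu <- abs(sapply(gamma_set, function(g) spu(z, g)))
  per_p <- sapply(seq_along(gamma_set), function(j)
    (1 + sum(null_spu[, j] >= obs_spu[j])) / (b + 1))
  minp_obs <- min(per_p)
  minp_null <- numeric(b)
  for (i in seq_len(b)) {
    ps <- sapply(seq_along(gamma_set), function(j)
      (1 + sum(null_spu[-i, j] >= null_spu[i, j])) / b)
    minp_null[i] <- min(ps)
  }
  list(per_gamma_p = per_p,
       p_aspu = (1 + sum(minp_null <= minp_obs)) / (b + 1))
}

# Reproduce the reference's null draws outside the package.
reference_draws <- function(reference) {
  set.seed(reference$seed)
  MASS::mvrnorm(reference$b, mu = rep(0, reference$K),
                Sigma = reference$sigma)
}
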