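#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], with
#' every default filled in: the analytic thresholds (genome-wide 5e-9,
#' generalization 1.07e-4 for 466 regions), the variant filter constants
#' (imputation quality 0.4, effective heterozygosity 35), the SPU power
#' set, the Monte-Carlo escalation schedule, the minimum subgroup size
#' (1000 participants, below which a subgroup is excluded from analysis),
#' and the simulation settings used when the pipeline generates its own
#' data.
#'
#' @param ... Named overrides, merged over the defaults (one level deep
#'   for the `simulate` sub-list).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_defaults <- function(...) {
  cfg <- list(
    seed = 1L,
    traits = c("HCT", "HGB", "MCH", "MCHC", "MCV", "RBCC", "RDW"),
    covariates = c("sex", "cov1", "cov2", "cov3"),
    alpha_genomewide = genomewide_threshold(),
    n_known_regions = 466L,
    min_quality = 0.4,
    min_effhet = 35,
    qc_sd = 4,
    min_subgroup_n = 1000L,
    gamma_set = c(1:8, Inf),
    b_schedule = c(1e3, 1e4, 1e5),
    window_mb = 10,
    locus_bp = 5e5,
    subgroups = NULL,             # restrict to these subgroup indices
    sigma_known = NULL,           # K x K null z correlation, if known;
                                  # otherwise estimated from the z-panel
    known_regions_file = NULL,
    simulate = list(n_subgroups = 2, n_samples = 1500, n_variants = 200,
                    monomorphic_fraction = 0)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (nm == "simulate" && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg$simulate[[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg$alpha_generalization <- generalization_threshold(cfg$n_known_regions)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override [pipeline_defaults()]; `Inf` in the
#' gamma set may be written as the string `"Inf"`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$gamma_set))
    raw$gamma_set <- as.numeric(unlist(raw$gamma_set))
  do.call(pipeline_defaults, raw)
}

#' Print every configuration default
#'
#' @param cfg A `pipeline_config` (default: the package defaults).
#' @return Invisibly, `cfg`.
#' @export
show_defaults <- function(cfg = pipeline_defaults()) {
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.list(v))
      v <- paste(names(v), vapply(v, function(x)
        paste(x, collapse = ","), ""), sep = "=", collapse = "; ")
    else v <- paste(format(v), collapse = ", ")
    cat(sprintf("%-22s %s\n", nm, v))
  }
  invisible(cfg)
}

#' Run the combined-phenotype pipeline end to end
#'
#' Stages, in order: data simulation (or loading), phenotype QC, variant
#' filtering, per-subgroup univariate association for every trait,
#' inverse-variance-weighted meta-analysis, genomic-control diagnostics,
#' the adaptive SPU combined-phenotype test, iterative conditional
#' analysis with locus definition, and (when a known-regions file is
#' configured) generalization testing. All stage outputs are written as
#' tab-delimited files under `out_dir` together with a run log recording
#' the seed, a configuration hash, per-stage record counts and timings.
#'
#' @param config A `pipeline_config` from [pipeline_defaults()] or
#'   [read_config()].
#' @param out_dir Output directory.
#' @param dataset Optional pre-built dataset (as from
#'   [simulate_dataset()]); when `NULL` one is simulated from
#'   `config$simulate` and `config$seed`.
#' @return Invisibly, a list with the principal in-memory results:
#'   `meta`, `lambda`, `aspu`, `conditional`, `signals`, `loci`,
#'   `generalization`.
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("seed\t%d", config$seed),
                 sprintf("config_hash\t%s", .config_hash(config)))
  stage <- function(name, n) {
    log_lines <<- c(log_lines, sprintf(
      "stage\t%s\trecords=%d\telapsed_s=%.2f", name, n,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  # -- simulate / load ------------------------------------------------
  if (is.null(dataset)) {
    sim <- config$simulate
    sc <- sim_config(
      n_subgroups = sim$n_subgroups,
      n_samples = sim$n_samples,
      n_variants = sim$n_variants,
      n_traits = length(config$traits),
      causal_effects = sim$causal_effects,
      monomorphic_fraction = sim$monomorphic_fraction,
      seed = config$seed)
    dataset <- simulate_dataset(sc)
    write_dataset(dataset, file.path(out_dir, "simulated"))
  }
  panels <- dataset$panels
  phenos <- dataset$phenotypes
  keep_sg <- which(vapply(panels, function(p) nrow(p$dosages), 0) >=
                     config$min_subgroup_n |
                     seq_along(panels) %in% config$subgroups)
  if (!is.null(config$subgroups)) keep_sg <- intersect(keep_sg, config$subgroups)
  if (length(keep_sg) == 0) stop("no subgroup satisfies the inclusion rules")
  panels <- panels[keep_sg]
  phenos <- phenos[keep_sg]
  stage("load", length(panels))

  # -- phenotype QC ---------------------------------------------------
  traits <- config$traits
  covs <- intersect(config$covariates, names(phenos[[1]]))
  phenos <- qc_phenotypes(phenos, traits, n_sd = config$qc_sd)
  stage("qc_phenotypes", nrow(attr(phenos, "exclusion_log")))

  # -- variant filter -------------------------------------------------
  filters <- lapply(panels, function(p)
    filter_variants(p, min_quality = config$min_quality,
                    min_effhet = config$min_effhet))
  for (s in seq_along(panels)) {
    keep <- filters[[s]]$retained
    panels[[s]]$variant_meta <- panels[[s]]$variant_meta[keep, , drop = FALSE]
    panels[[s]]$dosages <- panels[[s]]$dosages[, keep, drop = FALSE]
    write_summary(filters[[s]],
                  file.path(out_dir, sprintf("filter_subgroup%d.tsv",
                                             keep_sg[s])))
  }
  stage("filter_variants", sum(vapply(filters, function(f) sum(f$retained), 0)))

  # -- univariate + meta ---------------------------------------------
  assoc_all <- list()
  for (s in seq_along(panels)) {
    for (tr in traits) {
      assoc_all[[length(assoc_all) + 1L]] <-
        run_univariate(panels[[s]], phenos[[s]], tr, covs)
    }
  }
  assoc_tab <- do.call(rbind, assoc_all)
  write_summary(assoc_tab, file.path(out_dir, "univariate.tsv"))
  stage("univariate", nrow(assoc_tab))

  meta_tab <- ivw_meta(assoc_tab)
  write_summary(meta_tab, file.path(out_dir, "meta.tsv"))
  stage("meta", nrow(meta_tab))

  lambda <- lapply(split(meta_tab, meta_tab$Trait), function(g)
    suppressWarnings(genomic_lambda(z = g$Zscore, trait = g$Trait[1])))
  lam_tab <- data.frame(Trait = names(lambda),
                        Lambda = vapply(lambda, function(l) l$lambda, 0))
  write_summary(lam_tab, file.path(out_dir, "genomic_control.tsv"))
  stage("genomic_control", nrow(lam_tab))

  # -- combined phenotype + conditional -------------------------------
  cond <- conditional_iteration(
    panels, phenos, traits, covs, sigma = config$sigma_known,
    alpha = config$alpha_genomewide, b_schedule = config$b_schedule,
    gamma_set = config$gamma_set, seed = config$seed,
    window_mb = config$window_mb)
  aspu_tab <- cond$rounds[[1]]
  # ancestry specificity: monomorphic in at least one analyzed subgroup
  mono <- Reduce(`|`, lapply(panels, function(p) {
    stats::setNames(p$variant_meta$monomorphic, p$variant_meta$variant_id)[
      aspu_tab$MarkerName]
  }))
  present <- Reduce(`+`, lapply(panels, function(p) {
    as.integer(aspu_tab$MarkerName %in%
                 p$variant_meta$variant_id[!p$variant_meta$monomorphic])
  }))
  aspu_tab$AncestrySpecific <- unname(mono) | present < length(panels)
  write_summary(aspu_tab, file.path(out_dir, "aspu.tsv"))
  stage("aspu", nrow(aspu_tab))

  signals <- define_loci(cond$signals, merge_bp = config$locus_bp)
  loci <- attr(signals, "loci")
  if (nrow(signals) > 0) {
    sig_out <- signals
    sig_out$ancestry_specific <-
      aspu_tab$AncestrySpecific[match(sig_out$lead_variant,
                                      aspu_tab$MarkerName)]
    write_summary(sig_out, file.path(out_dir, "signals.tsv"))
    write_summary(loci, file.path(out_dir, "loci.tsv"))
  }
  stage("conditional", nrow(signals))

  # -- generalization -------------------------------------------------
  gen <- NULL
  if (!is.null(config$known_regions_file)) {
    known <- read_known_regions(config$known_regions_file)
    gen <- generalization_test(aspu_tab, known,
                               threshold = config$alpha_generalization)
    write_summary(gen, file.path(out_dir, "generalization.tsv"))
    stage("generalization", sum(gen$in_known_region))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(meta = meta_tab, lambda = lam_tab, aspu = aspu_tab,
                 conditional = cond, signals = signals, loci = loci,
                 generalization = gen))
}

# Order-independent hash of the configuration values; enough to confirm
# that two runs used the same settings.
.config_hash <- function(cfg) {
  s <- paste(names(cfg)[order(names(cfg))],
             vapply(cfg[order(names(cfg))], function(v)
               paste(format(unlist(v)), collapse = ","), ""),
             sep = "=", collapse = ";")
  # polynomial rolling hash mod a Mersenne prime, reported as hex
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
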