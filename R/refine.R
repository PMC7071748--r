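#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' @param dosage_a,dosage_b Equal-length numeric dosage vectors.
#' @return Squared Pearson correlation, or `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b))
    stop("dosage vectors must have equal length")
  if (stats::sd(dosage_a) == 0 || stats::sd(dosage_b) == 0) {
    warning("zero-variance dosage; r2 undefined")
    return(NA_real_)
  }
  stats::cor(dosage_a, dosage_b)^2
}

#' Select lead variants within fixed 10-Mb windows
#'
#' Within each tiling window (anchored at position 1) on each chromosome,
#' the variant with the smallest combined-phenotype p-value below the
#' significance threshold becomes a lead. Exact p ties break to the
#' smaller position.
#'
#' @param results Data.frame from [staged_aspu()] (columns MarkerName,
#'   Chromosome, Position, Paspu).
#' @param alpha Genome-wide significance threshold (default 5e-9).
#' @param window_mb Window size in megabases (default 10).
#' @return Data.frame of leads: MarkerName, Chromosome, Position, Paspu,
#'   window index. Zero rows when nothing is significant.
#' @export
select_window_leads <- function(results, alpha = 5e-9, window_mb = 10) {
  win_bp <- window_mb * 1e6
  sig <- results[!is.na(results$Paspu) & results$Paspu < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  sig$window <- paste0(sig$Chromosome, ":",
                       (sig$Position - 1) %/% win_bp)
  picked <- lapply(split(sig, sig$window), function(g) {
    g <- g[order(g$Paspu, g$Position), , drop = FALSE]
    g[1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(out$Chromosome, out$Position), , drop = FALSE]
}

# Re-run the association -> meta -> aSPU chain with the given lead
# dosages entered as extra covariates in every trait model whose variants
# share a chromosome with the lead. Variants that are themselves current
# leads are excluded from re-testing.
.conditioned_aspu <- function(panels, phenos, traits, covariates, leads,
                              sigma, b_schedule, gamma_set, seed,
                              p_floor = 1e-300) {
  lead_ids <- leads$MarkerName
  assoc_all <- list()
  for (s in seq_along(panels)) {
    panel <- panels[[s]]
    meta <- panel$variant_meta
    extra <- NULL
    if (length(lead_ids)) {
      idx <- match(lead_ids, meta$variant_id)
      pres <- !is.na(idx)
      if (any(pres)) {
        extra <- panel$dosages[, idx[pres], drop = FALSE]
        colnames(extra) <- lead_ids[pres]
        keepv <- apply(extra, 2, stats::sd) > 0
        extra <- extra[, keepv, drop = FALSE]
        if (ncol(extra) == 0) extra <- NULL
      }
    }
    test_ids <- setdiff(meta$variant_id, lead_ids)
    for (tr in traits) {
      assoc_all[[length(assoc_all) + 1L]] <-
        run_univariate(panel, phenos[[s]], tr, covariates,
                       extra_covariates = extra, variants = test_ids,
                       p_floor = p_floor)
    }
  }
  meta_tab <- ivw_meta(do.call(rbind, assoc_all), p_floor = p_floor)
  zpanel <- build_zpanel(split(meta_tab, meta_tab$Trait))
  staged_aspu(zpanel, sigma, b_schedule = b_schedule,
              gamma_set = gamma_set, seed = seed)
}

#' Iterative conditional analysis to enumerate independent signals
#'
#' Round 0 runs the unconditioned combined-phenotype analysis and takes
#' the top significant variant per 10-Mb window as the initial leads.
#' Each later round refits every trait's regression with all current lead
#' dosages (on the shared chromosome) as covariates, re-runs the
#' meta-analysis and the adaptive SPU test on the conditioned results,
#' and promotes newly significant window leads. Iteration stops when no
#' variant remains significant, so every reported signal is conditionally
#' independent of all others.
#'
#' @param panels List of per-subgroup `variant_panel`s.
#' @param phenos List of matching QC'd `phenotype_table`s.
#' @param traits Trait column names.
#' @param covariates Covariate column names.
#' @param sigma `null_corr` for the Monte-Carlo reference; when `NULL` it
#'   is estimated from the unconditioned z-panel.
#' @param alpha Significance threshold for declaring a signal
#'   (default 5e-9; set to something attainable for the chosen
#'   `b_schedule`, since Monte-Carlo p-values cannot fall below
#'   `1/(b_max + 1)`).
#' @param b_schedule Escalation schedule for [staged_aspu()].
#' @param gamma_set SPU powers.
#' @param seed Master seed.
#' @param window_mb Lead-selection window (default 10 Mb).
#' @param max_rounds Safety cap on conditioning rounds (default 20).
#' @return A list of class `conditional_result`: `signals` (data.frame
#'   with lead_variant, chromosome, position, conditioning_round,
#'   p_aspu_at_discovery, conditioned_on), `rounds` (per-round aSPU
#'   tables), `sigma`.
#' @export
conditional_iteration <- function(panels, phenos, traits, covariates,
                                  sigma = NULL, alpha = 5e-9,
                                  b_schedule = c(1e3, 1e4, 1e5),
                                  gamma_set = c(1:8, Inf), seed = 1L,
                                  window_mb = 10, max_rounds = 20) {
  # unconditioned association and meta-analysis, also used for Sigma
  assoc_all <- list()
  for (s in seq_along(panels)) {
    for (tr in traits) {
      assoc_all[[length(assoc_all) + 1L]] <-
        run_univariate(panels[[s]], phenos[[s]], tr, covariates)
    }
  }
  meta_tab <- ivw_meta(do.call(rbind, assoc_all))
  zpanel <- build_zpanel(split(meta_tab, meta_tab$Trait))
  if (is.null(sigma))
    sigma <- suppressWarnings(estimate_null_corr(zpanel))
  res0 <- staged_aspu(zpanel, sigma, b_schedule = b_schedule,
                      gamma_set = gamma_set, seed = seed)
  rounds <- list(res0)
  signals <- data.frame(lead_variant = character(0),
                        chromosome = character(0), position = integer(0),
                        conditioning_round = integer(0),
                        p_aspu_at_discovery = numeric(0),
                        conditioned_on = character(0),
                        stringsAsFactors = FALSE)
  leads0 <- select_window_leads(res0, alpha = alpha, window_mb = window_mb)
  if (nrow(leads0) == 0)
    return(structure(list(signals = signals, rounds = rounds, sigma = sigma),
                     class = "conditional_result"))
  signals <- rbind(signals, data.frame(
    lead_variant = leads0$MarkerName, chromosome = leads0$Chromosome,
    position = leads0$Position, conditioning_round = 0L,
    p_aspu_at_discovery = leads0$Paspu, conditioned_on = "",
    stringsAsFactors = FALSE))

  round <- 1L
  repeat {
    if (round > max_rounds) {
      warning("conditional iteration stopped at max_rounds = ", max_rounds)
      break
    }
    cur <- data.frame(MarkerName = signals$lead_variant)
    res <- .conditioned_aspu(panels, phenos, traits, covariates, cur,
                             sigma, b_schedule, gamma_set,
                             seed = as.integer(seed) + 100L * round)
    rounds[[length(rounds) + 1L]] <- res
    leads <- select_window_leads(res, alpha = alpha, window_mb = window_mb)
    if (nrow(leads) == 0) break
    signals <- rbind(signals, data.frame(
      lead_variant = leads$MarkerName, chromosome = leads$Chromosome,
      position = leads$Position, conditioning_round = round,
      p_aspu_at_discovery = leads$Paspu,
      conditioned_on = paste(cur$MarkerName, collapse = ","),
      stringsAsFactors = FALSE))
    round <- round + 1L
  }
  structure(list(signals = signals, rounds = rounds, sigma = sigma),
            class = "conditional_result")
}

#' Group independent signals into physical loci
#'
#' A locus is a +/- 500 kb window around a lead variant. Signals whose
#' leads fall within `merge_bp` of any lead already in a locus join that
#' locus; chained proximity (A near B, B near C) merges transitively, so a
#' locus can span more than 1 Mb in total. Input order is fixed by p-value
#' then position, making the grouping deterministic.
#'
#' @param signals Signals data.frame from [conditional_iteration()].
#' @param merge_bp Merge distance in base pairs (default 500000).
#' @return The signals with a `locus_id` column, plus attribute `loci`
#'   (one row per locus: locus_id, chromosome, lead span, n_signals).
#' @export
define_loci <- function(signals, merge_bp = 5e5) {
  if (nrow(signals) == 0) {
    signals$locus_id <- character(0)
    attr(signals, "loci") <- data.frame()
    return(signals)
  }
  ord <- order(signals$p_aspu_at_discovery, signals$position)
  s <- signals[ord, , drop = FALSE]
  locus <- rep(NA_integer_, nrow(s))
  next_id <- 0L
  for (i in seq_len(nrow(s))) {
    hit <- which(!is.na(locus) & s$chromosome == s$chromosome[i] &
                   abs(s$position - s$position[i]) <= merge_bp)
    hit <- setdiff(hit, i)
    if (length(hit)) {
      ids <- unique(locus[hit])
      locus[i] <- ids[1]
      if (length(ids) > 1) locus[locus %in% ids] <- ids[1]  # transitive merge
    } else {
      next_id <- next_id + 1L
      locus[i] <- next_id
    }
  }
  # relabel in genome order of the locus's most significant lead
  s$locus_id <- locus
  first <- do.call(rbind, lapply(split(s, s$locus_id), function(g)
    g[which.min(g$p_aspu_at_discovery), c("locus_id", "chromosome", "position")]))
  first <- first[order(first$chromosome, first$position), , drop = FALSE]
  relabel <- stats::setNames(sprintf("locus%02d", seq_len(nrow(first))),
                             first$locus_id)
  s$locus_id <- unname(relabel[as.character(s$locus_id)])
  s <- s[order(s$locus_id, s$conditioning_round, s$position), , drop = FALSE]
  rownames(s) <- NULL
  loci <- do.call(rbind, lapply(split(s, s$locus_id), function(g)
    data.frame(locus_id = g$locus_id[1], chromosome = g$chromosome[1],
               start = min(g$position) - merge_bp,
               end = max(g$position) + merge_bp,
               n_signals = nrow(g), stringsAsFactors = FALSE)))
  rownames(loci) <- NULL
  attr(s, "loci") <- loci
  s
}

#' Generalization test against previously reported regions
#'
#' A variant lying within `window_bp` of a previously reported variant
#' generalizes when its p-value is below the region-count Bonferroni
#' threshold (0.05 corrected for the number of previously reported 1-Mb
#' regions; 466 regions gives 1.07e-4). Variants not near any known
#' region are not evaluated (`in_known_region = FALSE`, `generalizes =
#' NA`).
#'
#' @param results Data.frame with MarkerName, Chromosome, Position and a
#'   p-value column.
#' @param known_regions Data.frame with `chromosome` and `position`
#'   columns (see [read_known_regions()]).
#' @param p_col Name of the p-value column to test (default "Paspu").
#' @param threshold Significance threshold (default
#'   `generalization_threshold(466)`).
#' @param window_bp Proximity window around known variants (default
#'   500000).
#' @return `results` with `in_known_region` and `generalizes` columns.
#' @export
generalization_test <- function(results, known_regions, p_col = "Paspu",
                                threshold = generalization_threshold(466),
                                window_bp = 5e5) {
  in_region <- vapply(seq_len(nrow(results)), function(i) {
    k <- known_regions[known_regions$chromosome ==
                         as.character(results$Chromosome[i]), , drop = FALSE]
    nrow(k) > 0 && any(abs(k$position - results$Position[i]) <= window_bp)
  }, TRUE)
  results$in_known_region <- in_region
  results$generalizes <- ifelse(in_region, results[[p_col]] < threshold, NA)
  results
}

#' Region-count Bonferroni threshold for generalization
#'
#' `0.05 / n_regions`, rounded to three significant figures; for the 466
#' previously reported 1-Mb regions this is 1.07e-4.
#'
#' @param n_regions Number of previously reported genomic regions.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The threshold.
#' @export
generalization_threshold <- function(n_regions, alpha = 0.05) {
  signif(alpha / n_regions, 3)
}

#' Genome-wide significance threshold for the combined-phenotype analysis
#'
#' Bonferroni correction of `alpha` for the assumed number of independent
#' tests (10 million for a 1000-Genomes-imputed panel), giving 5e-9.
#'
#' @param n_tests Assumed number of independent tests (default 1e7).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The threshold.
#' @export
genomewide_threshold <- function(n_tests = 1e7, alpha = 0.05) {
  alpha / n_tests
}

#' Annotate LD proxies of a lead variant
#'
#' Flags variants whose dosage r-squared with the lead exceeds `r2_min`
#' (default 0.8, the conventional proxy definition) within the same
#' chromosome.
#'
#' @param panel A `variant_panel` providing the dosages.
#' @param lead_id Lead variant id.
#' @param r2_min Proxy threshold (default 0.8).
#' @return Data.frame of proxies: variant_id, position, r2.
#' @export
ld_proxies <- function(panel, lead_id, r2_min = 0.8) {
  meta <- panel$variant_meta
  j <- match(lead_id, meta$variant_id)
  if (is.na(j)) stop("lead variant not on panel: ", lead_id)
  lead_chr <- meta$chromosome[j]
  g <- panel$dosages[, j]
  same <- which(meta$chromosome == lead_chr & meta$variant_id != lead_id)
  r2 <- vapply(same, function(k) {
    suppressWarnings(ld_r2(g, panel$dosages[, k]))
  }, 0)
  keep <- !is.na(r2) & r2 > r2_min
  data.frame(variant_id = meta$variant_id[same][keep],
             position = meta$position[same][keep],
             r2 = r2[keep], stringsAsFactors = FALSE)
}
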