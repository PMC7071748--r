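#' Harmonize coded alleles across studies
#'
#' Aligns every record of one variant to the coded/other allele pair of the
#' first contributing study. A record whose alleles are swapped has its
#' effect negated and its coded-allele frequency complemented. Strand flips
#' (A<->T, C<->G) are resolved the same way after complementing. Ambiguous
#' palindromic variants (A/T or C/G) with frequency in [0.4, 0.6] cannot be
#' oriented reliably and are dropped with a warning; records whose alleles
#' match neither orientation are dropped too.
#'
#' @param records Data.frame of association records for one variant
#'   (columns Allele1, Allele2, Freq1, Effect, ...).
#' @return The harmonized records (possibly fewer rows); attribute
#'   `dropped` counts removed records.
#' @keywords internal
.harmonize_alleles <- function(records) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  a1 <- toupper(records$Allele1[1])
  a2 <- toupper(records$Allele2[1])
  pal <- identical(comp[[a1]], a2)
  keep <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    b1 <- toupper(records$Allele1[i]); b2 <- toupper(records$Allele2[i])
    if (pal && records$Freq1[i] >= 0.4 && records$Freq1[i] <= 0.6) {
      keep[i] <- FALSE
      warning("ambiguous palindromic variant ", records$MarkerName[i],
              " with frequency near 0.5 dropped")
      next
    }
    if (b1 == a1 && b2 == a2) next
    flipped <- !is.na(comp[b1]) && !is.na(comp[b2]) &&
      comp[[b1]] == a1 && comp[[b2]] == a2
    swapped <- (b1 == a2 && b2 == a1) ||
      (!is.na(comp[b1]) && !is.na(comp[b2]) &&
         comp[[b1]] == a2 && comp[[b2]] == a1)
    if (flipped) {
      records$Allele1[i] <- a1; records$Allele2[i] <- a2
    } else if (swapped) {
      records$Effect[i] <- -records$Effect[i]
      records$Freq1[i] <- 1 - records$Freq1[i]
      records$Allele1[i] <- a1; records$Allele2[i] <- a2
    } else {
      keep[i] <- FALSE
      warning("allele mismatch for ", records$MarkerName[i],
              " not resolvable; record dropped")
    }
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-subgroup association records across studies, per variant
#' and trait, with weights `w_i = 1/se_i^2`:
#' `beta = sum(w_i b_i)/sum(w_i)`, `se = 1/sqrt(sum(w_i))`. Between-study
#' heterogeneity is measured by Cochran's Q,
#' `Q = sum(w_i (b_i - beta)^2)` on `n_studies - 1` degrees of freedom.
#' Heterogeneity is reported, never used to filter. Records with missing
#' beta or se (e.g. subgroup-monomorphic variants) do not contribute; a
#' variant absent from every study for a trait yields no row.
#'
#' @param records Data.frame of association records from
#'   [run_univariate()], stacked across subgroups (one trait or several).
#' @param p_floor Lower bound for meta p-values (default 1e-300).
#' @return A data.frame with one row per (variant, trait): MarkerName,
#'   Chromosome, Position, Allele1, Allele2, Freq1 (weighted), Effect,
#'   StdErr, Zscore, P, N, Trait, QStat, QDf, QPval, NStudies. `QPval` is 1
#'   for a single contributing study.
#' @export
ivw_meta <- function(records, p_floor = 1e-300) {
  usable <- is.finite(records$Effect) & is.finite(records$StdErr) &
    records$StdErr > 0
  records <- records[usable, , drop = FALSE]
  if (nrow(records) == 0) return(records)
  key <- paste(records$MarkerName, records$Trait, sep = "\r")
  out <- lapply(split(records, key), function(g) {
    if (nrow(g) > 1) g <- .harmonize_alleles(g)
    if (nrow(g) == 0) return(NULL)
    w <- 1 / g$StdErr^2
    beta <- sum(w * g$Effect) / sum(w)
    se <- 1 / sqrt(sum(w))
    q <- sum(w * (g$Effect - beta)^2)
    qdf <- nrow(g) - 1L
    qp <- if (qdf > 0) stats::pchisq(q, qdf, lower.tail = FALSE) else 1
    z <- beta / se
    data.frame(
      MarkerName = g$MarkerName[1], Chromosome = g$Chromosome[1],
      Position = g$Position[1], Allele1 = g$Allele1[1],
      Allele2 = g$Allele2[1],
      Freq1 = sum(g$Freq1 * g$N) / sum(g$N),
      Effect = beta, StdErr = se, Zscore = z,
      P = max(2 * stats::pnorm(-abs(z)), p_floor),
      N = sum(g$N), Trait = g$Trait[1],
      QStat = q, QDf = qdf, QPval = qp, NStudies = nrow(g),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(MarkerName = character(0), Chromosome = character(0),
                      Position = integer(0), Allele1 = character(0),
                      Allele2 = character(0), Freq1 = numeric(0),
                      Effect = numeric(0), StdErr = numeric(0),
                      Zscore = numeric(0), P = numeric(0), N = integer(0),
                      Trait = character(0), QStat = numeric(0),
                      QDf = integer(0), QPval = numeric(0),
                      NStudies = integer(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$Trait, out$Chromosome, out$Position), , drop = FALSE]
}

#' Genomic inflation factor and QQ-plot coordinates
#'
#' The genomic inflation factor is the median of the association chi-square
#' statistics (`z^2`, or `qchisq(1 - p, 1)` when p-values are supplied)
#' divided by 0.4549364, the median of the chi-square distribution with one
#' degree of freedom. Under the null the expectation is 1; inflation above
#' 1 indicates residual stratification or miscalibration.
#'
#' @param z Numeric vector of association z-scores (either this or `p`).
#' @param p Numeric vector of p-values (used when `z` is missing).
#' @param trait Optional trait label carried into the result.
#' @return A list of class `genomic_control` with `trait`, `lambda`,
#'   `n` and `qq_points` (data.frame of expected and observed -log10 p,
#'   ascending).
#' @export
genomic_lambda <- function(z = NULL, p = NULL, trait = NA_character_) {
  if (is.null(z) && is.null(p)) stop("supply z or p")
  if (!is.null(z)) {
    z <- z[is.finite(z)]
    if (length(z) == 0) stop("no finite statistics supplied")
    chisq <- z^2
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- p[is.finite(p) & p > 0 & p <= 1]
    if (length(p) == 0) stop("no usable p-values supplied")
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chisq) < 100)
    warning("genomic lambda estimated from fewer than 100 statistics")
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  m <- length(p)
  obs <- sort(p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(obs))
  structure(list(trait = trait, lambda = lambda, n = m, qq_points = qq),
            class = "genomic_control")
}

#' @export
print.genomic_control <- function(x, ...) {
  cat(sprintf("Genomic control%s: lambda = %.4f (n = %d)\n",
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$lambda, x$n))
  invisible(x)
}
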