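---
title: "Combined-phenotype association with the adaptive SPU test: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-phenotype association with the adaptive SPU test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

### Univariate stage

Each quantitative trait is regressed on a variant's allele dosage under an
additive genetic model,

$$y = \alpha + \beta g + X\delta + \varepsilon,$$

where $g \in [0,2]$ is the coded-allele dosage and $X$ holds the linear
covariates (age, sex, study site, ancestral principal components — all
standardized, so their units never matter downstream). The fit is ordinary
least squares under complete-case analysis per trait; the per-variant fits
are computed by residualizing $y$ and the dosage columns on $X$ once
(Frisch–Waugh–Lovell) and running the resulting simple regressions in a
single matrix pass, with degrees of freedom adjusted for the covariates.
P-values use the normal approximation to the Wald $z$, the behavior of
standard GWAS software; at GWAS sample sizes the $t$ correction is
negligible, and a flag is not offered because every downstream statistic
consumes $z$, not $p$.

Phenotype QC excludes values more than 4 standard deviations from the
trait mean, with mean and SD taken over the pooled study population before
any exclusion. Pooling (rather than per-subgroup moments) follows the
convention that the exclusion should reference the overall distribution;
a `n_sd` argument exposes the multiplier. Variants are filtered on
imputation quality ($\ge 0.4$) and effective heterozygosity
$2\,\mathrm{CAF}(1-\mathrm{CAF})\,N\,q \ge 35$. The boundary is read
inclusively: a variant at exactly 35 is retained, because the exclusion
rule is stated as "below 35".

### Meta-analysis

Subgroup results are combined by fixed-effect inverse-variance weighting
($w_i = 1/se_i^2$), with Cochran's $Q = \sum_i w_i(\beta_i - \bar\beta)^2$
on $n_\text{studies}-1$ degrees of freedom reported but never used to
filter. Coded alleles are harmonized to the first contributing study;
swapped alleles negate $\beta$ and complement the frequency, strand flips
are resolved by complementing, and palindromic (A/T, C/G) variants with
frequency in $[0.4, 0.6]$ are dropped — their orientation cannot be
determined, and silently keeping them risks sign errors. The genomic
inflation factor is $\lambda = \mathrm{median}(z^2)/0.4549364$.

### The adaptive SPU test

The combined-phenotype engine consumes the variants × traits z-score
matrix. The null correlation $\hat\Sigma$ of z-scores across traits —
induced by computing all traits on the same samples — is estimated as the
Pearson correlation of z columns over variants that look null ($|z| < 2$
in every trait, falling back to all variants when too few remain), with a
nearest-PSD repair if sampling noise leaves the matrix indefinite. True
signals are sparse in a genome-wide panel, so the null-selection rule and
the all-variants rule converge; the rule used is recorded in the result.

Given $B$ draws from $N_K(0,\hat\Sigma)$, each power $\gamma$ in
$\{1,\dots,8,\infty\}$ yields a Monte-Carlo p-value
$(1 + \#\{|SPU_\text{null}| \ge |SPU_\text{obs}|\})/(B+1)$; absolute
values on both sides make odd powers two-sided and even powers one-sided
in magnitude, the convention of the original test. The adaptive p-value
compares the observed minimum across the family with each null draw's own
leave-one-out minimum (computed against the other $B-1$ draws). The
$(1+\text{count})/(B+1)$ tie rule bounds every p-value in
$(0, 1]$ with floor $1/(B+1)$.

Two numerical points matter here. First, the leave-one-out minima are
computed with ranks in $O(B \log B)$ per power; the test suite verifies
exact agreement with the literal $O(B^2)$ double loop. Second, the power
$\gamma = 0$ is excluded by default: $SPU(0) = K$ is constant, its
Monte-Carlo p-value is 1 by the tie rule, and it can never win the
minimum, so including it (possible via `gamma_set`) changes nothing but
wastes a column.

Missing z-scores (a variant absent from a trait's meta-analysis, e.g.
monomorphic in every contributing subgroup) are substituted with 0 and
flagged rather than dropping the variant. Dropping would make
ancestry-specific variants untestable — exactly the variants a
multi-ethnic analysis exists to find; the flag supports sensitivity
reruns.

### Staged Monte-Carlo escalation

A production floor of $1/(1+B)$ at $B = 10^{11}$ cannot be reached by
materializing $B$ draws. The package's schedule evaluates all variants at
the smallest $B$, then re-evaluates at the next stage only variants with
$p \le 10/B$ — within an order of magnitude of the current floor, where
the estimate is still resolution-limited. P-values far from the floor are
already precise (relative MC error $\approx \sqrt{(1-p)/(pB)}$), so
promotion cannot lose a truly significant variant; the suite checks that
promoted variants reproduce the single-big-run p exactly and that
everything significant at the end was evaluated at the final stage. The
default schedule $10^3, 10^4, 10^5$ is a desk-scale choice; the escalation
factor of 10 is conventional, and nothing in the algorithm depends on it.

### Conditional analysis, loci, generalization

Round 0 takes the most significant variant per 10-Mb window (fixed tiles
anchored at position 1 — tiling is the simplest deterministic reading of
"windows on each chromosome"; exact p ties break to the smaller
position). Each subsequent round adds every current lead's dosage as a
covariate to every trait model on the shared chromosome, re-runs
meta-analysis and aSPU on the conditioned results, and promotes new
window leads, until nothing is significant. Conditioning on a lead twice
is a no-op: the duplicate column is detected as collinear and dropped
with a warning.

Loci are ±500-kb windows around leads, merged transitively when leads
chain (A–B 400 kb, B–C 400 kb ⇒ one locus), which is how a single locus
can legitimately carry many conditionally independent signals — the
structural scenario the acceptance suite reproduces with five planted
signals, two of them subgroup-monomorphic. LD proxies are variants with
dosage $r^2 > 0.8$ with the lead. Generalization of previously reported
regions uses $0.05/466 = 1.07 \times 10^{-4}$ (three significant
figures), applied to variants within 500 kb of a known variant; variants
outside known regions are not evaluated rather than counted as failures.

The stop criterion applies to the combined-phenotype p-value only; the
`trait` argument of the univariate stage supports per-trait sensitivity
reruns, and conditioning on an arbitrary user-supplied dosage column
(e.g. a structural variant) is the same code path as conditioning on a
lead SNP — no special case.

## 2. What the simulator emulates, and what it does not

The generator exists because no individual-level data from the motivating
study design is distributable; it reproduces the features each downstream
stage actually exercises:

* **Genotypes.** Two haploid alleles per sample under Hardy–Weinberg at
  subgroup-specific frequencies; a Gaussian copula with AR(1) structure
  (latent correlation `ld_rho`) within blocks of `ld_block_size`
  variants, independence across blocks. This is the simplest mechanism
  giving tunable $r^2$ for testing conditioning and proxy logic. Note the
  dosage-scale correlation is attenuated relative to the latent `ld_rho`,
  increasingly so as the two variants' frequencies diverge (thresholding
  a bivariate normal); tests that pin down $r^2$ magnitudes therefore use
  matched frequency ranges.
* **Imputation uncertainty.** Deterministic shrinkage of each dosage
  toward its expectation $2p$ by $\sqrt{q}$, so the dosage variance is
  $q \cdot 2p(1-p)$ — the variance-ratio reading of imputation quality
  that the effective-heterozygosity filter assumes. A probabilistic
  re-draw would emulate imputation more literally but would make the
  filter's inputs noisy and the generator harder to reason about;
  determinism was preferred.
* **Phenotypes.** Each trait is the sum of planted standardized effects
  on centered/scaled dosages, shared linear covariate effects, and a
  multivariate-normal residual with the package's default seven-trait
  correlation matrix. The pinned entries are HCT–HGB 0.94, HGB–RBCC 0.68
  and HCT–MCHC −0.02; the remaining entries were chosen once to be
  physiologically plausible while keeping the matrix positive definite
  (smallest eigenvalue ≈ 0.034) and are not revisited. All traits are
  standardized: physical units affect no statistic the pipeline computes.
* **Ancestry structure.** Subgroup-specific allele-frequency ranges and
  subgroup-monomorphic variants (random fraction, or targeted indices
  via `monomorphic_variants`) reproduce the ancestry-specific-variant
  scenario; monomorphic variants get constant dosage 0 and fail the
  heterozygosity filter in that subgroup, so their evidence comes from
  the subgroups where they segregate.
* **Effect sizes.** No effect-size distribution is asserted; effects are
  configuration. Where the test suite plants effects it uses standardized
  betas of 0.12–0.2 — large on purpose, since the recovery properties
  being tested concern the iteration logic, not power at realistic GWAS
  effect sizes.

Not emulated: realistic human LD maps and recombination hotspots,
admixture tracts, family structure (the motivating design's related
subgroup used generalized estimating equations; here all samples are
unrelated and OLS is exact), genotyping batch artifacts, and non-normal
trait distributions. Passing tests therefore demonstrate the correctness
and calibration of the statistical machinery under its stated model, not
robustness to every pathology of real cohort data.

## 3. Null-correlation estimation at desk scale

A genome-scale analysis estimates $\hat\Sigma$ from millions of variants,
making its sampling error negligible. The package's small simulated
regions (tens of variants) cannot: a $7 \times 7$ correlation estimated
from ~30 null variants errs by up to ~0.4 per entry, which distorts
exactly the extreme tail the adaptive test calibrates.
`estimate_null_corr()` warns below 1000 variants for this reason, and the
planted-signal scenarios in the tests and the acceptance script supply
the known residual correlation as $\Sigma$ instead — the desk-scale
equivalent of the genome-scale estimate. On panels of a few hundred
variants or more the estimated and known matrices give matching results.

## 4. Problem sizes and thresholds used by the tests

The suite runs simulations at the sizes a laptop handles comfortably:
subgroups of 800–1500 samples, regions of 20–500 variants, Monte-Carlo
references of $10^3$–$10^6$ draws, 5000-variant type-I sweeps at
$B = 10^4$, and 20-seed replications of the signal-recovery scenarios.
Where a scenario needs a significance threshold, it is chosen so the
Monte-Carlo floor is attainable at the scheduled $B$ (e.g. $3 \times
10^{-4}$ with $B_\max = 10^4$, floor $10^{-4}$); the production defaults
remain $5 \times 10^{-9}$ with the understanding that a production
schedule reaches a correspondingly large $B$. These are statements about
the demonstration scale, not about the method.

## 5. Known limitations

* Conditional analysis requires individual-level dosages; there is no
  summary-statistic approximation (GCTA-COJO style) in this version.
* Fixed-effect meta-analysis only; heterogeneity is reported, not
  modeled.
* The adaptive p-value is resolution-limited at $1/(B+1)$; claims below
  the floor of the configured schedule are impossible by construction.
* The command-line entry point (`inst/scripts/aspupipe.R`) is a thin
  wrapper over `run_pipeline()`; R users should call the functions
  directly, which expose everything the wrapper does and more.
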