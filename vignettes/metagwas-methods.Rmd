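---
title: "Methods: stratified GWAS meta-analysis, fine-mapping and downstream inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified GWAS meta-analysis, fine-mapping and downstream inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagwas)
```

This vignette documents the models behind `metagwas`, the parameters that
matter and their defaults, what the simulators do and do not emulate, and
the numerical decisions taken where the underlying methodology leaves
room.

## The stratified meta-analysis model

The data model is a collection of strata — independent case-control
genotyping projects analysed separately by logistic regression — each
contributing a per-allele log odds ratio $\hat\beta_{jk}$ with standard
error $\tau_{jk}$ for variant $j$. Strata are pooled by fixed-effects
inverse-variance weighting; Cochran's $Q$, $I^2$ and a
DerSimonian–Laird random-effects fit quantify between-stratum
heterogeneity. The fixed-effects estimate is the generalized
least-squares solution for a common mean, and the test suite holds the
implementation to that oracle at $10^{-12}$.

Filtering follows consortium practice and is strict on boundaries: a
stratum result is excluded when info $< 0.4$, folded MAF $< 0.005$, or
the OR lies outside $(1/3, 3)$ — values exactly on a boundary are
retained. The OR bound is evaluated on the log scale
($|\beta| > \ln 3$), which avoids spurious exclusions from
floating-point round-trips through `exp`. MAF is folded as
$\min(p, 1-p)$: the only frequency-symmetric reading. After pooling,
variants with results in fewer than 2 strata or with heterogeneity
$P < 5\times10^{-8}$ are dropped, and every exclusion is written to an
audit table rather than silently discarded.

Genomic inflation uses the median-$\chi^2$ estimator
$\lambda = \mathrm{med}(\chi^2)/0.4549$ — the standard genomic-control
definition, robust to a small fraction of true signal — and is rescaled
to a notional 1000/1000 study by the usual linear (Freedman) relation so
that studies of different size are comparable.

## Input conventions

Summary files are tab-separated with aliased column names (consortium
files disagree on headers, so the alias map is data, not code). Effects
may arrive as `beta`+`se`, OR with a 95% CI, or OR with a P-value. When
both a CI and a P are available the standard error is derived from the
P-value, $\tau = |\beta|/\Phi^{-1}(1-P/2)$: printed P-values carry more
significant digits than printed CI bounds, and the package's
reproductions of published BFDP and FRR figures confirm that the
P-derived $\tau$ tracks the original unrounded values more closely. The
inverse normal is evaluated through the upper tail
(`qnorm(p/2, lower.tail = FALSE)`), because $1 - p/2$ rounds to 1 in
double precision once $p < 10^{-16}$ — genome-wide P-values would
otherwise produce zero standard errors.

Positions in summary files are 1-based (build carried as metadata); BED
inputs are 0-based half-open. The single conversion rule — a SNP at
1-based $q$ overlaps $[s,e)$ iff $s \le q-1 < e$ — is owned by the
overlap module and tested against a brute-force scan.

Allele harmonization flips swapped records ($\beta \to -\beta$,
$p \to 1-p$), complements opposite-strand records, and flags A/T and C/G
pairs with frequency in $[0.4, 0.6]$ as strand-ambiguous rather than
guessing. Multi-allelic and indel allele strings are accepted verbatim;
reconciling them across imputation panels is left to the caller.

## Locus definition and fine-mapping

Genome-wide-significant variants ($P < 5\times10^{-8}$) seed ±500 kb
windows, merged when they overlap; windows around known leads can be
masked so previously reported loci are not re-counted. Lead selection is
deterministic: minimum $P$, then minimum $\tau$, then lexicographic
variant id.

Conditional analysis re-estimates a target's effect given a set of index
variants from marginal summary statistics plus a reference LD
correlation matrix. Effects are standardized by $\sqrt{2p(1-p)}$, the
joint coefficients solve $R\,a = b$ on the condition set plus target,
with covariance $R^{-1} D R D R^{-1}$ ($D$ the diagonal of standardized
standard errors), and the target's estimate is mapped back to the
per-allele scale. This linearizes the logistic model — standard for
summary-data joint analysis — and the acceptance suite quantifies the
approximation against individual-level joint regression on simulated LD
blocks: conditional estimates fall within 3 joint-model standard errors
of the oracle in ≥95% of blocks. Systems containing a pair with
$r^2 > 0.9$ (configurable) are refused with the offending pair named;
the stepwise secondary-signal search additionally requires conditional
$P < 5\times10^{-8}$ and $r^2 < 0.05$ against every selected signal.

Credible sets use the Wald relative likelihood
$\Lambda_j = \exp((z_j^2 - z_{\mathrm{lead}}^2)/2)$ — the only
likelihood ratio computable from summary data — with the inclusive
boundary $\Lambda \ge 0.01$. A $10^{-9}$ relative guard keeps variants
sitting exactly on the 1:100 boundary inside the set despite one-ulp
float noise. Windows are anchored on the lead variant, not the merged
locus span; when loci merge these can differ, and the choice is
deliberate (the likelihood comparison is against the lead).

BFDP follows Wakefield's approximate Bayes factor with prior probability
of association $\pi = 10^{-4}$ and prior variance
$W = (\ln 1.5 / 1.96)^2$, i.e. the prior's 97.5th OR percentile equals
the maximum plausible OR of 1.5. That convention — rather than, say, a
95th percentile — is validated by reproducing published BFDPs (98% for a
non-replicating variant, ≤4% across nine novel loci) from printed ORs
and P-values to within a percentage point.

## Familial relative risk

Under a log-additive model the per-variant contribution is
$p_j(1-p_j)(\beta_j^2 - \tau_j^2)$, summed and divided by $\ln\lambda$
with $\lambda = 2$ the familial relative risk of endometrial cancer.
Subtracting $\tau_j^2$ debiases $\hat\beta_j^2$; consequently pure-noise
variants contribute negatively, and such contributions are kept (with a
warning) because flooring them would bias sums upward. The estimator's
unbiasedness is verified by simulation, and additivity over disjoint
sets is a tested invariant. The per-variant effective sample size
$N_j = 1/(2p_j(1-p_j)\tau_j^2)$ and the frailty-scale conversion
$h_f^2 / (2\ln\lambda)$ are provided for heritability workflows; running
LD-score regression itself is out of scope.

## Mendelian randomization

`mr_ivw()` is fixed-effect IVW: a $1/\mathrm{se}_Y^2$-weighted
regression of outcome on exposure associations through the origin.
Exposure-side standard errors are ignored in the weights (the cited
two-sample convention; no measurement-error correction), so simulations
that probe unbiasedness use tight exposure SEs. A multiplicative
random-effect inflation ($\mathrm{se} \times \sqrt{Q/\mathrm{df}}$ when
$Q > \mathrm{df}$) is available but off by default — the reproduced
analyses describe plain inverse-variance weighting. `mr_mvivw()` fits
both exposure columns jointly (weighted least squares, no intercept,
fixed-effect covariance $(X'WX)^{-1}$), so the primary-exposure
coefficient is the direct effect net of the mediator; an all-zero
mediator column degrades gracefully to univariable IVW. Pleiotropy-robust
estimators (Egger, median) are intentionally absent.

## Case-only subtype heterogeneity

The primary test is logistic regression of the subtype indicator on
dosage among cases; its coefficient estimates the difference of
subtype-specific case-control log ORs. Perfect separation falls back to
the exact test on the collapsed allele-count table. A summary-level
contrast $z = (\beta_1-\beta_2)/\sqrt{\tau_1^2+\tau_2^2}$ is provided
for when only subgroup results exist, but it assumes independent
subgroups — false when subgroups share controls — and is labelled
approximate; it is never used as a stand-in for the case-only test in
validation.

## Enrichment

Overlap fractions of two SNP sets with a feature collection are compared
by Fisher's exact test, two-sided by the probability-mass rule (the sum
of hypergeometric outcomes no more probable than the observed table),
checked against full enumeration of the support. The reported odds ratio
is the sample cross-product ratio, matching how such contrasts are
usually quoted. Zero-margin tables return $P = 1$ with a warning instead
of failing. "Overlapped at least one feature" means the union across all
supplied feature sets; per-feature counts are also returned.

## What the simulators emulate — and what they do not

`sim_config()` defaults describe a 17-stratum design totalling 12,906
cases and 108,979 controls: a large array-consortium stratum
(4710/19,438), a biobank stratum with a huge control excess
(636/62,853), two medium strata (2271/2219, 424/558), a small matched
study (288/1440), and twelve strata sharing the remainder evenly. The
sampling model is the summary-level normal approximation
$\hat\beta_{jk} \sim N(\beta_j, \tau^2_{jk})$ with
$\tau^2_{jk} = [2p_j(1-p_j)\,\mathrm{info}_{jk}\,n_{\mathrm{eff},k}]^{-1}$,
$n_\mathrm{eff} = n_1 n_0/(n_1+n_0)$ — consistent with the effective-N
relation above at info = 1. Missingness is per-(variant, stratum)
Bernoulli (default 2%) so the minimum-strata filter is exercised.
Allele frequencies are uniform on (0.05, 0.95), info uniform on
(0.7, 1), causal effects $N(0, 0.1)$ on 1% of variants — ORs of
1.1–1.3 at common frequencies, the magnitude typical of the reproduced
loci.

Individual-level simulation exists only where an oracle needs it: LD
blocks (AR(1) latent Gaussians thresholded to haplotypes, quantitative
phenotype, marginal regressions) power the conditional-analysis checks,
and binomial dosage draws power the case-only checks. The generators do
not attempt realistic genome-wide LD, population stratification,
winner's-curse selection of lead SNPs, or case-control phenotypes for
the LD blocks (the conditional machinery is itself a linear
approximation, so a linear oracle is the right comparison). Passing
tests therefore demonstrate correctness of the statistical machinery
under its stated assumptions, not robustness to confounding or selection
effects present in real consortium data.

All generators are deterministic under a fixed seed.

## Problem sizes used in validation

The suites run at sizes chosen to make Monte-Carlo bands decisive while
keeping the full run in tens of seconds: 5000 replicates for pooled-CI
coverage (band 95% ± 1.5%), $10^6$ null z-scores for the inflation check
(λ within [0.99, 1.01]), 200 five-SNP LD blocks of 5000 individuals for
conditional-analysis fidelity, 500 replicates at 77 instruments and 200
at 368 for MR recovery, 2000 replicates for each null-calibration check
(binomial 3σ bands), and $10^4$ SNPs against random BEDs for the overlap
oracle.

## Known limitations

- The conditional-joint solver assumes the LD reference matches the
  analysis population; reference mismatch is not modelled.
- Fixed-effect MR standard errors ignore exposure-side uncertainty and
  instrument heterogeneity unless the random-effect option is enabled.
- The case-only model omits covariates (principal components are
  assumed to have been handled upstream, in the stratum analyses).
- Printed-table reproductions inherit the rounding of published ORs,
  frequencies and P-values; reproduced FRR shares land slightly below
  the published figures, consistent with their "up to" framing.
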