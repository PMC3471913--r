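---
title: "Regional heritability mapping: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability mapping: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhm)
```

## The model

Regional heritability mapping partitions additive genetic variance into a
whole-genome component and a component attributable to a short genomic
window.  For trait values $y$ and fixed effects $X\beta$ the per-window
model is

$$ y = X\beta + u + v + e, \qquad
   u \sim N(0, \sigma^2_u G), \quad
   v \sim N(0, \sigma^2_v Q), \quad
   e \sim N(0, \sigma^2_e I), $$

with one record per individual, so the random-effect incidence matrix is
the identity.  $G$ is the genomic relationship matrix built from all
SNPs; $Q$ is built identically from the window's SNPs only.  Writing
$\sigma^2_p = \sigma^2_u + \sigma^2_v + \sigma^2_e$, the quantities of
interest are the regional heritability $h^2_v = \sigma^2_v/\sigma^2_p$,
the residual whole-genome heritability $h^2_u = \sigma^2_u/\sigma^2_p$
and their sum.  The method's premise is that in samples containing both
close and distant relatedness, a window-level variance component
integrates over the gametic variance of the region and so collects the
joint contribution of several causal variants — common or rare — that
single-SNP regression dilutes.

Both matrices use the allele-frequency-weighted identity-by-state
kinship
$$ f_{ij} = \frac{1}{n}\sum_k
   \frac{(g_{ik}-p_k)(g_{jk}-p_k)}{p_k(1-p_k)}, $$
with genotypes coded $0, \tfrac12, 1$ (rare homozygote, heterozygote,
common homozygote) and $p_k$ the major-allele frequency, so the mean
coded genotype of a SNP *is* its major-allele frequency.  Relationship
matrices carry $2f_{ij}$ off the diagonal and $2f_{ii}$
(expectation $1+F$) on it.  Pairwise-complete SNP sets with per-pair
divisors handle missing genotypes without imputation; monomorphic SNPs
are skipped; a pair sharing no usable SNPs inside a window is an error
rather than a silent zero.  Frequencies are computed once on the full
analysed sample and reused for every window, so $G$ and all $Q$ share a
scale; the window's markers are *not* removed from $G$, whose tiny
resulting correlation with $Q$ is conservative for detecting regional
variance.

## Quality control and windows

Defaults follow common array-genotyping practice: individuals are
filtered first (call rate $\ge 0.97$), then SNPs on the retained sample
(call rate $\ge 0.98$, MAF $\ge 0.02$, Hardy–Weinberg $p \ge 10^{-6}$
from a 1-df Pearson $\chi^2$; an exact test is not needed at these
sample sizes).  Filtering individuals first makes SNP statistics reflect
the analysed sample.  Major-allele ties (frequency exactly 0.5)
deterministically designate the second `.bim` allele as major.  When
cohorts are merged, strand flips are resolved for unambiguous allele
pairs; A/T and C/G SNPs whose allele order differs are dropped, because
a swap cannot be told from a strand flip.

Windows of `size` SNPs shifted by `shift` (defaults 100/50) tile each
chromosome: SNPs 1–100, 51–150, 101–200, ….  After the last full
window, a truncated window starting at the next regular offset is
emitted iff it covers SNPs beyond the last full window *and* contains at
least `size/2` SNPs; so 275 SNPs yield windows starting at 1, 51, 101,
151 plus a trailing 201–275, while 200 SNPs yield exactly three
windows.  Chromosomes with fewer than `size/2` SNPs yield none, with a
warning.  This keeps chromosome ends analysable while keeping windows
comparable.

## REML

`reml_fit()` maximizes the restricted log-likelihood
$$ \ell = -\tfrac12\big(\log|V| + \log|X'V^{-1}X| + y'Py\big), \qquad
   V = \textstyle\sum_c \sigma^2_c K_c + \sigma^2_e I, $$
omitting the additive constant everywhere (only differences are used).
The optimizer is average-information REML — the AI matrix
$\mathrm{AI}_{cd} = \tfrac12\, y'PK_cPK_dPy$ and gradient
$-\tfrac12(\mathrm{tr}(PK_c) - y'PK_cPy)$ — with three EM warm-up
iterations for stability from the scale-free start
$\hat\sigma^2_{p}/(k+1)$ per component, and step-halving whenever an AI
step would decrease the likelihood or drive a variance negative
(negative proposals are clamped to zero).  Components on the zero bound
with negative gradient are held there but *kept in the model*, so
log-likelihoods remain comparable across windows; convergence is
declared when the likelihood improves by less than $10^{-6}$ (at most
200 iterations, with a `converged` flag otherwise).  A singular $V$ is
retried once with a ridge of $10^{-8}\sigma^2_p$ on the residual kernel.
Standard errors come from the inverse AI matrix and are reported as
such — they are not trusted near bounds.  A cited two-step scheme (fix
$\hat\sigma^2_u$ from a genome-only fit, then estimate $\sigma^2_v$ per
window) is available as `two_step = TRUE` for speed, but the default is
the full joint REML per window, which is exact and affordable at the
sample sizes this package targets.

The window test is $\mathrm{LRT} = 2(\log L_1 - \log L_0)$, floored at
zero so numerical noise in near-null windows cannot produce negative
statistics.  Under the null the regional variance sits on the boundary
of its parameter space, so the LRT is asymptotically
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; `mixture_pvalue()` implements the
corresponding survival function.  The scan fits the genomic-only null
once (it does not depend on the window) and reuses the single $G$ for
every window.

## Thresholds

Half-overlapping windows are counted as half-independent:
$m_\mathrm{eff} = N/2$ for $N$ windows, kept as a real number.  The
genome-wide threshold inverts the mixture survival at
$0.05/m_\mathrm{eff}$; the suggestive threshold at $1/m_\mathrm{eff}$,
i.e. one expected false positive per scan.  For $N = 5511$ these give
LRT 17.1 and 11.4, equivalent to $-\log_{10}p$ of 4.75 and 3.44.  The
single-SNP comparator uses the ordinary Bonferroni $-\log_{10}(0.05/m)$,
6.7 for 275,564 markers.  Enrichment of scan regions for externally
reported loci uses the exact binomial tail
$\Pr(X \ge k),\, X \sim \mathrm{Bin}(n_\mathrm{loci},
\mathrm{span}/3\,\mathrm{Gb})$.

## Permutation

`permutation_scan()` permutes individuals against each window's regional
matrix (rows and columns by one random permutation — a similarity
transform, so the spectrum is untouched) while phenotypes, fixed effects
and $G$ stay intact: overall heritability structure survives, regional
signal is destroyed, and because each window is permuted independently
all permuted tests are mutually uncorrelated.  Each replicate is one
genome scan; observed $-\log_{10}$ mixture p-values are paired with
uniform order statistics for Q-Q output.  Permuting phenotypes instead
would destroy the polygenic structure and is deliberately not offered.

## The synthetic-data generator

`sim_population()` emulates a population-isolate sample: founder
haplotypes with first-order Markov LD (a site copies the previous site's
latent uniform with probability $\rho$, giving exactly correlation
$\rho$ between equal-frequency neighbours and geometric decay with
distance), dropped through a village-structured pedigree with Poisson
family sizes, configurable migration, and Haldane recombination.  All
generations are genotyped; the pedigree is returned for validation only
and is never visible to analysis code.  Defaults (120 founders, 3
generations, mean 2.5 offspring, 3 villages, 10% migration,
$\rho = 0.9$, MAF uniform on [0.02, 0.5]) produce a few hundred
individuals with abundant full-sib and deeper relationships, the regime
the method is designed for.  `simulate_phenotype()` builds traits as
fixed effects + polygenic value + regional QTL values + noise, rescaling
every component to its target variance fraction *exactly* in the sample
(so recovery tests have exact truths); presets of interest are 30%
background heritability (a moderate-heritability trait such as serum
urate) and 80% (height).

An optional `maf_blocks` frequency profile partitions SNPs into
alternating low- and high-MAF classes of 25, with the low class mutually
unlinked (`rho_low = 0`: rare alleles arise on independent founder
haplotypes and are poorly tagged, as in real data) and the high class
arranged in small frequency-matched LD blocks (tight pairs in the power
study), so each 50-SNP window contains a well-tagged common class and a
poorly tagged rare class — the structure the embedded-QTL power design
sorts on.

What the generator does *not* emulate: coalescent allele-frequency
spectra, realistic recombination hotspots, genotyping error, population
admixture beyond discrete villages, or ascertainment of array SNPs.
Passing tests therefore demonstrate correctness and calibration of the
machinery on isolate-like relatedness structures, not performance on any
particular real cohort.

## The power experiment

`run_power_experiment()` follows the embedded-QTL design: in each 50-SNP
window, 1, 5 or 10 QTL are drawn from the 25 highest- or 25 lowest-MAF
SNPs (ties broken by position), additive effects with equal variance
shares and random signs are added to the observed trait, the summed
values are mean-centred and rescaled so the realized added variance is
exactly the requested fraction of the trait variance, and the QTL are
removed from the marker set (windows of 49/45/40 markers remain).  Each
augmented dataset is analysed both ways against its own Bonferroni
thresholds: the regional LRT, and single-marker score tests of the
remaining window markers.  The default added fraction is 2.5% of the
phenotypic variance.  The acceptance-level power study runs at n = 600
with 30 windows and an added fraction of 10%: with roughly one fifth of
the reference sample size, holding the detectability product
$n \cdot h^2_v$ at its reference value is the canonical way to scale the
design down, and the comparisons are qualitative (patterns, not power
values).

## Single-SNP comparator

`snp_score_test()` is the GRAMMAR/mmscore-style statistic
$(g'\hat Py)^2/(g'\hat Pg)$ with $\hat P$ from the genomic-only REML
fit, variance parameters estimated once and held fixed across SNPs; it
equals the squared GLS t-statistic at known $V$.  Missing genotypes
either drop their individuals (the projection is rebuilt exactly on the
complete subset at fixed variances) or are mean-imputed
(`missing = "mean"`, $O(n^2)$ per SNP).

## Numerical and design notes

* Follow-up fits of candidate regions (`joint_fit_regions()`) slide a
  batch of up to five non-overlapping regions one region at a time
  through the report order; each region's minimum, maximum and mean
  estimate across its batches is reported next to its single fit and the
  fully joint model.  Overlapping regions in one batch are an error
  (shared SNPs make the kernels collinear).
* Where overlapping adjacent windows both exceed a threshold, summaries
  count only the highest-LRT window of the run.
* `scan_with_snp_covariates()` appends dosage-coded SNP columns to $X$;
  the zero-SNP case reproduces the plain window fit exactly, and
  individuals missing a covariate genotype are dropped for that fit.
* Eigenvector covariates (`pca_covariates()`) fix signs so the
  largest-magnitude entry is positive; degenerate spectra (identity-like
  $G$) make individual components arbitrary.
* Test problem sizes are the package's desk-scale study conditions:
  parameter recovery at n = 500 / 2000 SNPs / 100 replicates; the
  permutation calibration at ~320 individuals, 10 windows x 20
  replicates; the power study at n = 600, 30 windows; the
  covariate-adjustment study at n = 450, 20 replicates.  At these scales
  a 100-SNP window is a few percent of the simulated genome (against
  ~0.04% of a real array), which slightly couples $Q$ and $G$; the
  recovery test shows the resulting bias is within Monte-Carlo error at
  the chosen conditions.

## Known limitations

Dense algebra throughout: fits are $O(n^3)$ per window, comfortable to a
few thousand individuals but not biobank scale.  Only autosomes and a
single record per individual are supported; no dominance or
interaction kernels; no haplotype- or IBD-based regional matrices; AI
standard errors near variance bounds are approximate; and the suggestive
threshold convention (one false positive per scan over
$m_\mathrm{eff} = N/2$ tests) is a documented choice rather than a
universal standard.
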