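---
title: "Summary-based conditional/joint analysis and risk-score evaluation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-based conditional/joint analysis and risk-score evaluation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cojoscore)
```

## The estimation problem

A GWAS meta-analysis publishes, per SNP, a marginal log odds ratio
$b_j$, its standard error $s_j$, the effect-allele frequency $p_j$, a
p-value, and a per-SNP sample size $n_j$ (non-integer for
meta-analyses, since cohorts contribute unevenly across SNPs).  Joint
re-estimation of several SNPs at one locus would normally need the
individual-level genotype matrix $X$ and phenotype $y$, which are not
available.  The package reconstructs the least-squares normal equations
from summary quantities plus a reference panel:

$$
(X'X)_{jj} = n_j v_j,\qquad
(X'X)_{jk} = r_{jk}\sqrt{v_j v_k}\,\min(n_j, n_k),\qquad
(X'y)_j = n_j v_j b_j,
$$

with $v_j = 2p_j(1-p_j)$ the Hardy–Weinberg dosage variance and
$r_{jk}$ the LD correlation between *effect-allele* dosages estimated
in the reference panel.  Joint effects solve
$X'X\,\beta = X'y$; the residual variance is
$\hat\sigma^2 = (y'y - \beta'X'y)/(n_{\rm dof} - k)$, and Wald
p-values use a normal reference.

Because $y'y$ is also unobserved, each SNP implies an estimate
$y'y_j = D_{jj} b_j^2 + D_{jj} s_j^2 (n_j - 1)$, and the working value
is the **median** over the region's SNPs — robust to individual SNPs
with mis-reported $n_j$.  Degrees of freedom use the median $n_j$ of
the selected set, again because $n_j$ varies widely within a
meta-analysis.  Off-diagonal sample sizes use $\min(n_j,n_k)$: the
overlap of two subsamples is at most the smaller one, and
underestimating the off-diagonal mass is the conservative direction.
If the approximated inputs ever produce $\hat\sigma^2 \le 0$, the fit
falls back to $y'y/n_{\rm dof}$ and flags the result rather than
emitting undefined standard errors.

Three exactness properties anchor the implementation and are asserted
in the tests:

* with all $r_{jk}=0$ the joint effects equal the marginal ones
  exactly, for any set size;
* for two SNPs with equal $n$, the standardized closed form
  $\beta_1^{J} = (b_1^{s} - r\,b_2^{s})/(1-r^2)$ holds to $10^{-10}$;
* when the marginal statistics, the LD matrix, **and** the per-SNP
  dosage variances all come from one complete quantitative-trait
  sample, the joint solution reproduces multiple-regression OLS
  coefficients to $10^{-6}$ relative error.  Exactness requires the
  empirical dosage variances, so `joint_fit()` accepts a `var_x`
  override; the default $2p(1-p)$ is the correct choice for real
  summary data, where the sample variance is unavailable.

## Stepwise selection

`stepwise_select()` mirrors classical forward–backward selection, run
on the approximated system: seed with the region's smallest marginal
p-value (if it passes the threshold); then alternately (i) evaluate
every non-selected SNP conditional on the current model — a candidate's
conditional statistics are its coefficient, SE and Wald p in a joint
fit over the model plus that candidate — adding the best passing
candidate, and (ii) refit the whole model jointly, dropping, worst
first and one per refit, any SNP whose joint p-value no longer passes.
The procedure stops when an iteration changes nothing, or at `max_iter`
(default 100, flagged as non-convergence).

Candidates whose maximum $r^2$ with any model SNP exceeds 0.9 are
skipped: beyond that, $X'X$ approaches singularity and the "two SNPs"
carry one signal.  All ties break deterministically by
(p-value, position, identifier), so the procedure is a pure function of
its inputs.  Regions are analyzed independently (cross-region LD is
treated as zero), matching the ±1 Mb per-locus restriction of the
analysis design; the lead SNP of a region is the marginal-p argmin over
the closed 2 Mb interval.

The threshold ladder 5×10⁻⁸, 5×10⁻⁷, 5×10⁻⁶, 5×10⁻⁵, 5×10⁻⁴ is swept
by refitting from scratch at each threshold; models at stricter
thresholds need not nest in looser ones and the code makes no such
claim.

## Reference-panel handling

The LD panel is quality-controlled the way imputation-era reference
cohorts are prepared: imputation-quality filter (info < 0.6, when
supplied), missingness > 10%, minor-allele frequency < 0.5%, and a
1-df Hardy–Weinberg chi-square at p < 0.005, applied in that order.
Imputed dosages are hard-called with open uncertainty bands
(0.33, 0.66) and (1.33, 1.66): dosages strictly inside a band become
missing, everything else rounds to {0, 1, 2}.  The band rule is applied
at the *genotype* level — masking individual calls — because dropping
any SNP with a single uncertain call would discard nearly everything; a
`snp_level = TRUE` option implements the stricter reading.  Band
endpoints round rather than mask; this affects only measure-zero
inputs.  LD is computed on the hard-called dosages (pairwise-complete,
with per-pair counts retained), while validation-cohort scoring uses
raw dosages untouched — hard-calling a scoring cohort would discard
information for no benefit.

Relatedness pruning uses the standard genomic relationship
$A_{ij} = m^{-1}\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k)/(2p_k(1-p_k))$ and
greedily removes, from each pair at or above 0.025, the member with
more over-threshold partners (ties to the later sample id) until no
pair remains.

Allele harmonization orients every summary SNP to the panel's counted
allele; flips preserve $|b|$, $s$, $p$ and $n$ (only the orientation
flag used by LD and scoring changes).  Strand-ambiguous A/T and C/G
SNPs are dropped when their frequency is uninformative (effect-allele
frequency in [0.35, 0.65]) and otherwise resolved by frequency
matching; both behaviors can be switched.  This is the conservative
community default in the absence of strand information.

## Risk scores and evaluation

A weight set is a list of (SNP, effect allele, log-OR weight); lead-SNP
sets carry marginal weights, C/J sets carry joint weights, and the
merged set keeps the joint weight where a SNP appears in both (the
joint estimate supersedes the marginal one for a selected SNP).
Scoring is $\sum_j w_j d_{ij}$ over effect-allele dosages with missing
genotypes mean-imputed at $2\hat p_j$ — keeping every individual's
score on the same scale.  Flipping a SNP's allele convention shifts all
scores by a constant and therefore never changes ranks or AUC.

Model comparison fits logistic regressions (IRLS, coefficient change
< 1e-8, ≤ 100 iterations, with a perfect-separation guard) for
baseline age+sex, baseline plus each GRS; AUC uses the Mann–Whitney
midrank formulation (exactly the tie-half pair count); paired AUC
differences use the DeLong placement-value covariance with a two-sided
normal reference, reporting p = 1 with a flag when two scores rank
samples identically; Nagelkerke's R² is computed against the
intercept-only null; AIC counts the intercept.

Liability-scale variance explained converts a per-SNP odds ratio and
risk-allele frequency to the latent probit scale: under HWE genotype
frequencies and multiplicative genotype odds $(1, OR, OR^2)$, the
baseline odds are solved numerically (bracket $10^{\pm12}$ on the log
scale) so the average penetrance equals the prevalence $K$ (default
0.10); penetrances map to liability-class means through
$\mu_g = T - \Phi^{-1}(1-\pi_g)$, $T = \Phi^{-1}(1-K)$; the explained
fraction is $V/(1+V)$ with $V$ the between-genotype variance.  Set
totals add per-SNP fractions under independence and cap at 1 with a
warning.  This construction is validated against an independent
Monte-Carlo route — simulate from the odds model, recover the liability
variance through a probit regression's latent-variable
interpretation — rather than against any published table.

## The synthetic-data generator

The generator produces exactly the statistical structure the method
consumes, with direct control over the quantity that matters — LD:

* **Genotypes.** Each haplotype thresholds a latent multivariate
  normal at $\Phi^{-1}(1-p_j)$; a genotype is the sum of two
  independent haplotypes.  Target correlations are specified on the
  latent scale; `genotype_r_from_latent()` computes the induced
  genotype-scale correlation by quadrature, and its inverse calibrates
  a latent value to a desired genotype correlation.  Allele-frequency
  asymmetry bounds the attainable correlation of two binary indicators
  (Fréchet bounds); targets beyond the bound clamp to the extreme with
  a warning.  The masked-pair preset hits this: at frequencies
  0.430/0.825 the minimum attainable genotype correlation is about
  −0.530, so the nominal target of −0.54 (itself derived from rounded
  published values) realizes as ≈ −0.53.  All downstream checks use
  the realized target.
* **Phenotypes.** Liability = standardized causal dosages times their
  effects, plus optional age (uniform 45–84, standardized) and
  mean-centered sex effects, plus Gaussian noise scaled so total
  variance is 1; cases exceed $\Phi^{-1}(1-K)$.  Causal dosages are
  standardized by their theoretical moments so stated betas are exact
  liability-scale effects per standardized dosage.
* **Summary statistics.** One single-SNP logistic regression per SNP
  (vectorized Newton iteration across SNPs, cross-checked against
  `glm` in the tests), recording log-OR, SE, Wald p, frequency and n —
  the exchange format the discovery side reads.
* **Truth.** For two-causal-SNP scenarios, `true_joint_logor()`
  computes the *population* joint and marginal logistic coefficients
  exactly: the 3×3 genotype distribution follows from the copula's
  orthant probabilities, penetrances from the liability model, and the
  population coefficients from a weighted likelihood fit over the nine
  cells.  This oracle matches a 2-million-sample individual-level fit
  to three decimals.

All randomness flows from the scenario seed; equal seeds give
bit-identical output.  Reference, GWAS and validation cohorts are
independent draws from the same law, so reference LD consistently
estimates GWAS-cohort LD.

What the generator does *not* emulate: recombination-map LD decay,
population stratification, imputation error, genotyping batch effects,
and cryptic relatedness.  Passing tests therefore demonstrate
correctness of the estimator and its calibration under clean LD
structure, not robustness to those real-data pathologies.

## Scales, and a known limitation of log-odds joint recovery

The masked-pair preset specifies liability-scale standardized effects
of 0.15 per SNP with risk-allele correlation $r \approx -0.53$.  Two
consequences, on different scales, deserve care:

* On the **liability scale** the attenuation identity is exact under
  joint normality of standardized genotypes: the expected standardized
  marginal effect is $\beta(1 + r) \approx 0.069$, less than half the
  joint effect.  The same ratio carries over, to good approximation,
  to the ratio of marginal to joint log-odds estimates — the tests
  verify both.
* On the **log-odds scale**, however, marginal effects of a
  liability-threshold trait do not combine linearly.  Solving the
  normal equations maps marginal log-ORs through linear LD algebra,
  which is exact for linear-model coefficients but only first-order
  for logistic ones.  At the preset's operating point the joint
  standardized log-ORs are ≈ 0.29 — large enough that the linear
  recovery overshoots the population joint log-OR by roughly 10%
  (about 1–1.5 standard errors at n = 50,000).  Stepwise selection,
  the attenuation ratio, and the direction and approximate magnitude
  of every effect are unaffected; but a 2-SE interval around the joint
  estimate covers the population joint log-OR well below its nominal
  rate in this regime.  The corresponding acceptance check is left
  failing by design rather than re-targeted, because it documents a
  real property of the method: summary-based joint estimation of
  binary traits is accurate for the modest effect sizes typical of
  GWAS loci (as in the bundled worked examples, where agreement is
  within 0.001) and degrades quadratically as standardized log-odds
  effects grow.

## Problem sizes used by the test suite

The suite favors the smallest sizes at which each property is
informative: the OLS-equivalence oracle runs at n = 2,000 × 20 SNPs;
masked-pair recovery at n = 50,000 with 200 replicates; DeLong null
calibration at 200 cases/1,800 controls with 2,000 replicates;
null-region discovery calibration with 500 replicates of 50-SNP regions
(n = 4,000 — the null calibration of a p-threshold rule does not depend
on sample size); the liability-variance Monte Carlo at n = 10⁶; and the
prediction comparison with 100 validation cohorts of n = 2,000.
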