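# cojoscore

Conditional/joint analysis of GWAS summary statistics with a
reference-panel LD matrix, and evaluation of the genetic risk scores it
produces.

## The problem

Genome-wide association meta-analyses report one *marginal* effect per
SNP: the log odds ratio from testing that SNP alone.  When a locus
harbors several risk variants (allelic heterogeneity), marginal effects
misrepresent the underlying signal — most strikingly when two risk
alleles are in negative linkage disequilibrium, so that each one's
marginal effect is attenuated and secondary signals can be invisible to
single-SNP analysis.  Re-fitting SNPs jointly requires individual-level
genotypes, which meta-analyses do not share.

`cojoscore` implements the summary-statistic workaround: approximate the
least-squares normal equations from published per-SNP statistics plus LD
correlations estimated in a reference panel of the same ancestry.  With
`p_j` the effect-allele frequency, `v_j = 2 p_j (1 - p_j)`, `n_j` the
per-SNP sample size, `b_j` the marginal effect and `r_jk` the
effect-allele LD correlation:

    (X'X)_jj = n_j v_j
    (X'X)_jk = r_jk sqrt(v_j v_k) min(n_j, n_k)
    (X'y)_j  = n_j v_j b_j

Joint effects solve `X'X b = X'y`; standard errors come from the
residual variance `(y'y - b'X'y) / (n - k)`, with `y'y` itself
reconstructed per SNP from `b_j`, `se_j` and `n_j` (median over the
region).  An iterative stepwise scheme alternates conditional testing of
candidate SNPs with joint re-estimation of the selected set, within
regions of ±1 Mb around established lead SNPs, across a ladder of
p-value thresholds (5×10⁻⁸ … 5×10⁻⁴).

Downstream, the package builds weighted genetic risk scores (lead-SNP
marginal weights vs. joint C/J weights), scores an independent
case-control cohort, and compares prediction models by AUC with the
paired DeLong test, Nagelkerke's R², AIC, and liability-scale variance
explained at a given disease prevalence.

A synthetic-data module generates every input with known ground truth:
LD-structured diploid genotypes through a Gaussian copula on haplotypes,
liability-threshold case/control phenotypes, and marginal logistic
summary statistics — including a preset that reproduces the
masked-association phenomenon (two risk alleles with genotype
correlation ≈ −0.54).

Audience: statistical geneticists who want a tested, scriptable
implementation of summary-based conditional/joint analysis and GRS
evaluation, or a simulation bench for methods work on allelic
heterogeneity.

## Worked example

A two-SNP locus fitted jointly from published marginal statistics alone
(*BCL11A*: rs2192512 with b = 0.058, se = 0.014, freq = 0.475,
n = 110,517; rs243019 with b = 0.086, se = 0.014, freq = 0.451,
n = 117,602; LD r = −0.017):

```r
library(cojoscore)
fit_twosnp_locus("BCL11A")
#> joint_model with 2 SNP(s)
#>      snp_id         bJ      bJ_se           pJ
#> 1 rs2192512 0.05947294 0.01420275 2.821368e-05
#> 2  rs243019 0.08695353 0.01381756 3.114473e-10
```

The joint estimates (0.059, 0.087) match the published conditional/joint
values (0.060, 0.087) to the third decimal: with negligible LD the two
signals are nearly independent and both survive joint fitting.

A full synthetic pipeline — simulate a masked pair, discover it, and
evaluate prediction:

```r
sc   <- preset_masked_pair(seed = 42, n_gwas = 20000, n_val = 2000, n_ref = 3000)
sim  <- simulate_study(sc)
reg  <- region_spec("snp025", "1", center_bp = 1960000, half_width_bp = 1e6)
disc <- run_discovery(sim$sumstats, sim$reference, list(reg))
disc$regions[[1]]$sweep[["5e-08"]]$model
#> joint_model with 2 SNP(s)
#>   snp_id        bJ      bJ_se           pJ
#> 1 snp025 0.4492495 0.04035012 8.591025e-29
#> 2 snp026 0.5667788 0.05262000 4.709883e-27
rep <- run_validation(disc, sim$sumstats, sim$validation$panel,
                      sim$validation$pheno)
rep$models[1:4, c("model", "auc", "nagelkerke_r2", "aic")]
#>          model       auc nagelkerke_r2      aic
#> 1      age+sex 0.5349302   0.002971148 1359.610
#> 2     lead GRS 0.5581626   0.009000092 1355.653
#> 3      C/J GRS 0.5672502   0.012698069 1351.991
#> 4 lead+C/J GRS 0.5672502   0.012698069 1351.991
```

Both masked SNPs are recovered with joint effects roughly double their
marginal estimates, and the two-SNP C/J score predicts better than the
single lead-SNP score (higher AUC, lower AIC).

A command-line wrapper is installed at `inst/cli/cojoscore`
(subcommands `simulate`, `discover`, `validate`).

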