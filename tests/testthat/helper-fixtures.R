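# Shared fixture builders; everything is generated in code.

# A small sumstat table with explicit positions on one chromosome.
make_stats <- function(n = 10, chrom = "1", seed = 1) {
  set.seed(seed)
  sumstat_table(data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    bp = sort(sample.int(2e6, n)),
    effect_allele = sample(c("A", "C", "G"), n, replace = TRUE),
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.1),
    se = runif(n, 0.01, 0.05),
    pval = runif(n),
    n = 1000 + rpois(n, 50),
    stringsAsFactors = FALSE))
}

# A tiny hand-built genotype panel.
make_panel <- function(dosage, alleleA = "A", alleleB = "G",
                       hard_called = all(dosage == round(dosage),
                                         na.rm = TRUE)) {
  m <- ncol(dosage)
  genotype_panel(
    sprintf("s%02d", seq_len(nrow(dosage))),
    data.frame(snp_id = sprintf("snp%02d", seq_len(m)), chrom = "1",
               bp = seq_len(m) * 1000, alleleA = rep_len(alleleA, m),
               alleleB = rep_len(alleleB, m), stringsAsFactors = FALSE),
    dosage, hard_called = hard_called)
}

# Per-SNP marginal linear-regression summary statistics from
# individual-level data: the independent oracle path for the
# quantitative-trait exactness checks.
marginal_linear_stats <- function(panel, y) {
  d <- panel$dosage
  n <- nrow(d)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  stats_j <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    sxy <- sum(xc * yc)
    b <- sxy / sxx
    rss <- syy - b * sxy
    se <- sqrt(rss / (n - 2) / sxx)
    tt <- b / se
    c(b, se, 2 * stats::pt(-abs(tt), df = n - 2), sxx / n)
  }, numeric(4))
  list(stats = sumstat_table(data.frame(
    snp_id = panel$variants$snp_id, chrom = panel$variants$chrom,
    bp = panel$variants$bp, effect_allele = panel$variants$alleleB,
    eaf = allele_freq(panel), beta = stats_j[1, ], se = stats_j[2, ],
    pval = pmax(stats_j[3, ], 1e-300), n = n, stringsAsFactors = FALSE)),
    var_x = stats_j[4, ], syy = syy)
}

# Quantitative-trait cohort with AR(1) block LD and a few causal SNPs.
make_quant_cohort <- function(n = 2000, m = 20, seed = 11) {
  R <- diag(m)
  start <- 1
  while (start + 1 <= m) {
    b <- start:min(start + 4, m)
    R[b, b] <- 0.6^abs(outer(seq_along(b), seq_along(b), "-"))
    start <- start + 7
  }
  sc <- sim_scenario(m_snps = m, maf = seq(0.15, 0.5, length.out = m),
                     latent_corr = R, causal = NULL, seed = seed,
                     n_gwas = n)
  set.seed(seed)
  panel <- simulate_panel(sc, n)
  beta <- rep(0, m)
  causal <- unique(pmin(c(2, max(1, m %/% 2), m - 1), m))
  beta[causal] <- c(0.3, -0.25, 0.2)[seq_along(causal)]
  y <- as.vector(panel$dosage %*% beta) + rnorm(n)
  list(panel = panel, y = y, beta = beta, scenario = sc)
}
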