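# The summary-statistic joint estimator: ypy reconstruction, joint and
# conditional fits, stepwise selection.

test_that("estimate_ypy follows the per-SNP reconstruction", {
  tab <- sumstat_table(data.frame(
    snp_id = "a", chrom = "1", bp = 1, effect_allele = "G", eaf = 0.5,
    beta = 0, se = 0.1, pval = 0.5, n = 1000))
  # v = 0.5, D = 500: ypy = 500*0 + 500*0.01*999 = 4995
  expect_equal(estimate_ypy(tab)$ypy, 4995)
  # two identical SNPs: median equals the common value
  tab2 <- sumstat_table(data.frame(
    snp_id = c("a", "b"), chrom = "1", bp = 1:2, effect_allele = "G",
    eaf = 0.5, beta = 0, se = 0.1, pval = 0.5, n = 1000))
  expect_equal(estimate_ypy(tab2)$ypy, 4995)
})

test_that("ypy median tracks the true phenotype sum of squares", {
  set.seed(42)
  n <- 2000
  m <- 50
  sc <- sim_scenario(m_snps = m, maf = runif(m, 0.1, 0.5), seed = 42,
                     n_gwas = n)
  panel <- simulate_panel(sc, n)
  y <- rnorm(n, sd = 2)
  ml <- marginal_linear_stats(panel, y)
  est <- estimate_ypy(ml$stats)
  expect_lt(abs(est$ypy / ml$syy - 1), 0.05)
})

test_that("single-SNP joint fit recovers the marginal statistics", {
  tab <- sumstat_table(data.frame(
    snp_id = "a", chrom = "1", bp = 1, effect_allele = "G", eaf = 0.3,
    beta = 0.08, se = 0.02, pval = 6.3e-5, n = 5000))
  ld <- structure(list(snp_ids = "a", r = matrix(1, 1, 1),
                       n_pairs = matrix(5000, 1, 1)), class = "ld_view")
  fit <- joint_fit(tab, ld, estimate_ypy(tab)$ypy)
  expect_equal(unname(fit$beta_joint), 0.08)
  expect_equal(unname(fit$se_joint), 0.02, tolerance = 0.02)
  expect_equal(unname(fit$p_joint), 6.3e-5, tolerance = 0.1)
})

test_that("orthogonal SNPs keep their marginal effects exactly", {
  tab <- make_stats(n = 5, seed = 15)
  k <- nrow(tab)
  ld <- structure(list(snp_ids = tab$snp_id,
                       r = diag(k), n_pairs = matrix(1000, k, k)),
                  class = "ld_view")
  fit <- joint_fit(tab, ld, estimate_ypy(tab)$ypy)
  expect_equal(unname(fit$beta_joint), tab$beta, tolerance = 1e-12)
})

test_that("two-SNP joint fit matches the standardized closed form", {
  # beta1_joint_std = (b1s - r b2s) / (1 - r^2) for equal sample sizes
  f <- c(0.35, 0.6)
  b <- c(0.09, -0.05)
  n <- c(20000, 20000)
  r <- -0.45
  tab <- sumstat_table(data.frame(
    snp_id = c("a", "b"), chrom = "1", bp = 1:2, effect_allele = "G",
    eaf = f, beta = b, se = c(0.012, 0.011), pval = c(1e-5, 1e-3), n = n))
  ld <- structure(list(snp_ids = c("a", "b"),
                       r = matrix(c(1, r, r, 1), 2),
                       n_pairs = matrix(20000, 2, 2)), class = "ld_view")
  fit <- joint_fit(tab, ld, estimate_ypy(tab)$ypy)
  s <- sqrt(2 * f * (1 - f))
  bs <- b * s
  expected_std <- c((bs[1] - r * bs[2]) / (1 - r^2),
                    (bs[2] - r * bs[1]) / (1 - r^2))
  expect_equal(unname(fit$beta_joint * s), expected_std, tolerance = 1e-10)
})

test_that("a masked pair has joint effects larger than marginal", {
  # both standardized betas positive, risk alleles negatively correlated
  f <- c(0.43, 0.825)
  s <- sqrt(2 * f * (1 - f))
  r <- -0.5
  b_std_joint <- c(0.10, 0.10)
  # implied marginal standardized effects: b + r * b_other
  b_std_marg <- b_std_joint + r * rev(b_std_joint)
  tab <- sumstat_table(data.frame(
    snp_id = c("a", "b"), chrom = "1", bp = 1:2, effect_allele = "G",
    eaf = f, beta = b_std_marg / s, se = c(0.02, 0.02),
    pval = c(1e-4, 1e-4), n = 50000))
  ld <- structure(list(snp_ids = c("a", "b"),
                       r = matrix(c(1, r, r, 1), 2),
                       n_pairs = matrix(50000, 2, 2)), class = "ld_view")
  fit <- joint_fit(tab, ld, estimate_ypy(tab)$ypy)
  expect_true(all(abs(fit$beta_joint) >= abs(tab$beta)))
  expect_equal(unname(fit$beta_joint * s), b_std_joint, tolerance = 1e-10)
})

test_that("joint_fit from same-sample summaries equals OLS (small case)", {
  qc <- make_quant_cohort(n = 500, m = 8, seed = 19)
  ml <- marginal_linear_stats(qc$panel, qc$y)
  ld <- ld_corr(qc$panel)
  fit <- joint_fit(ml$stats, ld, ml$syy, var_x = ml$var_x)
  ols <- lm(qc$y ~ qc$panel$dosage)
  expect_equal(unname(fit$beta_joint), unname(coef(ols)[-1]),
               tolerance = 1e-6)
  expect_equal(unname(fit$se_joint),
               unname(summary(ols)$coefficients[-1, 2]), tolerance = 0.05)
})

test_that("collinear X'X raises a hard error naming the pair", {
  tab <- make_stats(n = 2, seed = 8)
  tab$n <- c(1000, 1000)  # equal n makes r = 1 exactly singular
  ld <- structure(list(snp_ids = tab$snp_id,
                       r = matrix(c(1, 1, 1, 1), 2),
                       n_pairs = matrix(1000, 2, 2)), class = "ld_view")
  expect_error(joint_fit(tab, ld, estimate_ypy(tab)$ypy),
               "positive definite")
})

test_that("conditional stats reduce to marginal when LD is zero", {
  # statistics made mutually coherent: one phenotype scale behind all
  # SNPs, so the re-estimated residual variance matches the marginal one
  b <- c(0.10, 0.033, 0.010, 0.005)
  tab <- sumstat_table(data.frame(
    snp_id = paste0("s", 1:4), chrom = "1", bp = 1:4 * 1000,
    effect_allele = "G", eaf = 0.5, beta = b, se = 0.01,
    pval = 2 * pnorm(-abs(b) / 0.01), n = 10000))
  k <- nrow(tab)
  ld <- structure(list(snp_ids = tab$snp_id, r = diag(k),
                       n_pairs = matrix(1000, k, k)), class = "ld_view")
  ypy <- estimate_ypy(tab)$ypy
  model <- joint_fit(tab[1, ], ld, ypy)
  cs <- conditional_stats(tab, model, tab$snp_id[2], ld, ypy)
  expect_equal(cs$b_cond, tab$beta[2], tolerance = 1e-10)
  # p re-estimated under the joint residual variance: same within 2x
  expect_lt(abs(log(cs$p_cond / tab$pval[2])), log(2))
  expect_error(conditional_stats(tab, model, tab$snp_id[1], ld, ypy),
               "already in model")
})

test_that("conditioning on a masking partner amplifies the effect", {
  f <- c(0.4, 0.4)
  s <- sqrt(2 * f * (1 - f))
  r <- -0.5
  b_std_joint <- c(0.12, 0.12)
  b_std_marg <- b_std_joint + r * rev(b_std_joint)
  tab <- sumstat_table(data.frame(
    snp_id = c("a", "b"), chrom = "1", bp = 1:2, effect_allele = "G",
    eaf = f, beta = b_std_marg / s, se = 0.015, pval = c(1e-5, 1e-4),
    n = 50000))
  ld <- structure(list(snp_ids = c("a", "b"),
                       r = matrix(c(1, r, r, 1), 2),
                       n_pairs = matrix(50000, 2, 2)), class = "ld_view")
  ypy <- estimate_ypy(tab)$ypy
  model <- joint_fit(tab[1, ], ld, ypy)
  cs <- conditional_stats(tab, model, "b", ld, ypy)
  expect_gt(abs(cs$b_cond), abs(tab$beta[2]))
})

test_that("stepwise selection finds a lone signal and nothing else", {
  set.seed(33)
  sc <- sim_scenario(m_snps = 20, maf = runif(20, 0.2, 0.8),
                     causal = data.frame(index = 10, beta = 0.25),
                     seed = 33, n_gwas = 8000, n_ref = 2000)
  sim <- simulate_study(sc)
  harm <- suppressMessages(
    harmonize_to_reference(sim$sumstats, sim$reference$variants))
  ld <- ld_corr(sim$reference, harm$stats$snp_id,
                harm$stats$orientation)
  res <- stepwise_select(harm$stats, ld, 5e-8)
  expect_true(res$converged)
  expect_equal(res$model$snp_ids, "snp010")
  expect_equal(res$trace$action[1], "add")
})

test_that("stepwise returns an empty model when nothing passes", {
  tab <- make_stats(n = 10, seed = 44)
  tab$pval <- runif(10, 0.2, 1)
  k <- nrow(tab)
  ld <- structure(list(snp_ids = tab$snp_id, r = diag(k),
                       n_pairs = matrix(1000, k, k)), class = "ld_view")
  res <- stepwise_select(tab, ld, 5e-8)
  expect_null(res$model)
  expect_true(res$converged)
})

test_that("the collinearity guard keeps near-duplicates out", {
  tab <- make_stats(n = 3, seed = 55)
  tab$pval <- c(1e-20, 1e-19, 0.5)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.999  # SNP 2 is a near-copy of SNP 1
  ld <- structure(list(snp_ids = tab$snp_id, r = r,
                       n_pairs = matrix(1000, 3, 3)), class = "ld_view")
  res <- stepwise_select(tab, ld, 5e-4)
  expect_false(tab$snp_id[2] %in% res$model$snp_ids)
  expect_true("skip-collinear" %in% res$trace$action)
})

test_that("stepwise selection is deterministic given its inputs", {
  sc <- preset_masked_pair(seed = 61, n_gwas = 10000, n_ref = 2000)
  sim <- simulate_study(sc)
  harm <- suppressMessages(
    harmonize_to_reference(sim$sumstats, sim$reference$variants))
  ld <- ld_corr(sim$reference, harm$stats$snp_id, harm$stats$orientation)
  r1 <- stepwise_select(harm$stats, ld, 5e-4)
  r2 <- stepwise_select(harm$stats, ld, 5e-4)
  expect_identical(r1$model$beta_joint, r2$model$beta_joint)
  expect_identical(r1$trace, r2$trace)
})

test_that("thresholds_sweep runs one selection per threshold", {
  tab <- make_stats(n = 6, seed = 66)
  tab$pval[3] <- 1e-9
  k <- nrow(tab)
  ld <- structure(list(snp_ids = tab$snp_id, r = diag(k),
                       n_pairs = matrix(1000, k, k)), class = "ld_view")
  sweep_res <- thresholds_sweep(tab, ld)
  expect_length(sweep_res, 5)
  expect_named(sweep_res, c("5e-08", "5e-07", "5e-06", "5e-05", "5e-04"))
})
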