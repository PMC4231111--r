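# The synthetic-data generator: copula LD control, liability phenotypes,
# marginal GWAS, presets, and determinism.

test_that("copula-induced genotype correlation matches its prediction", {
  p1 <- 0.4; p2 <- 0.6; rho <- -0.7
  predicted <- genotype_r_from_latent(rho, p1, p2)
  R <- diag(2); R[1, 2] <- R[2, 1] <- rho
  sc <- sim_scenario(m_snps = 2, maf = c(p1, p2), latent_corr = R,
                     seed = 14)
  set.seed(14)
  panel <- simulate_panel(sc, 5000)
  realized <- cor(panel$dosage)[1, 2]
  expect_lt(abs(realized - predicted), 0.08)
  expect_lt(realized, 0)
  # inversion recovers the latent correlation
  expect_equal(latent_from_genotype_r(predicted, p1, p2), rho,
               tolerance = 1e-6)
  # unattainable targets clamp with a warning
  expect_warning(latent_from_genotype_r(-0.9, 0.43, 0.825), "clamping")
})

test_that("identity LD spec yields near-independent SNPs", {
  sc <- sim_scenario(m_snps = 20, maf = runif(20, 0.2, 0.8), seed = 15,
                     n_gwas = 5000)
  set.seed(15)
  panel <- simulate_panel(sc, 5000)
  r <- cor(panel$dosage)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 0.05), 0.95)
})

test_that("the same seed reproduces the study bit for bit", {
  sc <- preset_masked_pair(seed = 16, n_gwas = 1500, n_ref = 400,
                           n_val = 300)
  s1 <- simulate_study(sc)
  s2 <- simulate_study(sc)
  expect_identical(s1$reference$dosage, s2$reference$dosage)
  expect_identical(s1$gwas$pheno$status, s2$gwas$pheno$status)
  expect_identical(s1$sumstats, s2$sumstats)
  # a different seed gives a different draw
  s3 <- simulate_study(preset_masked_pair(seed = 17, n_gwas = 1500,
                                          n_ref = 400, n_val = 300))
  expect_false(identical(s1$reference$dosage, s3$reference$dosage))
})

test_that("case fraction honors the prevalence", {
  sc <- sim_scenario(m_snps = 5, maf = 0.3, seed = 18, K = 0.10,
                     n_gwas = 10000)
  set.seed(18)
  panel <- simulate_panel(sc, 10000)
  ph <- simulate_phenotype(panel, sc)
  expect_gt(mean(ph$status), 0.08)
  expect_lt(mean(ph$status), 0.12)
  expect_true(all(ph$age >= 45 & ph$age <= 84))
  expect_true(all(ph$sex %in% 0:1))
})

test_that("explained-variance overflow is rejected", {
  sc <- sim_scenario(m_snps = 2, maf = 0.5,
                     causal = data.frame(index = 1:2, beta = c(0.9, 0.9)),
                     seed = 19, n_gwas = 200)
  set.seed(19)
  panel <- simulate_panel(sc, 200)
  expect_error(simulate_phenotype(panel, sc), ">= 1")
})

test_that("null marginal p-values are uniform", {
  sc <- sim_scenario(m_snps = 200, maf = runif(200, 0.1, 0.9), seed = 20,
                     n_gwas = 3000)
  set.seed(20)
  panel <- simulate_panel(sc, 3000)
  ph <- simulate_phenotype(panel, sc)
  ss <- marginal_gwas(panel, ph)
  ks <- suppressWarnings(ks.test(ss$pval, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("marginal_gwas agrees with glm and round-trips through .ma", {
  sc <- sim_scenario(m_snps = 6, maf = seq(0.2, 0.7, length.out = 6),
                     causal = data.frame(index = 2, beta = 0.3),
                     seed = 21, n_gwas = 2500)
  set.seed(21)
  panel <- simulate_panel(sc, 2500)
  ph <- simulate_phenotype(panel, sc)
  ss <- marginal_gwas(panel, ph)
  ref <- glm(ph$status ~ panel$dosage[, 4], family = binomial)
  expect_equal(ss$beta[4], unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(ss$se[4], sqrt(vcov(ref)[2, 2]), tolerance = 1e-4)
  path <- withr::local_tempfile(fileext = ".ma")
  write_ma(ss, path)
  back <- read_ma(path)
  expect_equal(back$beta, ss$beta, tolerance = 1e-10)
  expect_equal(back$snp_id, ss$snp_id)
})

test_that("monomorphic SNPs are excluded from the marginal scan", {
  sc <- sim_scenario(m_snps = 3, maf = c(0.4, 0.001, 0.4), seed = 22,
                     n_gwas = 300)
  set.seed(22)
  panel <- simulate_panel(sc, 300)
  panel$dosage[, 2] <- 0
  ph <- simulate_phenotype(panel, sc)
  expect_message(ss <- marginal_gwas(panel, ph), "monomorphic")
  expect_equal(nrow(ss), 2)
})

test_that("masked-pair preset encodes the attenuation arithmetic", {
  sc <- preset_masked_pair(seed = 23)
  expect_equal(sc$K, 0.10)
  expect_equal(sc$maf[sc$causal$index], c(0.430, 0.825))
  expect_equal(sc$causal$beta, c(0.15, 0.15))
  r_target <- genotype_r_from_latent(
    sc$latent_corr[25, 26], sc$maf[25], sc$maf[26])
  expect_lt(r_target, -0.5)
  # expected standardized marginal effect: beta (1 + r), attenuated
  marg <- 0.15 * (1 + r_target)
  expect_lt(marg, 0.15 / 2)
  expect_lt(abs(marg - 0.069), 0.005)
  ev <- eigen(sc$latent_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("chain preset places the published consecutive correlations", {
  sc <- preset_chain(seed = 24)
  idx <- sc$causal$index
  r12 <- genotype_r_from_latent(sc$latent_corr[idx[1], idx[2]],
                                sc$maf[idx[1]], sc$maf[idx[2]])
  r23 <- genotype_r_from_latent(sc$latent_corr[idx[2], idx[3]],
                                sc$maf[idx[2]], sc$maf[idx[3]])
  expect_equal(r12, 0.344, tolerance = 1e-6)
  expect_equal(r23, -0.126, tolerance = 1e-6)
  ev <- eigen(sc$latent_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("population truth: marginals attenuate, joint effects do not", {
  sc <- preset_masked_pair(seed = 25)
  truth <- true_joint_logor(sc)
  expect_length(truth$joint, 2)
  expect_true(all(truth$joint > 0))
  expect_true(all(truth$marginal < truth$joint))
  # marginal/joint ratio on the standardized scale tracks 1 + r
  r_target <- genotype_r_from_latent(
    sc$latent_corr[25, 26], sc$maf[25], sc$maf[26])
  expect_lt(abs(truth$marginal[1] / truth$joint[1] - (1 + r_target)),
            0.12)
})

test_that("reference LD estimates GWAS-cohort LD consistently", {
  sc <- preset_masked_pair(seed = 26, n_gwas = 4000)
  gaps <- vapply(c(500, 4000), function(n_ref) {
    set.seed(26)
    ref <- simulate_panel(sc, n_ref, prefix = "r")
    gwas <- simulate_panel(sc, 4000, prefix = "g")
    abs(cor(ref$dosage[, 25], ref$dosage[, 26]) -
          cor(gwas$dosage[, 25], gwas$dosage[, 26]))
  }, numeric(1))
  expect_lt(gaps[2], 0.06)
})

test_that("sim bundles are written in pipeline-ready text formats", {
  sc <- preset_masked_pair(seed = 27, n_gwas = 800, n_ref = 200,
                           n_val = 150)
  sim <- simulate_study(sc)
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_ma(paths["sumstats"])
  expect_equal(nrow(back), nrow(sim$sumstats))
  ref <- read_traw(paths["reference"])
  expect_equal(ref$dosage, sim$reference$dosage, tolerance = 1e-6)
  regions <- read_regions(paths["regions"])
  expect_length(regions, 1)
})
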