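# Synthetic-data generation with known ground truth: LD-structured
# diploid genotype panels via a Gaussian copula on haplotypes,
# liability-threshold case/control phenotypes with demographic
# covariates, and per-SNP marginal logistic summary statistics.

#' Genotype-scale correlation induced by a latent (copula) correlation
#'
#' Haplotype allele indicators arise by thresholding a standard bivariate
#' normal at `qnorm(1 - p_j)`; this computes the resulting correlation
#' between the indicators (which equals the correlation between diploid
#' genotypes, since a genotype is the sum of two independent haplotypes).
#' The orthant probability is evaluated by one-dimensional quadrature.
#'
#' @param rho latent correlation in (-1, 1).
#' @param p1,p2 allele frequencies.
#' @return genotype-scale Pearson correlation.
#' @export
genotype_r_from_latent <- function(rho, p1, p2) {
  if (rho == 0) return(0)
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  s <- sqrt(1 - rho^2)
  p11 <- stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((rho * z - t2) / s)
  }, lower = t1, upper = Inf, rel.tol = 1e-10)$value
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

#' Latent correlation required for a target genotype-scale correlation
#'
#' Inverts [genotype_r_from_latent()] numerically.  Allele-frequency
#' asymmetry bounds the attainable indicator correlation (the Frechet
#' bounds on the haplotype table); a target beyond the attainable range
#' is clamped to the nearest extreme with a warning.
#'
#' @param target desired genotype correlation.
#' @param p1,p2 allele frequencies.
#' @return latent correlation.
#' @export
latent_from_genotype_r <- function(target, p1, p2) {
  if (target == 0) return(0)
  f <- function(rho) genotype_r_from_latent(rho, p1, p2) - target
  lo <- -0.9999
  hi <- 0.9999
  if (f(lo) > 0) {
    warning("target r = ", target, " below the attainable minimum ",
            signif(f(lo) + target, 3), " for these frequencies; clamping")
    return(lo)
  }
  if (f(hi) < 0) {
    warning("target r = ", target, " above the attainable maximum ",
            signif(f(hi) + target, 3), " for these frequencies; clamping")
    return(hi)
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9)$root
}

#' Define a simulation scenario
#'
#' A scenario fixes everything the generator needs: SNP count and allele
#' frequencies, the latent LD structure, causal effects on the liability
#' scale, disease prevalence, demographic effects, cohort sizes, and the
#' seed (all randomness flows from it).
#'
#' @param m_snps number of SNPs.
#' @param maf per-SNP effect(B)-allele frequencies (recycled).
#' @param latent_corr latent correlation matrix (`m_snps` square,
#'   positive definite) or `NULL` for independence.
#' @param causal data frame with columns `index` (SNP column) and `beta`
#'   (standardized liability effect); `NULL` for a null scenario.
#' @param K disease prevalence (default 0.10).
#' @param n_ref,n_gwas,n_val cohort sizes for the LD reference, the
#'   association cohort, and the validation cohort.
#' @param age_effect,sex_effect liability effects of standardized age and
#'   of male sex.
#' @param seed integer seed (mandatory).
#' @param chrom,bp_start,bp_step genomic coordinates assigned to the
#'   simulated SNPs.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(m_snps, maf = 0.3, latent_corr = NULL,
                         causal = NULL, K = 0.10,
                         n_ref = 6000, n_gwas = 20000, n_val = 2200,
                         age_effect = 0, sex_effect = 0, seed,
                         chrom = "1", bp_start = 1000000L,
                         bp_step = 40000L) {
  if (missing(seed)) stop("a seed is mandatory")
  maf <- rep_len(maf, m_snps)
  stopifnot(all(maf > 0 & maf < 1), K > 0, K < 1)
  if (!is.null(latent_corr)) {
    stopifnot(nrow(latent_corr) == m_snps, ncol(latent_corr) == m_snps)
    ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) stop("latent correlation matrix not positive definite")
  }
  if (!is.null(causal)) {
    stopifnot(all(causal$index >= 1 & causal$index <= m_snps))
  }
  structure(list(m_snps = m_snps, maf = maf, latent_corr = latent_corr,
                 causal = causal, K = K, n_ref = n_ref, n_gwas = n_gwas,
                 n_val = n_val, age_effect = age_effect,
                 sex_effect = sex_effect, seed = as.integer(seed),
                 chrom = chrom, bp_start = bp_start, bp_step = bp_step),
            class = "sim_scenario")
}

scenario_variants <- function(scenario) {
  m <- scenario$m_snps
  data.frame(snp_id = sprintf("snp%03d", seq_len(m)),
             chrom = scenario$chrom,
             bp = scenario$bp_start + (seq_len(m) - 1) * scenario$bp_step,
             alleleA = "A", alleleB = "G", stringsAsFactors = FALSE)
}

#' Simulate an LD-structured diploid genotype panel
#'
#' Each haplotype is drawn from a Gaussian copula: a latent multivariate
#' normal with the scenario's correlation, thresholded at
#' `qnorm(1 - p_j)` to allele indicators; the genotype is the sum of two
#' independent haplotypes.  Dosages count `alleleB` (the `G` allele, the
#' allele the `maf` refers to).
#'
#' @param scenario a [sim_scenario()].
#' @param n number of samples.
#' @param prefix sample-id prefix.
#' @return a hard-called [genotype_panel()].
#' @export
simulate_panel <- function(scenario, n, prefix = "s") {
  m <- scenario$m_snps
  thr <- stats::qnorm(1 - scenario$maf)
  # only columns with off-diagonal structure need the chol transform
  dep <- integer(0)
  ch <- NULL
  if (!is.null(scenario$latent_corr)) {
    R <- scenario$latent_corr
    dep <- which(colSums(abs(R - diag(m)) > 1e-12) > 0)
    if (length(dep) > 0) ch <- chol(R[dep, dep, drop = FALSE])
  }
  draw_hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (length(dep) > 0) {
      z[, dep] <- z[, dep, drop = FALSE] %*% ch
    }
    t(t(z) > thr) + 0
  }
  dosage <- draw_hap() + draw_hap()
  genotype_panel(sprintf("%s%05d", prefix, seq_len(n)),
                 scenario_variants(scenario), dosage, hard_called = TRUE)
}

#' Simulate a liability-threshold phenotype with covariates
#'
#' Liability = sum of standardized causal-genotype effects + age and sex
#' effects + Gaussian noise scaled so the total liability variance is 1;
#' status is 1 when liability exceeds `qnorm(1 - K)`.  Genotypes are
#' standardized with the scenario's theoretical moments
#' (`mean 2p`, `sd sqrt(2p(1-p))`), so the stated causal betas are exact
#' per-standardized-dosage liability effects.  Age is uniform on 45-84
#' years, sex is Bernoulli(1/2).
#'
#' @param panel a [genotype_panel()] from [simulate_panel()].
#' @param scenario the generating [sim_scenario()].
#' @return data frame `(sample_id, status, age, sex)` of class
#'   `phenotype_frame`, with the per-sample genetic liability attached as
#'   attribute `genetic_liability`.
#' @export
simulate_phenotype <- function(panel, scenario) {
  n <- length(panel$sample_ids)
  age <- stats::runif(n, 45, 84)
  sex <- stats::rbinom(n, 1, 0.5)
  age_std <- (age - 64.5) / sqrt((84 - 45)^2 / 12)
  g_lia <- numeric(n)
  var_g <- 0
  if (!is.null(scenario$causal) && nrow(scenario$causal) > 0) {
    idx <- scenario$causal$index
    p <- scenario$maf[idx]
    z <- sweep(panel$dosage[, idx, drop = FALSE], 2, 2 * p, "-")
    z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
    g_lia <- as.vector(z %*% scenario$causal$beta)
    var_g <- stats::var(g_lia)
  }
  explained <- var_g + scenario$age_effect^2 + 0.25 * scenario$sex_effect^2
  if (explained >= 1) stop("explained liability variance >= 1")
  # sex is mean-centered so the population prevalence stays at K
  lia <- g_lia + scenario$age_effect * age_std +
    scenario$sex_effect * (sex - 0.5) +
    stats::rnorm(n, sd = sqrt(1 - explained))
  status <- as.integer(lia > stats::qnorm(1 - scenario$K))
  out <- data.frame(sample_id = panel$sample_ids, status = status,
                    age = age, sex = sex, stringsAsFactors = FALSE)
  attr(out, "genetic_liability") <- g_lia
  class(out) <- c("phenotype_frame", "data.frame")
  out
}

# Single-SNP logistic regressions for all SNPs at once: per-SNP
# two-parameter (intercept + dosage) Newton-Raphson, vectorized across
# the dosage matrix, with a glm.fit fallback for any column that fails
# to converge.  Returns a 3 x m matrix (beta, se, p for the dosage
# term).
logistic_marginal_all <- function(D, y, tol = 1e-8, maxit = 30) {
  m <- ncol(D)
  n <- nrow(D)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- rep(0, m)
  D2 <- D * D
  converged <- rep(FALSE, m)
  for (it in seq_len(maxit)) {
    eta <- sweep(D * rep(b, each = n), 2, a, "+")
    mu <- stats::plogis(eta)
    res <- y - mu
    w <- mu * (1 - mu)
    g1 <- colSums(res)
    g2 <- colSums(res * D)
    h11 <- colSums(w)
    h12 <- colSums(w * D)
    h22 <- colSums(w * D2)
    det <- h11 * h22 - h12^2
    da <- (h22 * g1 - h12 * g2) / det
    db <- (h11 * g2 - h12 * g1) / det
    a <- a + da
    b <- b + db
    converged <- abs(da) < tol & abs(db) < tol
    if (all(converged)) break
  }
  se <- sqrt(h11 / det)
  for (j in which(!converged)) {
    fit <- stats::glm.fit(cbind(1, D[, j]), y, family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-10,
                                                       maxit = 100))
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    v <- chol2inv(chol(crossprod(cbind(1, D[, j]) * sqrt(w))))
    b[j] <- fit$coefficients[2]
    se[j] <- sqrt(v[2, 2])
  }
  p <- pmax(2 * stats::pnorm(-abs(b / se)), .Machine$double.xmin)
  rbind(beta = b, se = se, p = p)
}

#' Marginal single-SNP logistic GWAS
#'
#' One logistic regression of status on dosage per SNP (no covariates by
#' default — the summary-statistic convention of meta-analysis inputs),
#' recording the log odds ratio, its SE, the Wald p-value, the
#' effect-allele frequency in the cohort, and the sample size.
#' Monomorphic SNPs are excluded with a message.
#'
#' @param panel a [genotype_panel()].
#' @param pheno matching phenotype frame.
#' @return a [sumstat_table()] (effect allele = the panel's `alleleB`).
#' @export
marginal_gwas <- function(panel, pheno) {
  stopifnot(identical(panel$sample_ids, pheno$sample_id))
  y <- pheno$status
  if (length(unique(y)) < 2) stop("both outcome classes required")
  f <- allele_freq(panel)
  poly <- !is.na(f) & f > 0 & f < 1
  if (any(!poly)) {
    message("marginal_gwas: excluded ", sum(!poly), " monomorphic SNP(s)")
  }
  idx <- which(poly)
  res <- logistic_marginal_all(panel$dosage[, idx, drop = FALSE], y)
  v <- panel$variants[idx, , drop = FALSE]
  sumstat_table(data.frame(
    snp_id = v$snp_id, chrom = v$chrom, bp = v$bp,
    effect_allele = v$alleleB, other_allele = v$alleleA,
    eaf = f[idx], beta = res["beta", ], se = res["se", ],
    pval = res["p", ], n = length(y), stringsAsFactors = FALSE))
}

#' Simulate a complete study
#'
#' Draws three independent cohorts from the scenario's generative law —
#' an LD reference panel, an association (GWAS) cohort with phenotypes
#' and marginal summary statistics, and a validation cohort — plus the
#' ground truth.
#'
#' @param scenario a [sim_scenario()].
#' @return list of class `sim_output` with elements `reference`, `gwas`
#'   (`panel`, `pheno`), `validation` (`panel`, `pheno`), `sumstats`,
#'   and `truth` (causal spec, realized reference LD, scenario).
#' @export
simulate_study <- function(scenario) {
  set.seed(scenario$seed)
  reference <- simulate_panel(scenario, scenario$n_ref, prefix = "ref")
  gwas_panel <- simulate_panel(scenario, scenario$n_gwas, prefix = "gws")
  gwas_pheno <- simulate_phenotype(gwas_panel, scenario)
  val_panel <- simulate_panel(scenario, scenario$n_val, prefix = "val")
  val_pheno <- simulate_phenotype(val_panel, scenario)
  sumstats <- marginal_gwas(gwas_panel, gwas_pheno)
  structure(list(
    reference = reference,
    gwas = list(panel = gwas_panel, pheno = gwas_pheno),
    validation = list(panel = val_panel, pheno = val_pheno),
    sumstats = sumstats,
    truth = list(causal = scenario$causal,
                 ld_reference = ld_corr(reference)$r,
                 scenario = scenario)),
    class = "sim_output")
}

# Build an m x m latent correlation matrix that places `latent_block`
# (a small correlation matrix) on the SNPs in `at` and leaves all other
# SNPs independent.
embed_block <- function(m, latent_block, at) {
  R <- diag(m)
  R[at, at] <- latent_block
  R
}

#' Masked-pair scenario preset
#'
#' Two causal risk alleles in negative LD: standardized liability effects
#' of +0.15 each, frequencies 0.43 and 0.825, and a genotype-scale
#' correlation of -0.54 between the risk-allele dosages (clamped to the
#' attainable extreme, about -0.53, since the Frechet bound for these
#' frequencies falls just short of the nominal target), embedded among
#' 50 null SNPs.  Because the risk alleles are negatively correlated,
#' each SNP's expected standardized marginal effect is attenuated to
#' `beta (1 + r) = 0.069`, so single-SNP analysis understates both
#' effects while the joint fit recovers them.
#'
#' @param seed scenario seed.
#' @param n_gwas,n_val,n_ref cohort sizes (defaults: 50,000 association
#'   samples, a 2,210-sample validation cohort, a 6,000-sample
#'   reference).
#' @return a [sim_scenario()].
#' @export
preset_masked_pair <- function(seed, n_gwas = 50000, n_val = 2210,
                               n_ref = 6000) {
  m <- 52
  causal_idx <- c(25, 26)
  maf <- rep(0.3, m)
  maf[causal_idx] <- c(0.430, 0.825)
  set.seed(seed)
  maf[-causal_idx] <- stats::runif(m - 2, 0.1, 0.9)
  rho <- suppressWarnings(latent_from_genotype_r(-0.54, 0.430, 0.825))
  R <- embed_block(m, matrix(c(1, rho, rho, 1), 2), causal_idx)
  sim_scenario(m_snps = m, maf = maf, latent_corr = R,
               causal = data.frame(index = causal_idx,
                                   beta = c(0.15, 0.15)),
               K = 0.10, n_ref = n_ref, n_gwas = n_gwas, n_val = n_val,
               seed = seed)
}

#' Three-SNP chain scenario preset
#'
#' Three causal SNPs with consecutive genotype-scale correlations 0.344
#' and -0.126 (a moderate-positive / weak-negative chain with one
#' dominant effect in the middle), embedded among null SNPs, to exercise
#' stepwise selection with a three-SNP truth.
#'
#' @param seed scenario seed.
#' @param n_gwas,n_val,n_ref cohort sizes.
#' @return a [sim_scenario()].
#' @export
preset_chain <- function(seed, n_gwas = 50000, n_val = 2210,
                         n_ref = 6000) {
  m <- 50
  causal_idx <- c(24, 25, 26)
  maf <- rep(0.3, m)
  freqs <- c(0.479, 0.237, 0.063)
  maf[causal_idx] <- freqs
  set.seed(seed)
  maf[-causal_idx] <- stats::runif(m - 3, 0.1, 0.9)
  r12 <- latent_from_genotype_r(0.344, freqs[1], freqs[2])
  r23 <- latent_from_genotype_r(-0.126, freqs[2], freqs[3])
  block <- diag(3)
  block[1, 2] <- block[2, 1] <- r12
  block[2, 3] <- block[3, 2] <- r23
  block[1, 3] <- block[3, 1] <- r12 * r23  # Markov fill keeps it PD
  R <- embed_block(m, block, causal_idx)
  sim_scenario(m_snps = m, maf = maf, latent_corr = R,
               causal = data.frame(index = causal_idx,
                                   beta = c(0.05, 0.20, 0.08)),
               K = 0.10, n_ref = n_ref, n_gwas = n_gwas, n_val = n_val,
               seed = seed)
}

#' Population joint log odds ratios for a two-causal-SNP scenario
#'
#' Exact (quadrature-level) population values of the joint and marginal
#' logistic regression coefficients implied by the generative model, for
#' scenarios with exactly two causal SNPs.  The 3 x 3 joint genotype
#' distribution is derived from the copula's haplotype orthant
#' probabilities; per-cell penetrances follow from the liability model;
#' the population logistic coefficients are the weighted-likelihood fit
#' over the nine cells.  Serves as the ground truth for coverage checks.
#'
#' @param scenario a [sim_scenario()] with two causal SNPs.
#' @return list with `joint` (per-dosage log-OR vector, length 2) and
#'   `marginal` (single-SNP population log-ORs).
#' @export
true_joint_logor <- function(scenario) {
  stopifnot(!is.null(scenario$causal), nrow(scenario$causal) == 2)
  idx <- scenario$causal$index
  p <- scenario$maf[idx]
  beta <- scenario$causal$beta
  rho <- if (is.null(scenario$latent_corr)) 0 else
    scenario$latent_corr[idx[1], idx[2]]
  # haplotype joint probabilities
  t1 <- stats::qnorm(1 - p[1])
  t2 <- stats::qnorm(1 - p[2])
  p11 <- if (rho == 0) p[1] * p[2] else
    stats::integrate(function(z) {
      stats::dnorm(z) * stats::pnorm((rho * z - t2) / sqrt(1 - rho^2))
    }, lower = t1, upper = Inf, rel.tol = 1e-10)$value
  hap <- matrix(0, 2, 2)  # [a1 + 1, a2 + 1]
  hap[2, 2] <- p11
  hap[2, 1] <- p[1] - p11
  hap[1, 2] <- p[2] - p11
  hap[1, 1] <- 1 - p[1] - p[2] + p11
  # genotype joint = convolution of two independent haplotype draws
  gj <- matrix(0, 3, 3)
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
    gj[a1 + b1 + 1, a2 + b2 + 1] <- gj[a1 + b1 + 1, a2 + b2 + 1] +
      hap[a1 + 1, a2 + 1] * hap[b1 + 1, b2 + 1]
  }
  z1 <- (0:2 - 2 * p[1]) / sqrt(2 * p[1] * (1 - p[1]))
  z2 <- (0:2 - 2 * p[2]) / sqrt(2 * p[2] * (1 - p[2]))
  r_geno <- genotype_r_from_latent(rho, p[1], p[2])
  var_g <- sum(beta^2) + 2 * beta[1] * beta[2] * r_geno
  sd_e <- sqrt(1 - var_g)
  T_thr <- stats::qnorm(1 - scenario$K)
  cells <- expand.grid(g1 = 0:2, g2 = 0:2)
  w <- gj[cbind(cells$g1 + 1, cells$g2 + 1)]
  mu <- beta[1] * z1[cells$g1 + 1] + beta[2] * z2[cells$g2 + 1]
  pen <- stats::pnorm((mu - T_thr) / sd_e)
  x <- cbind(1, cells$g1, cells$g2)
  fit <- suppressWarnings(
    stats::glm.fit(x, pen, weights = w, family = stats::binomial()))
  marg <- vapply(1:2, function(k) {
    xk <- cbind(1, cells[[k]])
    suppressWarnings(
      stats::glm.fit(xk, pen, weights = w,
                     family = stats::binomial()))$coefficients[2]
  }, numeric(1))
  list(joint = unname(fit$coefficients[2:3]), marginal = unname(marg))
}

#' Write a simulated study to disk in pipeline-ready formats
#'
#' Emits the same text formats the pipeline reads: `.ma` summary
#' statistics, transposed-dosage genotype text (traw layout) for each
#' cohort, phenotype/covariate TSVs, and a single-region definition TSV.
#'
#' @param sim a `sim_output` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sumstats = file.path(dir, "sumstats.ma"),
    reference = file.path(dir, "reference.traw"),
    validation = file.path(dir, "validation.traw"),
    pheno = file.path(dir, "validation_pheno.tsv"),
    regions = file.path(dir, "regions.tsv"))
  write_ma(sim$sumstats, paths["sumstats"])
  write_traw(sim$reference, paths["reference"])
  write_traw(sim$validation$panel, paths["validation"])
  utils::write.table(sim$validation$pheno, paths["pheno"], quote = FALSE,
                     sep = "\t", row.names = FALSE)
  lead <- define_lead_snp(sim$sumstats)
  li <- match(lead, sim$sumstats$snp_id)
  regions <- data.frame(lead_snp_id = lead,
                        chrom = sim$sumstats$chrom[li],
                        center_bp = sim$sumstats$bp[li],
                        half_width_bp = 1000000L)
  utils::write.table(regions, paths["regions"], quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(paths)
}
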