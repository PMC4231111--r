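# Prediction-performance evaluation: logistic models with covariates,
# AUC and the paired DeLong test, Nagelkerke's pseudo-R2, AIC, and
# liability-scale variance explained.

#' Fit a logistic prediction model
#'
#' Maximum-likelihood logistic regression of case status on the supplied
#' covariates (iteratively reweighted least squares, coefficient-change
#' convergence below 1e-8, at most 100 iterations).  Errors on perfect
#' separation (a standardized coefficient diverging beyond 15), advising
#' penalization.
#'
#' @param status 0/1 outcome vector (1 = case); both classes required.
#' @param covariates data frame of predictors (e.g. age, sex, grs); an
#'   intercept is always included.  Pass `NULL` for an intercept-only
#'   (baseline prevalence) model.
#' @return list with `coefficients`, `loglik`, `fitted`, `n`, `k`
#'   (parameter count including the intercept), `converged`.
#' @export
fit_logistic <- function(status, covariates = NULL) {
  status <- as.numeric(status)
  stopifnot(all(status %in% c(0, 1)))
  if (length(unique(status)) < 2) stop("both outcome classes required")
  if (is.null(covariates)) {
    x <- matrix(1, nrow = length(status), ncol = 1,
                dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    const <- vapply(covariates, function(v) stats::var(as.numeric(v)) == 0,
                    logical(1))
    if (any(const)) {
      stop("constant covariate(s): ",
           paste(names(covariates)[const], collapse = ", "))
    }
    x <- cbind("(Intercept)" = 1, as.matrix(covariates))
  }
  fit <- stats::glm.fit(x, status, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  if (any(abs(fit$coefficients * sds) > 15, na.rm = TRUE)) {
    stop("apparent perfect separation (diverging coefficient); ",
         "consider a penalized fit")
  }
  mu <- fit$fitted.values
  ll <- sum(status * log(mu) + (1 - status) * log(1 - mu))
  list(coefficients = fit$coefficients, loglik = ll, fitted = mu,
       n = length(status), k = ncol(x), converged = fit$converged)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (case, control) pairs in
#' which the case scores higher, counting ties as one half.  Computed via
#' midranks, so it matches exhaustive pair enumeration exactly.
#'
#' @param scores numeric predictor.
#' @param status 0/1 outcome (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, status) {
  status <- as.numeric(status)
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each case, the fraction of controls it
# beats (ties half); for each control, the fraction of cases it is beaten
# by.  Computed with ranks in O(n log n).
delong_placements <- function(scores, status) {
  cases <- scores[status == 1]
  controls <- scores[status == 0]
  m <- length(cases)
  n <- length(controls)
  all_r <- rank(c(cases, controls), ties.method = "average")
  case_r <- rank(cases, ties.method = "average")
  control_r <- rank(controls, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - case_r) / n                 # per-case
  v01 <- 1 - (all_r[m + seq_len(n)] - control_r) / m      # per-control
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two scores measured on the same
#' samples, using the DeLong structural-component (placement-value)
#' covariance estimator and a two-sided normal reference.  Identical
#' score rankings give a zero-variance difference, reported as `p = 1`
#' with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b numeric predictors on the same samples.
#' @param status 0/1 outcome (1 = case).
#' @return list with `auc_a`, `auc_b`, `delta_auc`, `var_delta`, `z`,
#'   `p`, `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, status) {
  status <- as.numeric(status)
  stopifnot(length(scores_a) == length(status),
            length(scores_b) == length(status))
  pa <- delong_placements(scores_a, status)
  pb <- delong_placements(scores_b, status)
  m <- sum(status == 1)
  n <- sum(status == 0)
  if (m < 2 || n < 2) stop("need >= 2 cases and >= 2 controls")
  s10 <- stats::cov(cbind(pa$v10, pb$v10))  # case components, 2x2
  s01 <- stats::cov(cbind(pa$v01, pb$v01))  # control components, 2x2
  S <- s10 / m + s01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc
  if (var_delta <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                var_delta = 0, z = 0, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(var_delta)
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
       var_delta = var_delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Nagelkerke's pseudo-R-squared
#'
#' Cox-Snell R2 rescaled by its maximum attainable value:
#' `(1 - exp(2 (ll0 - ll1) / n)) / (1 - exp(2 ll0 / n))`.
#'
#' @param model_ll log-likelihood of the fitted model.
#' @param null_ll log-likelihood of the nested null model (must not
#'   exceed `model_ll`).
#' @param n sample size.
#' @return R2 in `[0, 1]`.
#' @export
nagelkerke <- function(model_ll, null_ll, n) {
  if (null_ll > model_ll + 1e-12) {
    stop("null log-likelihood exceeds model log-likelihood; ",
         "models are not nested on the same data")
  }
  (1 - exp(2 * (null_ll - model_ll) / n)) / (1 - exp(2 * null_ll / n))
}

#' Akaike information criterion
#'
#' @param model_ll model log-likelihood.
#' @param k_params number of estimated parameters (intercept included).
#' @return `2 k - 2 ll`.
#' @export
aic_of <- function(model_ll, k_params) {
  2 * k_params - 2 * model_ll
}

#' Liability-scale variance explained by one SNP
#'
#' Under Hardy-Weinberg genotype frequencies and multiplicative genotype
#' odds `(1, OR, OR^2)`, the baseline odds `o0` is solved numerically so
#' the population risk matches the prevalence `K`; genotype penetrances
#' are mapped to liability-scale means through the probit
#' (`mu_g = T - qnorm(1 - pi_g)`, `T = qnorm(1 - K)`), and the explained
#' fraction is `V / (1 + V)` with `V` the variance of the genotype means.
#'
#' @param odds_ratio per-allele odds ratio (> 0).
#' @param risk_allele_freq frequency of the risk allele in (0, 1).
#' @param K disease prevalence (default 0.10).
#' @return fraction of liability variance in `[0, 1)`.
#' @export
liability_variance_snp <- function(odds_ratio, risk_allele_freq, K = 0.10) {
  stopifnot(odds_ratio > 0, risk_allele_freq > 0, risk_allele_freq < 1,
            K > 0, K < 1)
  if (odds_ratio == 1) return(0)
  p <- risk_allele_freq
  f <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # genotypes 0, 1, 2 risk alleles
  or_g <- odds_ratio^(0:2)
  risk_at <- function(log_o0) {
    o <- exp(log_o0) * or_g
    sum(f * o / (1 + o)) - K
  }
  root <- stats::uniroot(risk_at, lower = log(1e-12), upper = log(1e12),
                         tol = 1e-12)
  pi_g <- exp(root$root) * or_g / (1 + exp(root$root) * or_g)
  T_thr <- stats::qnorm(1 - K)
  mu_g <- T_thr - stats::qnorm(1 - pi_g)
  mu_bar <- sum(f * mu_g)
  V <- sum(f * (mu_g - mu_bar)^2)
  V / (1 + V)
}

#' Liability-scale variance explained by a SNP collection
#'
#' Sum of per-SNP fractions under an independence assumption, capped at 1
#' with a warning if the sum exceeds it.
#'
#' @param odds_ratios,risk_allele_freqs parallel vectors.
#' @param K disease prevalence.
#' @return total fraction.
#' @export
liability_variance_set <- function(odds_ratios, risk_allele_freqs,
                                   K = 0.10) {
  stopifnot(length(odds_ratios) == length(risk_allele_freqs))
  if (length(odds_ratios) == 0) return(0)
  total <- sum(mapply(liability_variance_snp, odds_ratios,
                      risk_allele_freqs, MoreArgs = list(K = K)))
  if (total > 1) {
    warning("summed liability variance exceeds 1; capping")
    total <- 1
  }
  total
}

#' Liability-scale variance explained by a weight set
#'
#' Converts each weight to a risk-allele odds ratio (`exp(|w|)`, with the
#' risk-allele frequency flipped to `1 - eaf` for protective effect
#' alleles) and sums per-SNP liability-variance fractions.
#'
#' @param weights a [weight_set()].
#' @param freqs named effect-allele frequencies covering the weight SNPs.
#' @param K disease prevalence.
#' @return total fraction.
#' @export
weightset_liability_variance <- function(weights, freqs, K = 0.10) {
  if (nrow(weights) == 0) return(0)
  f <- freqs[weights$snp_id]
  if (anyNA(f)) stop("missing frequency for weight SNP(s)")
  risk_f <- ifelse(weights$weight >= 0, f, 1 - f)
  liability_variance_set(exp(abs(weights$weight)), risk_f, K = K)
}
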