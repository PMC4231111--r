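# Approximate conditional/joint (C/J) effect estimation from marginal
# summary statistics plus a reference LD matrix, and the iterative
# stepwise model-selection scheme built on it.
#
# The least-squares normal equations X'X b = X'y are reconstructed from
# summary-level quantities: with p_j the effect-allele frequency and
# v_j = 2 p_j (1 - p_j) the Hardy-Weinberg dosage variance,
#   (X'X)_jj = n_j v_j
#   (X'X)_jk = r_jk sqrt(v_j v_k) min(n_j, n_k)      (j != k)
#   (X'y)_j  = n_j v_j b_j
# where b_j is the marginal effect and r_jk the reference-panel LD
# correlation between effect-allele dosages.  The off-diagonal sample
# size is min(n_j, n_k): the overlap of two meta-analysis subsamples is
# at most the smaller of the two.

#' Estimate the phenotype sum of squares from summary statistics
#'
#' Each SNP implies an estimate of `y'y` (the centered phenotype sum of
#' squares) through its marginal fit:
#' `ypy_j = D_jj b_j^2 + D_jj s_j^2 (n_j - 1)` with `D_jj = n_j v_j`.
#' The working value is the median over SNPs, which is robust to
#' occasional mis-specified per-SNP sample sizes.
#'
#' @param stats a [sumstat_table()].
#' @param freqs per-SNP effect-allele frequencies to use for `v_j`
#'   (default: the table's own `eaf`; pass reference-panel frequencies
#'   when available).
#' @return list with `ypy` (median) and `per_snp` (named vector).
#' @export
estimate_ypy <- function(stats, freqs = stats$eaf) {
  stopifnot(nrow(stats) >= 1, length(freqs) == nrow(stats))
  v <- 2 * freqs * (1 - freqs)
  D <- stats$n * v
  per_snp <- D * stats$beta^2 + D * stats$se^2 * (stats$n - 1)
  names(per_snp) <- stats$snp_id
  list(ypy = stats::median(per_snp), per_snp = per_snp)
}

# Reconstruct X'X and X'y for a SNP set.  var_x overrides the
# Hardy-Weinberg variance 2p(1-p) with, e.g., empirical dosage variances
# (under which the reconstruction is exact for a complete sample).
build_normal_eq <- function(stats, ld, freqs, var_x = NULL) {
  k <- nrow(stats)
  ord <- match(stats$snp_id, ld$snp_ids)
  if (anyNA(ord)) {
    stop("LD matrix does not cover SNP(s): ",
         paste(stats$snp_id[is.na(ord)], collapse = ", "))
  }
  r <- ld$r[ord, ord, drop = FALSE]
  v <- if (is.null(var_x)) 2 * freqs * (1 - freqs) else var_x
  D <- stats$n * v
  n_min <- outer(stats$n, stats$n, pmin)
  xtx <- r * sqrt(outer(v, v)) * n_min
  diag(xtx) <- D
  xty <- D * stats$beta
  dimnames(xtx) <- list(stats$snp_id, stats$snp_id)
  names(xty) <- stats$snp_id
  list(xtx = xtx, xty = xty, r = r)
}

#' Joint effect estimation for a fixed SNP set
#'
#' Solves the reconstructed normal equations for the SNPs in `stats`
#' jointly, and derives standard errors from the residual variance
#' `sigma2 = (ypy - b' X'y) / (n_dof - k)` with `n_dof` the median
#' per-SNP sample size of the set.  P-values are two-sided normal Wald
#' tests.  If the approximated inputs yield `sigma2 <= 0`, the fit falls
#' back to `sigma2 = ypy / n_dof` with a warning and sets
#' `sigma2_floored`.
#'
#' @param stats a [sumstat_table()] restricted to the SNP set (order
#'   defines the output order).
#' @param ld an `ld_view` covering the set, oriented to effect alleles.
#' @param ypy phenotype sum of squares, typically from [estimate_ypy()]
#'   over the whole region.
#' @param freqs effect-allele frequencies for the variance terms
#'   (default: the table's `eaf`).
#' @param var_x optional per-SNP dosage variances overriding `2p(1-p)`.
#' @return a `joint_model`: list with `snp_ids`, `beta_joint`,
#'   `se_joint`, `p_joint`, `sigma2`, `ypy`, `n_model`, `xtx`,
#'   `sigma2_floored`.
#' @export
joint_fit <- function(stats, ld, ypy, freqs = stats$eaf, var_x = NULL) {
  stopifnot(nrow(stats) >= 1)
  eq <- build_normal_eq(stats, ld, freqs, var_x)
  k <- nrow(stats)
  ch <- tryCatch(chol(eq$xtx), error = function(e) NULL)
  if (is.null(ch)) {
    off <- abs(eq$r)
    diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("X'X not positive definite; most collinear pair: ",
         stats$snp_id[worst[1]], " / ", stats$snp_id[worst[2]],
         " (r = ", signif(eq$r[worst[1], worst[2]], 3), ")")
  }
  beta <- backsolve(ch, forwardsolve(t(ch), eq$xty))
  xtx_inv <- chol2inv(ch)
  n_dof <- stats::median(stats$n)
  sigma2 <- (ypy - sum(beta * eq$xty)) / (n_dof - k)
  floored <- FALSE
  if (!is.finite(sigma2) || sigma2 <= 0) {
    warning("non-positive residual variance estimate; flooring at ypy/n")
    sigma2 <- ypy / n_dof
    floored <- TRUE
  }
  se <- sqrt(sigma2 * diag(xtx_inv))
  p <- 2 * stats::pnorm(-abs(beta / se))
  p[p == 0] <- .Machine$double.xmin
  structure(list(snp_ids = stats$snp_id,
                 beta_joint = stats::setNames(beta, stats$snp_id),
                 se_joint = stats::setNames(se, stats$snp_id),
                 p_joint = stats::setNames(p, stats$snp_id),
                 sigma2 = sigma2, ypy = ypy, n_model = n_dof,
                 xtx = eq$xtx, sigma2_floored = floored),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("joint_model with", length(x$snp_ids), "SNP(s)\n")
  print(data.frame(snp_id = x$snp_ids, bJ = x$beta_joint,
                   bJ_se = x$se_joint, pJ = x$p_joint,
                   row.names = NULL))
  invisible(x)
}

#' Conditional statistics for a candidate SNP
#'
#' The candidate's effect adjusted for the SNPs currently in the model:
#' its coefficient, SE and Wald p-value in a joint fit over
#' `model SNPs + candidate` (model coefficients are re-estimated in the
#' same fit).
#'
#' @param stats a [sumstat_table()] covering the model SNPs and the
#'   candidate.
#' @param model a `joint_model` (the current selected set).
#' @param candidate `snp_id` of the SNP to test; must not be in the model.
#' @param ld `ld_view` covering model and candidate.
#' @param ypy phenotype sum of squares.
#' @param freqs optional frequency overrides aligned with `stats` rows.
#' @return list with `b_cond`, `se_cond`, `p_cond`.
#' @export
conditional_stats <- function(stats, model, candidate, ld, ypy,
                              freqs = NULL) {
  if (candidate %in% model$snp_ids) stop("candidate already in model")
  ids <- c(model$snp_ids, candidate)
  idx <- match(ids, stats$snp_id)
  if (anyNA(idx)) stop("stats table does not cover model + candidate")
  sub <- stats[idx, , drop = FALSE]
  class(sub) <- c("sumstat_table", "data.frame")
  f <- if (is.null(freqs)) sub$eaf else freqs[idx]
  fit <- joint_fit(sub, ld, ypy, freqs = f)
  k <- length(ids)
  list(b_cond = unname(fit$beta_joint[k]),
       se_cond = unname(fit$se_joint[k]),
       p_cond = unname(fit$p_joint[k]))
}

#' Stepwise conditional/joint model selection for one region
#'
#' The iterative scheme: seed with the region's minimum marginal p-value
#' SNP if it passes `p_threshold`; then alternately (a) test every
#' non-model SNP conditional on the current model — skipping candidates
#' whose maximum squared LD with any model SNP exceeds `r2_collinear` —
#' and add the best if its conditional p passes the threshold, and
#' (b) refit all selected SNPs jointly, dropping (worst first, one per
#' refit) any whose joint p-value no longer passes.  Stops when an
#' iteration neither adds nor drops, or at `max_iter`.  Fully
#' deterministic: candidate ties are broken by (p, bp, snp_id).
#'
#' @param stats a [sumstat_table()] for the region, harmonized to the LD
#'   panel.
#' @param ld `ld_view` over the region's SNPs, effect-allele oriented.
#' @param p_threshold selection p-value threshold.
#' @param r2_collinear squared-correlation guard for candidates
#'   (default 0.9).
#' @param max_iter iteration cap (default 100); hitting it sets
#'   `converged = FALSE` on the result.
#' @param freqs optional frequencies aligned with `stats` rows (e.g.
#'   reference-panel frequencies); default uses the table's `eaf`.
#' @return list with `model` (a `joint_model`, or `NULL` when nothing is
#'   selected), `trace` (data frame of events: iteration, action, snp_id,
#'   p), and `converged`.
#' @export
stepwise_select <- function(stats, ld, p_threshold, r2_collinear = 0.9,
                            max_iter = 100, freqs = NULL) {
  stopifnot(nrow(stats) >= 1, p_threshold > 0, p_threshold <= 1)
  if (is.null(freqs)) freqs <- stats$eaf
  ypy <- estimate_ypy(stats, freqs)$ypy
  trace <- list()
  note <- function(iter, action, snp, p) {
    trace[[length(trace) + 1]] <<- data.frame(
      iteration = iter, action = action, snp_id = snp, p = p,
      stringsAsFactors = FALSE)
  }

  ord <- order(stats$pval, stats$bp, stats$snp_id)
  seed <- ord[1]
  if (stats$pval[seed] >= p_threshold) {
    note(0L, "stop", NA_character_, NA_real_)
    return(list(model = NULL, trace = do.call(rbind, trace),
                converged = TRUE))
  }
  in_model <- stats$snp_id[seed]
  note(0L, "add", stats$snp_id[seed], stats$pval[seed])

  refit <- function(ids) {
    idx <- match(ids, stats$snp_id)
    sub <- stats[idx, , drop = FALSE]
    class(sub) <- c("sumstat_table", "data.frame")
    joint_fit(sub, ld, ypy, freqs = freqs[idx])
  }
  model <- refit(in_model)
  converged <- FALSE

  ld_ord <- match(stats$snp_id, ld$snp_ids)
  r_full <- ld$r[ld_ord, ld_ord, drop = FALSE]

  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    midx <- match(in_model, stats$snp_id)
    cand_idx <- setdiff(seq_len(nrow(stats)), midx)
    if (length(cand_idx) > 0) {
      r2_max <- apply(r_full[cand_idx, midx, drop = FALSE]^2, 1, max)
      collinear <- r2_max > r2_collinear
      for (ci in cand_idx[collinear]) {
        note(iter, "skip-collinear", stats$snp_id[ci], NA_real_)
      }
      cand_idx <- cand_idx[!collinear]
    }
    if (length(cand_idx) > 0) {
      cond <- vapply(cand_idx, function(ci) {
        cs <- conditional_stats(stats, model, stats$snp_id[ci], ld, ypy,
                                freqs = freqs)
        cs$p_cond
      }, numeric(1))
      best <- order(cond, stats$bp[cand_idx], stats$snp_id[cand_idx])[1]
      if (cond[best] < p_threshold) {
        new_id <- stats$snp_id[cand_idx[best]]
        in_model <- c(in_model, new_id)
        note(iter, "add", new_id, cond[best])
        model <- refit(in_model)
        changed <- TRUE
      }
    }
    # backward elimination: worst joint p first, one removal per refit
    repeat {
      pj <- model$p_joint
      bad <- pj >= p_threshold
      if (!any(bad) || length(in_model) == 1) break
      worst <- names(which.max(pj))
      in_model <- setdiff(in_model, worst)
      note(iter, "drop", worst, unname(pj[worst]))
      model <- refit(in_model)
      changed <- TRUE
    }
    if (length(in_model) == 1 && model$p_joint[1] >= p_threshold) {
      # the sole remaining SNP no longer passes: empty model
      note(iter, "drop", in_model, unname(model$p_joint[1]))
      note(iter, "stop", NA_character_, NA_real_)
      return(list(model = NULL, trace = do.call(rbind, trace),
                  converged = TRUE))
    }
    if (!changed) {
      converged <- TRUE
      note(iter, "stop", NA_character_, NA_real_)
      break
    }
  }
  if (!converged) warning("stepwise_select: max_iter reached")
  list(model = model, trace = do.call(rbind, trace), converged = converged)
}

#' Run stepwise selection across a ladder of p-value thresholds
#'
#' One [stepwise_select()] per threshold; models at stricter thresholds
#' need not be nested in looser ones.  The default ladder is the
#' conventional five thresholds from genome-wide significance down to
#' 5e-4.
#'
#' @param stats,ld,r2_collinear,max_iter,freqs as in [stepwise_select()].
#' @param thresholds numeric vector of p-value thresholds.
#' @return named list (one entry per threshold) of [stepwise_select()]
#'   results.
#' @export
thresholds_sweep <- function(stats, ld,
                             thresholds = c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4),
                             r2_collinear = 0.9, max_iter = 100,
                             freqs = NULL) {
  out <- lapply(thresholds, function(th) {
    stepwise_select(stats, ld, th, r2_collinear, max_iter, freqs)
  })
  names(out) <- formatC(thresholds, format = "e", digits = 0)
  out
}

#' Tabulate a region's marginal and joint statistics
#'
#' Side-by-side marginal (`b`, `se`, `p`, `n`) and joint (`bJ`, `bJ_se`,
#' `pJ`) statistics for the selected SNPs of a region, ordered by
#' position, plus the LD `r` between each SNP and the next selected SNP
#' at the locus (the conventional consecutive-pair presentation).
#'
#' @param stats region [sumstat_table()].
#' @param model a `joint_model` (or `NULL` for an empty row set).
#' @param ld `ld_view` covering the model SNPs.
#' @return data frame with one row per selected SNP.
#' @export
tabulate_region <- function(stats, model, ld) {
  cols <- c("snp_id", "chrom", "bp", "effect_allele", "eaf",
            "beta", "se", "pval", "n")
  if (is.null(model)) {
    out <- stats[0, cols]
    out$bJ <- out$bJ_se <- out$pJ <- out$ld_r_next <- numeric(0)
    return(out)
  }
  idx <- match(model$snp_ids, stats$snp_id)
  out <- stats[idx, cols]
  out$bJ <- unname(model$beta_joint)
  out$bJ_se <- unname(model$se_joint)
  out$pJ <- unname(model$p_joint)
  out <- out[order(out$bp, out$snp_id), , drop = FALSE]
  k <- nrow(out)
  ord <- match(out$snp_id, ld$snp_ids)
  out$ld_r_next <- c(if (k > 1) ld$r[cbind(ord[-k], ord[-1])], 0)
  rownames(out) <- NULL
  out
}
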