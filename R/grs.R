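# Weighted genetic risk scores: weight-set construction and scoring.

#' Construct a weight set
#'
#' @param snp_id,effect_allele,weight,source parallel vectors; `weight`
#'   is on the log odds-ratio scale and `source` is `"marginal"` or
#'   `"joint"` per SNP.
#' @param label descriptive label for the score.
#' @return data frame of class `weight_set`.
#' @export
weight_set <- function(snp_id, effect_allele, weight, source, label = "") {
  df <- data.frame(snp_id = as.character(snp_id),
                   effect_allele = toupper(as.character(effect_allele)),
                   weight = as.numeric(weight),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$snp_id)) stop("duplicated snp_id in weight set")
  if (any(!is.finite(df$weight))) stop("non-finite weight")
  attr(df, "label") <- label
  class(df) <- c("weight_set", "data.frame")
  df
}

#' Lead-SNP weight set with marginal weights
#'
#' One entry per lead SNP, weighted by its marginal log odds ratio from
#' the summary statistics.
#'
#' @param stats a [sumstat_table()].
#' @param lead_ids lead SNP ids (all must be present in `stats`).
#' @param label score label.
#' @return a [weight_set()].
#' @export
build_lead_weightset <- function(stats, lead_ids, label = "lead") {
  idx <- match(lead_ids, stats$snp_id)
  if (anyNA(idx)) {
    stop("lead SNP(s) absent from stats: ",
         paste(lead_ids[is.na(idx)], collapse = ", "))
  }
  weight_set(stats$snp_id[idx], stats$effect_allele[idx], stats$beta[idx],
             rep("marginal", length(idx)), label = label)
}

#' Conditional/joint weight set
#'
#' Union over regions of the selected SNPs with their joint coefficients
#' as weights.  Regions must not share SNPs.
#'
#' @param models named list of per-region `joint_model`s (entries may be
#'   `NULL` for regions where nothing was selected).
#' @param stats a [sumstat_table()] supplying effect alleles.
#' @param label score label.
#' @return a [weight_set()] (possibly empty).
#' @export
build_cj_weightset <- function(models, stats, label = "cj") {
  models <- Filter(Negate(is.null), models)
  ids <- unlist(lapply(models, `[[`, "snp_ids"), use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("SNP(s) selected in more than one region: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  w <- unlist(lapply(models, `[[`, "beta_joint"), use.names = FALSE)
  if (length(ids) == 0) {
    return(weight_set(character(0), character(0), numeric(0), character(0),
                      label = label))
  }
  idx <- match(ids, stats$snp_id)
  if (anyNA(idx)) stop("model SNP(s) absent from stats table")
  weight_set(ids, stats$effect_allele[idx], w,
             rep("joint", length(ids)), label = label)
}

#' Merge two weight sets
#'
#' Combines entries; when a SNP appears in both, the entry from `b`
#' (conventionally the joint-weight set) wins.
#'
#' @param a,b [weight_set()]s.
#' @param label label for the merged score.
#' @return a [weight_set()].
#' @export
merge_weightsets <- function(a, b, label = "merged") {
  keep_a <- !(a$snp_id %in% b$snp_id)
  weight_set(c(a$snp_id[keep_a], b$snp_id),
             c(a$effect_allele[keep_a], b$effect_allele),
             c(a$weight[keep_a], b$weight),
             c(a$source[keep_a], b$source), label = label)
}

#' Score individuals with a weighted GRS
#'
#' `score_i = sum_j w_j d_ij` over the weight SNPs present in the panel,
#' with `d_ij` the effect-allele dosage (the panel dosage, reflected when
#' the weight's effect allele is the panel's `alleleA`).  Missing dosages
#' are mean-imputed as `2 * effect-allele frequency` in the panel; weight
#' SNPs absent from the panel are dropped with a message.  Raw dosages
#' are used as stored — validation scoring deliberately does not
#' hard-call.
#'
#' @param panel a [genotype_panel()].
#' @param weights a [weight_set()].
#' @return data frame `(sample_id, score, n_snps_used)`.
#' @export
score_panel <- function(panel, weights) {
  idx <- match(weights$snp_id, panel$variants$snp_id)
  absent <- is.na(idx)
  if (any(absent)) {
    message("score_panel: ", sum(absent),
            " weight SNP(s) absent from panel, dropped")
  }
  w <- weights[!absent, , drop = FALSE]
  idx <- idx[!absent]
  if (nrow(w) == 0) stop("no weight SNPs overlap the panel")
  d <- panel$dosage[, idx, drop = FALSE]
  pb <- toupper(panel$variants$alleleB[idx])
  pa <- toupper(panel$variants$alleleA[idx])
  flip <- w$effect_allele == pa
  bad <- !flip & w$effect_allele != pb
  if (any(bad)) {
    stop("effect allele matches neither panel allele for: ",
         paste(w$snp_id[bad], collapse = ", "))
  }
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  f_eff <- colMeans(d, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(d)) > 0)) {
    d[is.na(d[, j]), j] <- 2 * f_eff[j]
  }
  data.frame(sample_id = panel$sample_ids,
             score = as.vector(d %*% w$weight),
             n_snps_used = nrow(w),
             stringsAsFactors = FALSE)
}

#' Write a weight set as TSV
#' @param weights a [weight_set()].
#' @param path output file.
#' @export
write_weightset <- function(weights, path) {
  utils::write.table(as.data.frame(weights), path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(path)
}
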