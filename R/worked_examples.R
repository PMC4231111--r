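# Worked-example inputs: published two-SNP loci reproducible from
# printed marginal statistics and consecutive-pair LD alone.

#' Load the bundled two-SNP locus worked examples
#'
#' Marginal statistics (effect allele, frequency, log-OR, SE, p, n) and
#' the within-locus LD `r` for five type-2 diabetes loci at which exactly
#' two SNPs were selected by conditional/joint analysis, together with
#' the published joint estimates (`bJ`) for comparison.  These are the
#' loci whose joint fits are fully determined by printed inputs.
#'
#' @return data frame with one row per SNP; `ld_r_next` is the LD between
#'   each SNP and the next SNP of the same locus.
#' @export
twosnp_examples <- function() {
  path <- system.file("extdata", "twosnp_loci.tsv", package = "cojoscore")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Joint fit of one two-SNP worked-example locus
#'
#' Reconstructs the two-SNP normal equations from the locus's printed
#' marginal statistics and LD `r` and solves for the joint effects.
#'
#' @param locus locus name as in [twosnp_examples()].
#' @param examples the examples table (default: bundled data).
#' @return a `joint_model` (see [joint_fit()]).
#' @export
fit_twosnp_locus <- function(locus, examples = twosnp_examples()) {
  rows <- examples[examples$locus == locus, , drop = FALSE]
  if (nrow(rows) != 2) stop("unknown or non-two-SNP locus: ", locus)
  stats <- sumstat_table(rows[, c("snp_id", "chrom", "bp",
                                  "effect_allele", "eaf", "beta", "se",
                                  "pval", "n")])
  r <- rows$ld_r_next[1]
  ld <- structure(list(
    snp_ids = stats$snp_id,
    r = matrix(c(1, r, r, 1), 2,
               dimnames = list(stats$snp_id, stats$snp_id)),
    n_pairs = matrix(NA_real_, 2, 2)), class = "ld_view")
  ypy <- estimate_ypy(stats)$ypy
  joint_fit(stats, ld, ypy)
}
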