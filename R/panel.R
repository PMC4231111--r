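# Reference genotype panel: containers, I/O, QC and LD computation.

#' Construct a genotype panel
#'
#' Holds a samples-by-variants dosage matrix counting copies of `alleleB`
#' (values in `[0, 2]`, `NA` for missing), together with sample ids and
#' variant metadata.  Panels are `hard_called` when every non-missing
#' dosage is an integer in `{0, 1, 2}`.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param variants data frame with columns `snp_id`, `chrom`, `bp`,
#'   `alleleA`, `alleleB`.
#' @param dosage numeric matrix, `length(sample_ids)` rows by
#'   `nrow(variants)` columns.
#' @param hard_called logical flag.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_ids, variants, dosage,
                           hard_called = FALSE) {
  sample_ids <- as.character(sample_ids)
  stopifnot(is.matrix(dosage),
            nrow(dosage) == length(sample_ids),
            ncol(dosage) == nrow(variants),
            all(c("snp_id", "chrom", "bp", "alleleA", "alleleB") %in%
                  names(variants)))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (hard_called && any(dosage != round(dosage), na.rm = TRUE)) {
    stop("hard_called panel contains non-integer dosages")
  }
  if (anyDuplicated(variants$snp_id)) stop("duplicated variant snp_id")
  dimnames(dosage) <- list(sample_ids, variants$snp_id)
  structure(list(sample_ids = sample_ids,
                 variants = as.data.frame(variants,
                                          stringsAsFactors = FALSE),
                 dosage = dosage,
                 hard_called = hard_called),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants;",
      if (x$hard_called) "hard-called" else "dosage", "\n")
  invisible(x)
}

#' Subset a panel by samples and/or variants
#'
#' @param panel a [genotype_panel()].
#' @param samples sample ids or indices to keep (default all).
#' @param snp_ids variant ids to keep, in the requested order (default all).
#' @return a [genotype_panel()].
#' @export
subset_panel <- function(panel, samples = NULL, snp_ids = NULL) {
  si <- if (is.null(samples)) seq_along(panel$sample_ids) else {
    if (is.character(samples)) match(samples, panel$sample_ids) else samples
  }
  vi <- if (is.null(snp_ids)) seq_len(nrow(panel$variants)) else
    match(snp_ids, panel$variants$snp_id)
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(vi)) {
    stop("variant(s) absent from panel: ",
         paste(snp_ids[is.na(vi)], collapse = ", "))
  }
  genotype_panel(panel$sample_ids[si], panel$variants[vi, , drop = FALSE],
                 panel$dosage[si, vi, drop = FALSE], panel$hard_called)
}

#' Read a transposed-dosage text panel (PLINK traw layout)
#'
#' Tab-delimited text with header
#' `CHR SNP (C)M POS COUNTED ALT <sample ids...>`, one row per variant and
#' dosages counting the `COUNTED` allele; `NA` marks missing.  This is the
#' plain-text layout PLINK emits with `--recode A-transpose`.
#'
#' @param path file path.
#' @return a [genotype_panel()] (dosages count `alleleB = COUNTED`).
#' @export
read_traw <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
  if (!all(meta_cols %in% names(raw))) {
    stop("not a traw file: expected header columns ",
         paste(meta_cols, collapse = " "))
  }
  sample_ids <- setdiff(names(raw), meta_cols)
  dosage <- t(as.matrix(raw[, sample_ids, drop = FALSE]))
  variants <- data.frame(snp_id = raw$SNP, chrom = as.character(raw$CHR),
                         bp = raw$POS, alleleA = raw$ALT,
                         alleleB = raw$COUNTED, stringsAsFactors = FALSE)
  hard <- all(dosage == round(dosage), na.rm = TRUE)
  genotype_panel(sample_ids, variants, dosage, hard_called = hard)
}

#' Write a panel as transposed-dosage text (PLINK traw layout)
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @export
write_traw <- function(panel, path) {
  out <- data.frame(CHR = panel$variants$chrom, SNP = panel$variants$snp_id,
                    CM = 0, POS = panel$variants$bp,
                    COUNTED = panel$variants$alleleB,
                    ALT = panel$variants$alleleA,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[3] <- "(C)M"
  out <- cbind(out, as.data.frame(t(panel$dosage)))
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from a VCF file
#'
#' Uses the `DS` FORMAT field (imputed dosage of the ALT allele) when
#' present, otherwise derives hard-call dosages from `GT`.  Dosages count
#' the ALT allele (`alleleB = ALT`).
#'
#' @param path uncompressed or bgzipped VCF.
#' @param field `"DS"` or `"GT"`; default prefers `DS` and falls back.
#' @return a [genotype_panel()].
#' @export
read_vcf_panel <- function(path, field = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF panels requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if (is.null(field)) field <- if ("DS" %in% fmt) "DS" else "GT"
  if (field == "DS") {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    hard <- FALSE
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }
    ds <- apply(gt, c(1, 2), count_alt)
    hard <- TRUE
  }
  fix <- vcfR::getFIX(vcf)
  variants <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                         bp = as.numeric(fix[, "POS"]),
                         alleleA = fix[, "REF"], alleleB = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_panel(colnames(ds), variants, t(ds), hard_called = hard)
}

#' Hard-call imputed dosages with an uncertainty band
#'
#' Dosages strictly inside either open band (heterozygote-adjacent
#' uncertainty zones) are set missing; everything else is rounded to the
#' nearest integer in `{0, 1, 2}`.  Band endpoints themselves are kept and
#' rounded.  Idempotent on already-integer dosages.
#'
#' @param panel a [genotype_panel()].
#' @param low_band,high_band open intervals of dosage values treated as
#'   uncalled.
#' @param snp_level if `TRUE`, drop any variant with at least one dosage
#'   inside a band instead of masking genotypes (a stricter reading of the
#'   same rule).
#' @return a hard-called [genotype_panel()].
#' @export
hard_call <- function(panel, low_band = c(0.33, 0.66),
                      high_band = c(1.33, 1.66), snp_level = FALSE) {
  d <- panel$dosage
  in_band <- (d > low_band[1] & d < low_band[2]) |
    (d > high_band[1] & d < high_band[2])
  in_band[is.na(in_band)] <- FALSE
  if (snp_level) {
    bad_snp <- colSums(in_band) > 0
    d <- d[, !bad_snp, drop = FALSE]
    variants <- panel$variants[!bad_snp, , drop = FALSE]
    d <- pmin(pmax(round(d), 0), 2)
    return(genotype_panel(panel$sample_ids, variants, d, hard_called = TRUE))
  }
  d[in_band] <- NA
  d <- pmin(pmax(round(d), 0), 2)
  genotype_panel(panel$sample_ids, panel$variants, d, hard_called = TRUE)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the Hardy-Weinberg expectation at the sample allele
#' frequency.  Monomorphic variants return `p = 1` by convention.
#'
#' @param counts numeric vector `(n_AA, n_Aa, n_aa)`.
#' @return list with `statistic` and `p`.
#' @export
hwe_chi2 <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(list(statistic = 0, p = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-variant allele frequency
#'
#' Frequency of `alleleB` (the counted allele): mean non-missing dosage
#' divided by two.  Variants with all dosages missing return `NA`.
#'
#' @param panel a [genotype_panel()].
#' @return named numeric vector, one entry per variant.
#' @export
allele_freq <- function(panel) {
  f <- colMeans(panel$dosage, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  f
}

#' Variant-level quality control
#'
#' Applies, in order: imputation-quality filter (`info < info_min`, only
#' when an `info` vector is supplied), missingness (`> miss_max`), minor
#' allele frequency (`< maf_min`), and Hardy-Weinberg equilibrium
#' (`p < hwe_p_min`, hard-called panels only).  Set a threshold to `NULL`
#' to disable that rule.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor-allele frequency (default 0.005).
#' @param miss_max maximum missing fraction (default 0.10).
#' @param hwe_p_min minimum HWE chi-square p-value (default 0.005).
#' @param info_min minimum imputation-quality score (default 0.6).
#' @param info optional per-variant imputation-quality vector.
#' @return list with `panel` (filtered) and `report` (per-rule exclusion
#'   counts and per-variant first failing rule).
#' @export
qc_variants <- function(panel, maf_min = 0.005, miss_max = 0.10,
                        hwe_p_min = 0.005, info_min = 0.6, info = NULL) {
  m <- nrow(panel$variants)
  fail <- rep(NA_character_, m)

  if (!is.null(info) && !is.null(info_min)) {
    stopifnot(length(info) == m)
    fail[is.na(fail) & info < info_min] <- "info"
  }
  if (!is.null(miss_max)) {
    miss <- colMeans(is.na(panel$dosage))
    fail[is.na(fail) & miss > miss_max] <- "missingness"
  }
  if (!is.null(maf_min)) {
    f <- allele_freq(panel)
    maf <- pmin(f, 1 - f)
    fail[is.na(fail) & (is.na(maf) | maf < maf_min)] <- "maf"
  }
  if (!is.null(hwe_p_min)) {
    if (!panel$hard_called) {
      stop("HWE filtering requires a hard-called panel")
    }
    hwe_p <- vapply(seq_len(m), function(j) {
      d <- panel$dosage[, j]
      d <- d[!is.na(d)]
      if (length(d) == 0) return(1)
      hwe_chi2(c(sum(d == 0), sum(d == 1), sum(d == 2)))$p
    }, numeric(1))
    fail[is.na(fail) & hwe_p < hwe_p_min] <- "hwe"
  }

  keep <- is.na(fail)
  if (!any(keep)) stop("all variants removed by QC")
  report <- list(
    counts = table(factor(fail, levels = c("info", "missingness", "maf",
                                           "hwe"))),
    variant = data.frame(snp_id = panel$variants$snp_id,
                         excluded = !keep, rule = fail,
                         stringsAsFactors = FALSE)
  )
  list(panel = subset_panel(panel, snp_ids = panel$variants$snp_id[keep]),
       report = report)
}

#' Effect-allele-oriented LD correlation matrix
#'
#' Pairwise-complete Pearson correlations between oriented dosages.  A
#' SNP's `orientation` flag of `-1` means its effect allele is the panel's
#' `alleleA`, so its dosage is reflected (`2 - d`) before correlating;
#' entry `(j, k)` is then the correlation between the effect-allele counts
#' of SNPs `j` and `k`.  Variants monomorphic in the subsample get zero
#' off-diagonal correlation with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param snp_ids ordered subset of variants (default: all).
#' @param orientation per-SNP `+1`/`-1` flags aligned with `snp_ids`.
#' @return an `ld_view`: list with `snp_ids`, `r` (correlation matrix) and
#'   `n_pairs` (pairwise-complete sample counts).
#' @export
ld_corr <- function(panel, snp_ids = NULL, orientation = NULL) {
  if (is.null(snp_ids)) snp_ids <- panel$variants$snp_id
  sub <- subset_panel(panel, snp_ids = snp_ids)
  d <- sub$dosage
  if (is.null(orientation)) orientation <- rep(1L, length(snp_ids))
  stopifnot(length(orientation) == length(snp_ids),
            all(orientation %in% c(-1L, 1L)))
  flip <- orientation == -1L
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  sds <- apply(d, 2, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  if (any(mono)) {
    warning("monomorphic variant(s) in LD subsample: ",
            paste(snp_ids[mono], collapse = ", "))
    r[mono, ] <- 0
    r[, mono] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  present <- !is.na(sub$dosage)
  n_pairs <- crossprod(present)
  dimnames(r) <- dimnames(n_pairs) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r = r, n_pairs = n_pairs),
            class = "ld_view")
}

#' @export
print.ld_view <- function(x, ...) {
  cat("ld_view over", length(x$snp_ids), "SNPs\n")
  invisible(x)
}

#' Genomic relationship matrix
#'
#' Standard allelic-covariance relationship
#' `A_ij = (1/m) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`
#' over the panel's variants; missing dosages are mean-imputed per variant
#' (contributing zero after centering).
#'
#' @param panel a [genotype_panel()].
#' @return symmetric samples-by-samples matrix.
#' @export
grm <- function(panel) {
  f <- allele_freq(panel)
  usable <- !is.na(f) & f > 0 & f < 1
  if (sum(usable) < 2) stop("need >= 2 polymorphic variants")
  d <- panel$dosage[, usable, drop = FALSE]
  f <- f[usable]
  z <- sweep(d, 2, 2 * f, "-")
  z <- sweep(z, 2, sqrt(2 * f * (1 - f)), "/")
  z[is.na(z)] <- 0
  tcrossprod(z) / ncol(z)
}

#' Prune related samples from a panel
#'
#' Computes the genomic relationship matrix and greedily removes, from
#' each pair at or above `threshold`, the member with more over-threshold
#' partners (ties go to the later sample id) until no related pair
#' remains.
#'
#' @param panel a [genotype_panel()].
#' @param threshold relationship-coefficient cutoff (default 0.025).
#' @return character vector of retained sample ids.
#' @export
relatedness_prune <- function(panel, threshold = 0.025) {
  A <- grm(panel)
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  ids <- panel$sample_ids
  repeat {
    Ak <- A[keep, keep, drop = FALSE]
    over <- Ak >= threshold
    deg <- rowSums(over)
    if (all(deg == 0)) break
    # remove the sample with the most related partners; tie -> later id
    worst <- which(deg == max(deg))
    victim_local <- worst[length(worst)]
    victim <- which(keep)[victim_local]
    keep[victim] <- FALSE
  }
  ids[keep]
}
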