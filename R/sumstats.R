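# Summary-statistics I/O, validation, regional subsetting and lead-SNP
# definition.

#' Construct a summary-statistic table
#'
#' A `sumstat_table` is a data frame with one row per SNP carrying the
#' marginal association statistics used by the conditional/joint machinery:
#' effect allele, effect-allele frequency, log odds ratio (or linear-model
#' beta), its standard error, the marginal p-value, and the per-SNP sample
#' size.  Meta-analyses routinely report non-integer sample sizes, so `n`
#' is a positive real.
#'
#' @param df data frame with columns `snp_id`, `chrom`, `bp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `chrom`, `bp` and `other_allele` may be `NA` (the minimal exchange
#'   dialect omits positions); all other fields are mandatory.
#' @param validate drop rows that violate the numeric invariants
#'   (`se > 0`, `0 < eaf < 1`, `0 < pval <= 1`, `n > 1`) instead of
#'   erroring.  The number of dropped rows is reported with a message.
#' @return a data frame of class `sumstat_table`.
#' @export
sumstat_table <- function(df, validate = TRUE) {
  required <- c("snp_id", "effect_allele", "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("chrom", "bp", "other_allele")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df <- df[, c("snp_id", "chrom", "bp", "effect_allele", "other_allele",
               "eaf", "beta", "se", "pval", "n")]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$bp <- as.numeric(df$bp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  ok <- is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    is.finite(df$eaf) & df$eaf > 0 & df$eaf < 1 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    is.finite(df$n) & df$n > 1
  if (any(!ok)) {
    if (!validate) stop(sum(!ok), " row(s) violate sumstat invariants")
    message("sumstat_table: dropped ", sum(!ok),
            " row(s) failing numeric validation")
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid summary-statistic rows")
  if (anyDuplicated(df$snp_id)) {
    stop("duplicated snp_id: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sumstat_table", "data.frame")
  df
}

#' Default column mapping for the .ma summary-statistics dialect
#'
#' The minimal exchange format is whitespace-delimited text with header
#' `SNP A1 A2 freq b se p N`; `CHR`/`BP` columns are optional extensions
#' carrying genomic positions.  Supply a different mapping to read other
#' headers.
#'
#' @param snp,a1,a2,freq,b,se,p,n,chrom,bp header names for each field.
#' @return named character vector used by [read_ma()].
#' @export
ma_dialect <- function(snp = "SNP", a1 = "A1", a2 = "A2", freq = "freq",
                       b = "b", se = "se", p = "p", n = "N",
                       chrom = "CHR", bp = "BP") {
  c(snp = snp, a1 = a1, a2 = a2, freq = freq, b = b, se = se, p = p, n = n,
    chrom = chrom, bp = bp)
}

#' Read a .ma-style summary-statistics file
#'
#' @param path whitespace-delimited text file with a header row.
#' @param dialect column mapping, see [ma_dialect()].
#' @return a [sumstat_table()].
#' @export
read_ma <- function(path, dialect = ma_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mandatory <- c("snp", "a1", "freq", "b", "se", "p", "n")
  for (field in mandatory) {
    if (!dialect[[field]] %in% names(raw)) {
      stop("missing mandatory column '", dialect[[field]], "' in ", path)
    }
  }
  get_opt <- function(field) {
    if (dialect[[field]] %in% names(raw)) raw[[dialect[[field]]]] else NA
  }
  sumstat_table(data.frame(
    snp_id = raw[[dialect[["snp"]]]],
    chrom = get_opt("chrom"),
    bp = get_opt("bp"),
    effect_allele = raw[[dialect[["a1"]]]],
    other_allele = get_opt("a2"),
    eaf = raw[[dialect[["freq"]]]],
    beta = raw[[dialect[["b"]]]],
    se = raw[[dialect[["se"]]]],
    pval = raw[[dialect[["p"]]]],
    n = raw[[dialect[["n"]]]],
    stringsAsFactors = FALSE
  ))
}

#' Write a summary-statistic table as .ma text
#'
#' Writes the extended dialect `SNP A1 A2 freq b se p N [CHR BP]`;
#' position columns are included when present.
#'
#' @param stats a [sumstat_table()].
#' @param path output file.
#' @export
write_ma <- function(stats, path) {
  out <- data.frame(SNP = stats$snp_id, A1 = stats$effect_allele,
                    A2 = stats$other_allele, freq = stats$eaf,
                    b = stats$beta, se = stats$se, p = stats$pval,
                    N = stats$n, stringsAsFactors = FALSE)
  if (!all(is.na(stats$chrom))) {
    out$CHR <- stats$chrom
    out$BP <- stats$bp
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Define an analysis region around a lead SNP
#'
#' Regions are closed intervals `[center_bp - half_width_bp,
#' center_bp + half_width_bp]` on one chromosome; the default half-width of
#' 1 Mb gives the conventional 2 Mb window around an established locus.
#'
#' @param lead_snp_id SNP identifier anchoring the region.
#' @param chrom chromosome (character).
#' @param center_bp 1-based center position.
#' @param half_width_bp half-width in base pairs (> 0 unless degenerate).
#' @return a `region_spec` list.
#' @export
region_spec <- function(lead_snp_id, chrom, center_bp,
                        half_width_bp = 1000000L) {
  stopifnot(half_width_bp >= 0, center_bp >= 1)
  structure(list(lead_snp_id = as.character(lead_snp_id),
                 chrom = as.character(chrom),
                 center_bp = as.numeric(center_bp),
                 half_width_bp = as.numeric(half_width_bp)),
            class = "region_spec")
}

#' Read a region list from a 4-column TSV
#'
#' Expected columns: `lead_snp_id`, `chrom`, `center_bp`, `half_width_bp`.
#'
#' @param path TSV file with header.
#' @return list of [region_spec()] objects.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    region_spec(df$lead_snp_id[i], df$chrom[i], df$center_bp[i],
                df$half_width_bp[i])
  })
}

#' Subset a summary-statistic table to a region
#'
#' @param stats a [sumstat_table()] with positions.
#' @param region a [region_spec()].
#' @return the rows with `chrom == region$chrom` and
#'   `|bp - center_bp| <= half_width_bp` (closed interval).  An empty
#'   result is returned with a warning, not an error.
#' @export
extract_region <- function(stats, region) {
  if (!region$chrom %in% stats$chrom) {
    stop("chromosome ", region$chrom, " absent from table")
  }
  keep <- stats$chrom == region$chrom &
    abs(stats$bp - region$center_bp) <= region$half_width_bp
  keep[is.na(keep)] <- FALSE
  out <- stats[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("region ", region$lead_snp_id, " is empty")
  rownames(out) <- NULL
  class(out) <- c("sumstat_table", "data.frame")
  out
}

#' Identify the lead SNP of a region
#'
#' The lead SNP is the variant with the smallest marginal p-value inside
#' the region; ties are broken by smallest position, then lexicographically
#' by id, so the result is invariant to row order.
#'
#' @param stats a [sumstat_table()].
#' @param region a [region_spec()]; pass `NULL` to search the whole table.
#' @return the lead `snp_id` (character scalar).
#' @export
define_lead_snp <- function(stats, region = NULL) {
  if (!is.null(region)) stats <- extract_region(stats, region)
  if (nrow(stats) == 0) stop("cannot define a lead SNP in an empty region")
  ord <- order(stats$pval, stats$bp, stats$snp_id)
  stats$snp_id[ord[1]]
}

#' Harmonize summary statistics to a reference panel's allele coding
#'
#' Orients each SNP's effect allele against the allele the panel counts
#' (its `alleleB`).  SNPs whose effect allele is the counted allele get
#' orientation `+1`; SNPs whose effect allele is the panel's other allele
#' get orientation `-1` (betas are untouched; the orientation flag is what
#' downstream LD and scoring use).  Strand-ambiguous A/T and C/G SNPs are
#' excluded under the default policy when their frequency is uninformative
#' (effect-allele frequency within `ambiguous_band`), and otherwise
#' resolved by comparing frequencies with the panel.  SNPs absent from the
#' panel or with incompatible allele pairs are dropped and counted.
#'
#' @param stats a [sumstat_table()].
#' @param panel_variants data frame with columns `snp_id`, `alleleA`,
#'   `alleleB` and optionally `freq` (frequency of alleleB, used for
#'   ambiguity resolution).
#' @param ambiguous_policy `"exclude"` drops all strand-ambiguous SNPs;
#'   `"band"` (default) drops only those with `eaf` inside
#'   `ambiguous_band` and resolves the rest by frequency matching;
#'   `"keep"` treats them like any other SNP.
#' @param ambiguous_band frequency band within which an ambiguous SNP is
#'   considered unresolvable.
#' @return list with `stats` (harmonized table plus an `orientation`
#'   column) and `report` (per-SNP disposition: kept / flipped /
#'   ambiguous_dropped / absent / incompatible).
#' @export
harmonize_to_reference <- function(stats, panel_variants,
                                   ambiguous_policy = c("band", "exclude",
                                                        "keep"),
                                   ambiguous_band = c(0.35, 0.65)) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  idx <- match(stats$snp_id, panel_variants$snp_id)
  n <- nrow(stats)
  disposition <- character(n)
  orientation <- rep(NA_integer_, n)

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  is_ambiguous <- function(a, b) !is.na(a) && !is.na(b) &&
    a %in% names(comp) && identical(unname(comp[a]), b)

  pa <- toupper(panel_variants$alleleA[idx])
  pb <- toupper(panel_variants$alleleB[idx])
  pf <- if ("freq" %in% names(panel_variants)) panel_variants$freq[idx] else
    rep(NA_real_, n)

  for (i in seq_len(n)) {
    if (is.na(idx[i])) {
      disposition[i] <- "absent"
      next
    }
    ea <- stats$effect_allele[i]
    oa <- stats$other_allele[i]
    if (ea == pb[i] && (is.na(oa) || oa == pa[i])) {
      orientation[i] <- 1L
    } else if (ea == pa[i] && (is.na(oa) || oa == pb[i])) {
      orientation[i] <- -1L
    } else {
      disposition[i] <- "incompatible"
      next
    }
    if (is_ambiguous(pa[i], pb[i])) {
      if (ambiguous_policy == "exclude") {
        disposition[i] <- "ambiguous_dropped"
        orientation[i] <- NA_integer_
        next
      }
      if (ambiguous_policy == "band") {
        inside <- stats$eaf[i] >= ambiguous_band[1] &&
          stats$eaf[i] <= ambiguous_band[2]
        if (inside || is.na(pf[i])) {
          disposition[i] <- "ambiguous_dropped"
          orientation[i] <- NA_integer_
          next
        }
        # resolve by frequency: pick the orientation whose implied panel
        # frequency is closer to the reported effect-allele frequency
        f_as_is <- if (orientation[i] == 1L) pf[i] else 1 - pf[i]
        if (abs(stats$eaf[i] - f_as_is) >
            abs(stats$eaf[i] - (1 - f_as_is))) {
          orientation[i] <- -orientation[i]
        }
      }
    }
    disposition[i] <- if (orientation[i] == 1L) "kept" else "flipped"
  }

  report <- data.frame(snp_id = stats$snp_id, disposition = disposition,
                       orientation = orientation, stringsAsFactors = FALSE)
  keep <- disposition %in% c("kept", "flipped")
  out <- stats[keep, , drop = FALSE]
  out$orientation <- orientation[keep]
  rownames(out) <- NULL
  class(out) <- c("sumstat_table", "data.frame")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("harmonize_to_reference: dropped ", n_dropped, " SNP(s) (",
            sum(disposition == "absent"), " absent, ",
            sum(disposition == "incompatible"), " incompatible, ",
            sum(disposition == "ambiguous_dropped"), " ambiguous)")
  }
  list(stats = out, report = report)
}
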