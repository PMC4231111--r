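# End-to-end orchestration: per-region discovery across thresholds and
# validation-cohort prediction comparisons, plus a small command-line
# front end.

#' Per-region conditional/joint discovery across thresholds
#'
#' For each region: harmonize the summary statistics to the reference
#' panel, subset to the region, compute effect-allele-oriented LD, and
#' run the stepwise threshold sweep.  Reference-panel allele frequencies
#' replace the reported ones for the variance terms when
#' `use_panel_freq = TRUE` (the convention when the summary file carries
#' no frequencies of its own).
#'
#' @param sumstats a [sumstat_table()].
#' @param panel the reference [genotype_panel()] (hard-called for LD).
#' @param regions list of [region_spec()]s.
#' @param thresholds p-value threshold ladder.
#' @param r2_collinear,max_iter passed to [stepwise_select()].
#' @param use_panel_freq use panel allele frequencies for `v_j`.
#' @param out_dir if non-NULL, write one Table-1-style TSV per threshold
#'   plus the stepwise trace.
#' @return list of class `discovery_result`: per-region list with
#'   `region`, `stats`, `ld`, `sweep` (threshold -> stepwise result),
#'   plus `thresholds` and `tables` (threshold -> combined data frame).
#' @export
run_discovery <- function(sumstats, panel, regions,
                          thresholds = c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4),
                          r2_collinear = 0.9, max_iter = 100,
                          use_panel_freq = TRUE, out_dir = NULL) {
  harm <- harmonize_to_reference(sumstats, panel$variants)
  stats <- harm$stats
  panel_f <- allele_freq(panel)
  failed <- character(0)
  per_region <- list()
  for (rg in regions) {
    res <- tryCatch({
      reg_stats <- extract_region(stats, rg)
      if (nrow(reg_stats) == 0) stop("empty region")
      ld <- ld_corr(panel, reg_stats$snp_id,
                    orientation = reg_stats$orientation)
      freqs <- if (use_panel_freq) {
        pf <- panel_f[match(reg_stats$snp_id, panel$variants$snp_id)]
        ifelse(reg_stats$orientation == 1L, pf, 1 - pf)
      } else reg_stats$eaf
      sweep_res <- thresholds_sweep(reg_stats, ld, thresholds,
                                    r2_collinear, max_iter, freqs)
      list(region = rg, stats = reg_stats, ld = ld, sweep = sweep_res)
    }, error = function(e) {
      warning("region ", rg$lead_snp_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, rg$lead_snp_id) else
      per_region[[rg$lead_snp_id]] <- res
  }
  if (length(per_region) == 0) stop("all regions failed")

  th_names <- formatC(thresholds, format = "e", digits = 0)
  tables <- lapply(th_names, function(tn) {
    do.call(rbind, lapply(per_region, function(r) {
      tb <- tabulate_region(r$stats, r$sweep[[tn]]$model, r$ld)
      if (nrow(tb) > 0) tb$region <- r$region$lead_snp_id
      tb
    }))
  })
  names(tables) <- th_names
  out <- structure(list(regions = per_region, thresholds = thresholds,
                        tables = tables, failed = failed,
                        harmonization = harm$report),
                   class = "discovery_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tn in th_names) {
      utils::write.table(tables[[tn]],
                         file.path(out_dir, paste0("table1.", tn, ".tsv")),
                         quote = FALSE, sep = "\t", row.names = FALSE)
    }
    traces <- do.call(rbind, lapply(names(per_region), function(id) {
      do.call(rbind, lapply(th_names, function(tn) {
        tr <- per_region[[id]]$sweep[[tn]]$trace
        if (is.null(tr)) return(NULL)
        cbind(region = id, threshold = tn, tr)
      }))
    }))
    utils::write.table(traces, file.path(out_dir, "trace.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  }
  out
}

#' Prediction comparison on a validation cohort
#'
#' At each threshold, fits four logistic models — baseline (age + sex),
#' baseline + lead-SNP GRS, baseline + C/J GRS, and baseline + merged
#' lead/C/J GRS — and reports AUC, delta-AUC over baseline, Nagelkerke's
#' R2, AIC, liability-scale variance explained by each weight set, and
#' the pairwise DeLong comparison of the lead and C/J scores.
#'
#' @param discovery a `discovery_result` from [run_discovery()].
#' @param sumstats the (original) [sumstat_table()] used for discovery.
#' @param val_panel validation [genotype_panel()] (raw dosages; scoring
#'   does not hard-call).
#' @param val_pheno phenotype frame `(sample_id, status, age, sex)`.
#' @param K disease prevalence for the liability-scale conversion.
#' @return list of class `prediction_report`: `models` (one row per
#'   model per threshold), `pairs` (DeLong comparisons), `weights`.
#' @export
run_validation <- function(discovery, sumstats, val_panel, val_pheno,
                           K = 0.10) {
  stopifnot(all(c("status", "age", "sex") %in% names(val_pheno)))
  if (length(unique(val_pheno$status)) < 2) {
    stop("both outcome classes required in the validation cohort")
  }
  lead_ids <- vapply(discovery$regions, function(r) {
    define_lead_snp(r$stats)
  }, character(1))
  base_cov <- val_pheno[, c("age", "sex")]
  null_fit <- fit_logistic(val_pheno$status, NULL)  # intercept only
  base_fit <- fit_logistic(val_pheno$status, base_cov)
  base_auc <- auc(base_fit$fitted, val_pheno$status)
  freqs <- stats::setNames(sumstats$eaf, sumstats$snp_id)

  th_names <- names(discovery$tables)
  model_rows <- list()
  pair_rows <- list()
  weight_sets <- list()
  add_model <- function(threshold, label, ws, fit, scores) {
    model_rows[[length(model_rows) + 1]] <<- data.frame(
      threshold = threshold, model = label,
      n_snps = if (is.null(ws)) 0L else nrow(ws),
      auc = auc(fit$fitted, val_pheno$status),
      delta_auc = auc(fit$fitted, val_pheno$status) - base_auc,
      nagelkerke_r2 = nagelkerke(fit$loglik, null_fit$loglik, fit$n),
      aic = aic_of(fit$loglik, fit$k),
      liability_variance = if (is.null(ws)) NA_real_ else
        weightset_liability_variance(ws, freqs, K),
      stringsAsFactors = FALSE)
  }

  model_rows[[1]] <- data.frame(
    threshold = "-", model = "age+sex", n_snps = 0L, auc = base_auc,
    delta_auc = 0,
    nagelkerke_r2 = nagelkerke(base_fit$loglik, null_fit$loglik,
                               base_fit$n),
    aic = aic_of(base_fit$loglik, base_fit$k),
    liability_variance = NA_real_, stringsAsFactors = FALSE)

  for (tn in th_names) {
    models <- lapply(discovery$regions, function(r) r$sweep[[tn]]$model)
    selected <- !vapply(models, is.null, logical(1))
    if (!any(selected)) next
    lead_sel <- lead_ids[selected]
    lead_ws <- build_lead_weightset(sumstats, unique(lead_sel),
                                    label = paste0("lead@", tn))
    cj_ws <- build_cj_weightset(models[selected], sumstats,
                                label = paste0("cj@", tn))
    both_ws <- merge_weightsets(lead_ws, cj_ws,
                                label = paste0("lead+cj@", tn))
    scored <- lapply(list(lead = lead_ws, cj = cj_ws, both = both_ws),
                     function(ws) score_panel(val_panel, ws)$score)
    fits <- lapply(scored, function(s) {
      fit_logistic(val_pheno$status, cbind(base_cov, grs = s))
    })
    add_model(tn, "lead GRS", lead_ws, fits$lead, scored$lead)
    add_model(tn, "C/J GRS", cj_ws, fits$cj, scored$cj)
    add_model(tn, "lead+C/J GRS", both_ws, fits$both, scored$both)
    dl <- delong_compare(fits$cj$fitted, fits$lead$fitted,
                         val_pheno$status)
    pair_rows[[length(pair_rows) + 1]] <- data.frame(
      threshold = tn, model_a = "C/J GRS", model_b = "lead GRS",
      delta_auc = dl$delta_auc, delong_p = dl$p,
      stringsAsFactors = FALSE)
    weight_sets[[tn]] <- list(lead = lead_ws, cj = cj_ws, both = both_ws)
  }

  structure(list(models = do.call(rbind, model_rows),
                 pairs = do.call(rbind, pair_rows),
                 weights = weight_sets),
            class = "prediction_report")
}

#' Write a prediction report as TSV + JSON
#'
#' @param report a `prediction_report`.
#' @param dir output directory.
#' @export
write_prediction_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$models, file.path(dir, "table2.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  if (!is.null(report$pairs)) {
    utils::write.table(report$pairs, file.path(dir, "delong_pairs.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
  }
  jsonlite::write_json(list(models = report$models, pairs = report$pairs),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (emit a synthetic input bundle from a preset),
#' `discover` (per-region C/J threshold sweep), `validate` (prediction
#' comparison).  A thin wrapper over the package functions; see
#' `inst/cli/cojoscore` for the installed script.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code, invisibly.
#' @export
cojo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cojoscore <command> [options]",
    "commands:",
    "  simulate --preset masked-pair|chain --seed INT --out DIR",
    "  discover --sumstats FILE --panel FILE --regions FILE --out DIR",
    "           [--threshold P ...]",
    "  validate --sumstats FILE --panel FILE --regions FILE",
    "           --val-panel FILE --pheno FILE --out DIR [--threshold P ...]",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  opts <- list(threshold = character(0))
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!grepl("^--", args[i]) || i == length(args)) {
      message("unknown or incomplete flag: ", args[i], "\n", usage)
      return(invisible(2L))
    }
    if (key == "threshold") {
      opts$threshold <- c(opts$threshold, args[i + 1])
    } else {
      opts[[key]] <- args[i + 1]
    }
    i <- i + 2
  }
  need <- function(keys) {
    miss <- setdiff(keys, names(opts)[!vapply(opts, function(x)
      length(x) == 0, logical(1))])
    if (length(miss) > 0) {
      message("missing required flag(s): ",
              paste0("--", miss, collapse = " "), "\n", usage)
      TRUE
    } else FALSE
  }
  thresholds <- if (length(opts$threshold) > 0)
    as.numeric(opts$threshold) else c(5e-8, 5e-7, 5e-6, 5e-5, 5e-4)

  if (cmd == "simulate") {
    if (need(c("preset", "seed", "out"))) return(invisible(2L))
    scenario <- switch(opts$preset,
                       "masked-pair" = preset_masked_pair(as.integer(opts$seed)),
                       "chain" = preset_chain(as.integer(opts$seed)),
                       { message("unknown preset: ", opts$preset)
                         return(invisible(2L)) })
    sim <- simulate_study(scenario)
    write_sim_bundle(sim, opts$out)
    message("wrote simulation bundle to ", opts$out)
    return(invisible(0L))
  }
  load_inputs <- function() {
    panel <- read_traw(opts$panel)
    list(sumstats = read_ma(opts$sumstats), panel = panel,
         regions = read_regions(opts$regions))
  }
  if (cmd == "discover") {
    if (need(c("sumstats", "panel", "regions", "out"))) return(invisible(2L))
    inp <- load_inputs()
    run_discovery(inp$sumstats, inp$panel, inp$regions, thresholds,
                  out_dir = opts$out)
    message("discovery written to ", opts$out)
    return(invisible(0L))
  }
  if (cmd == "validate") {
    if (need(c("sumstats", "panel", "regions", "val-panel", "pheno",
               "out"))) return(invisible(2L))
    inp <- load_inputs()
    disc <- run_discovery(inp$sumstats, inp$panel, inp$regions, thresholds)
    val_panel <- read_traw(opts[["val-panel"]])
    pheno <- utils::read.table(opts$pheno, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    rep <- run_validation(disc, inp$sumstats, val_panel, pheno)
    write_prediction_report(rep, opts$out)
    message("validation report written to ", opts$out)
    return(invisible(0L))
  }
  message("unknown command: ", cmd, "\n", usage)
  invisible(2L)
}
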