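#' End-to-end analysis pipeline
#'
#' Runs the full workflow on a simulated cohort: simulate -> QC (call
#' rate, IBD relatedness, PCA) -> GWAS (binomial and multinomial) ->
#' LD-aware instrument selection with common-tag replacement ->
#' classifier evaluation -> one-sample MR, writing every intermediate
#' table as TSV plus a parameter log under `out_dir`. All randomness
#' derives from the config's root seed via fixed per-stage offsets, so a
#' rerun with the same config is byte-identical on all numeric tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate","qc","gwas","select","evaluate","mr")`; later stages
#'   reuse in-memory results of earlier ones, so dropping a stage drops
#'   its outputs only.
#' @param k_pcs PCs for structure adjustment (default 10).
#' @param alpha genome-wide screening threshold.
#' @param r2_threshold,high_r2,low_r2 LD selection thresholds.
#' @param ridge classifier penalty.
#' @param mr_contrast,mr_outcome one-sample MR exposure contrast and
#'   outcome trait.
#' @return Invisibly, a list with the main in-memory artifacts: `cohort`,
#'   `qc`, `scan_binomial`, `scan_multinomial`, `selection`, `evaluation`,
#'   `mr`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "abokit_out",
                         stages = c("simulate", "qc", "gwas", "select",
                                    "evaluate", "mr"),
                         k_pcs = 10, alpha = 5e-8, r2_threshold = 0.8,
                         high_r2 = 0.9, low_r2 = 0.8, ridge = 1e-4,
                         mr_contrast = "B-vs-nonB", mr_outcome = "sbp") {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline_log.txt")
  log_line <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                     file = logf, append = TRUE)
  cat(sprintf("abokit pipeline\nroot seed: %d\n", config$rng_seed), file = logf)
  log_line("parameters: k_pcs=%d alpha=%g r2_threshold=%g high_r2=%g low_r2=%g ridge=%g",
           k_pcs, alpha, r2_threshold, high_r2, low_r2, ridge)
  log_line("config: n_samples=%d typing_error_rate=%g n_null_snps=%d dup_pairs=%d sib_pairs=%d",
           config$n_samples, config$typing_error_rate, config$n_null_snps,
           config$n_duplicate_pairs, config$n_sib_pairs)
  out <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_abokit("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- stage("simulate", simulate_cohort(config))
  out$cohort <- cohort
  if ("simulate" %in% stages) {
    write_vcf(cohort$genotypes, file.path(out_dir, "genotypes.vcf"))
    write_phenotypes(cohort$samples, file.path(out_dir, "phenotypes.tsv"))
    write_truth_tables(cohort, out_dir)
    write_sim_config(config, file.path(out_dir, "sim_config.txt"))
    log_line("simulate: %d samples, %d SNPs", nrow(cohort$samples),
             ncol(cohort$genotypes$dosage))
  }

  qc <- stage("qc", qc_cohort(cohort))
  pcs <- stage("qc", {
    null_ids <- qc$geno$snp_info$snp_id[qc$geno$snp_info$chrom != "9"]
    compute_pcs(subset_geno(qc$geno, snps = null_ids),
                k = min(k_pcs, length(null_ids), nrow(qc$samples)))
  })
  out$qc <- qc; out$pcs <- pcs
  if ("qc" %in% stages) {
    data.table::fwrite(qc$report$dropped, file.path(out_dir, "qc_dropped.tsv"),
                       sep = "\t")
    data.table::fwrite(
      data.frame(metric = c("n_input", "n_dropped_callrate",
                            "n_dropped_relatedness", "n_retained"),
                 value = c(qc$report$n_input, qc$report$n_dropped_callrate,
                           qc$report$n_dropped_relatedness,
                           qc$report$n_retained)),
      file.path(out_dir, "qc_report.tsv"), sep = "\t")
    data.table::fwrite(cbind(sample_id = rownames(pcs$scores),
                             as.data.frame(pcs$scores)),
                       file.path(out_dir, "pc_scores.tsv"), sep = "\t")
    log_line("qc: retained %d of %d samples", qc$report$n_retained,
             qc$report$n_input)
  }

  if (!any(c("gwas", "select", "evaluate", "mr") %in% stages)) {
    return(invisible(out))
  }
  scan_bin <- stage("gwas", run_scan(qc$geno, qc$samples, "binomial",
                                     pcs = pcs$scores))
  scan_multi <- stage("gwas", run_scan(qc$geno, qc$samples, "multinomial",
                                       pcs = pcs$scores))
  out$scan_binomial <- scan_bin; out$scan_multinomial <- scan_multi
  if ("gwas" %in% stages) {
    data.table::fwrite(scan_bin, file.path(out_dir, "gwas_binomial.tsv"),
                       sep = "\t")
    data.table::fwrite(scan_multi, file.path(out_dir, "gwas_multinomial.tsv"),
                       sep = "\t")
    log_line("gwas: %d binomial rows, %d multinomial rows",
             nrow(scan_bin), nrow(scan_multi))
  }

  if (!any(c("select", "evaluate", "mr") %in% stages)) return(invisible(out))
  selection <- stage("select",
                     select_instruments(scan_bin, qc$geno, alpha = alpha,
                                        r2_threshold = r2_threshold,
                                        high_r2 = high_r2, low_r2 = low_r2))
  out$selection <- selection
  if ("select" %in% stages) {
    writeLines(selection$selected, file.path(out_dir, "selected_snps.txt"))
    if (!is.null(selection$ld)) {
      ld_df <- as.data.frame(as.table(unclass(selection$ld)))
      names(ld_df) <- c("snp_a", "snp_b", "r2")
      data.table::fwrite(ld_df[ld_df$snp_a != ld_df$snp_b, ],
                         file.path(out_dir, "ld_table.tsv"), sep = "\t")
    }
    log_line("select: %d SNPs {%s}", length(selection$selected),
             paste(selection$selected, collapse = ", "))
  }

  if ("evaluate" %in% stages && length(selection$selected)) {
    evaluation <- stage("evaluate",
                        evaluate_snp_set(qc$geno, qc$samples,
                                         selection$selected, ridge = ridge))
    out$evaluation <- evaluation
    data.table::fwrite(evaluation$binary,
                       file.path(out_dir, "binary_metrics.tsv"), sep = "\t")
    data.table::fwrite(evaluation$report$per_type,
                       file.path(out_dir, "per_type_metrics.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(evaluation$report$confusion),
                       file.path(out_dir, "confusion_matrix.tsv"), sep = "\t")
    coded <- code_additive(subset_geno(qc$geno, snps = selection$selected))
    keep <- stats::complete.cases(coded$dosage)
    data.table::fwrite(
      probability_pattern_table(evaluation$model,
                                coded$dosage[keep, , drop = FALSE]),
      file.path(out_dir, "probability_patterns.tsv"), sep = "\t")
    log_line("evaluate: accuracy %.4f, F1 micro %.4f, F1 macro %.4f",
             evaluation$report$accuracy, evaluation$report$f1_micro,
             evaluation$report$f1_macro)
  }

  if ("mr" %in% stages && length(selection$selected)) {
    mr <- stage("mr", one_sample_mr(qc$geno, qc$samples, mr_contrast,
                                    mr_outcome, selection$selected,
                                    boot_seed = derive_seed(config$rng_seed, 99)))
    out$mr <- mr
    mr_tab <- data.frame(
      contrast = mr_contrast, outcome = mr_outcome,
      method = c("IVW", "weighted_median"),
      estimate = c(mr$ivw$estimate,
                   if (is.null(mr$weighted_median)) NA else mr$weighted_median$estimate),
      se = c(mr$ivw$se,
             if (is.null(mr$weighted_median)) NA else mr$weighted_median$se),
      p = c(mr$ivw$p,
            if (is.null(mr$weighted_median)) NA else mr$weighted_median$p),
      n_instruments = mr$ivw$n_instruments)
    data.table::fwrite(mr_tab, file.path(out_dir, "mr_results.tsv"), sep = "\t")
    data.table::fwrite(mr$instruments, file.path(out_dir, "mr_instruments.tsv"),
                       sep = "\t")
    log_line("mr: IVW estimate %.4f (p=%.3g)", mr$ivw$estimate, mr$ivw$p)
  }
  invisible(out)
}
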