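pipeline_defaults <- function() {
  list(
    seed = 1L,
    sim = list(),              # overrides forwarded to sim_config()
    qc = list(min_n_run = 10, motif = "TTTAGGG", terminal_window = 1e4,
              min_copies = 10),
    collapse = list(factor = 1.75),
    sv = list(min_sv_len = 50, dup_overlap = 0.5),
    mine = list(k = NULL, min_expressed_samples = 3, min_value = 1.0,
                replicates = 20),
    sexscan = list(tau_on = 1.0, tau_off = 0.1, tissue = "flower",
                   n_biased = 7, n_unbiased = 50, n_outside = 5)
  )
}

#' Structured configuration for the end-to-end toy pipeline
#'
#' Per-stage parameter blocks with documented defaults. Unknown block or
#' parameter names are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param ... Named blocks (`seed`, `sim`, `qc`, `collapse`, `sv`, `mine`,
#'   `sexscan`) whose entries override the defaults; `sim` entries are
#'   forwarded to [sim_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown pipeline_config block(s): ", paste(bad, collapse = ", ")))
  }
  for (blk in names(over)) {
    if (blk == "seed") {
      cfg$seed <- as.integer(over$seed)
      next
    }
    known <- if (blk == "sim") names(formals(sim_config)) else names(cfg[[blk]])
    bad <- setdiff(names(over[[blk]]), known)
    if (length(bad) > 0) {
      abort(paste0("unknown parameter(s) in block '", blk, "': ",
                   paste(bad, collapse = ", ")))
    }
    cfg[[blk]][names(over[[blk]])] <- over[[blk]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full simulate-and-recover toy pipeline
#'
#' Executes simulate, assembly QC, collapse calling with corrected lengths
#' and sex-candidate ranking, SV classification, coexpression mining and
#' the sex-biased expression scan on one seeded synthetic genome, and
#' scores every stage against the planted truth. With an output directory,
#' the stage tables are written as TSV and the summary as JSON.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional directory for the report bundle.
#' @return A list of class `pipeline_report` with per-stage results and a
#'   named logical vector `checks` of truth-recovery outcomes.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  scfg <- do.call(sim_config, config$sim)
  genome <- simulate_diploid_genome(scfg, seed = seed)
  truth <- genome$truth
  depth <- simulate_depth_track(truth, seed = seed + 1L)
  blocks <- simulate_alignment_blocks(truth)
  expr_sim <- simulate_expression(scfg$expr_spec, seed = seed + 2L)

  # --- assembly QC ----------------------------------------------------
  qc <- do.call(qc_assembly, c(list(bind_rows(genome$hap1, genome$hap2)),
                               config$qc))
  qc_sum <- glance(qc)
  expected_gaps <- truth$gaps |>
    group_by(.data$chrom) |> summarise(n = n(), .groups = "drop")
  qc_gap_ok <- all(qc$n_gaps[match(expected_gaps$chrom, qc$chrom)] ==
                     expected_gaps$n) &&
    sum(qc$n_gaps) == nrow(truth$gaps)
  qc_telo_ok <- all(qc$telomere_left) && all(qc$telomere_right)
  t2t_expected <- setdiff(qc$chrom, unique(truth$gaps$chrom))
  qc_t2t_ok <- setequal(qc$chrom[qc$t2t], t2t_expected)

  # --- collapse + sex candidate --------------------------------------
  baseline <- modal_depth(depth)
  calls <- call_collapsed(depth, baseline, factor = config$collapse$factor)
  col_rec <- collapse_recovery(depth, calls, truth)
  col_rep <- collapse_recovery_replicates(truth, base_seed = seed * 50L,
                                          factor = config$collapse$factor)
  corr_len <- corrected_lengths(truth$chrom_pairs, calls)

  # --- SV classification ---------------------------------------------
  svs <- classify_svs(blocks, min_sv_len = config$sv$min_sv_len,
                      dup_overlap = config$sv$dup_overlap)
  sv_rec <- sv_recovery(svs, truth)
  trans_chroms <- c(svs$tchrom[svs$sv_type == "TRANS"],
                    svs$qchrom[svs$sv_type == "TRANS"])
  trans_pairs <- unique(as.integer(sub("^chr([0-9]+)_h[12]$", "\\1",
                                       trans_chroms)))
  trans_pairs <- setdiff(trans_pairs, truth$sex_pair$pair)
  candidates <- rank_sex_candidates(corr_len, excluded_pairs = trans_pairs)
  sex_ok <- candidates$pair[1] == truth$sex_pair$pair &&
    candidates$w_chrom[1] == truth$sex_pair$chrom_w

  # --- coexpression mining -------------------------------------------
  fit <- mine_candidates(expr_sim$expr, expr_sim$labels, k = config$mine$k,
                         min_expressed_samples = config$mine$min_expressed_samples,
                         min_value = config$mine$min_value)
  mod_rec <- module_recovery(fit, expr_sim)
  # the recovery guarantee is replicate-level; average over seeded reruns
  mod_rep <- module_recovery_replicates(scfg$expr_spec,
                                        n_seeds = config$mine$replicates,
                                        base_seed = seed * 100L,
                                        k = config$mine$k)

  # --- sex-biased expression scan ------------------------------------
  w_region <- tibble(chrom = truth$sex_pair$chrom_w,
                     start = truth$sex_pair$insert_at,
                     end = truth$sex_pair$insert_at + truth$sex_pair$extra_len)
  sx <- config$sexscan
  sex_sim <- simulate_sex_expression(w_region, n_biased = sx$n_biased,
                                     n_unbiased = sx$n_unbiased,
                                     n_outside = sx$n_outside,
                                     seed = seed + 3L)
  biased <- sex_biased_genes(sex_sim$expr, w_region, sex_sim$positions,
                             tau_on = sx$tau_on, tau_off = sx$tau_off,
                             tissue = sx$tissue)
  sex_scan_ok <- setequal(biased$gene, sex_sim$truth$gene) &&
    all(biased$bias[match(sex_sim$truth$gene, biased$gene)] ==
          sex_sim$truth$bias)

  checks <- c(
    qc_gap_counts = qc_gap_ok,
    qc_telomeres = qc_telo_ok,
    qc_t2t = qc_t2t_ok,
    collapse_sensitivity = isTRUE(col_rep$sensitivity >= 0.95),
    collapse_precision = isTRUE(col_rep$precision >= 0.95),
    sv_recall = all(sv_rec$recall >= 0.95, na.rm = TRUE),
    sv_precision = all(sv_rec$precision >= 0.95, na.rm = TRUE),
    sex_pair_recovered = isTRUE(sex_ok),
    module_recall = isTRUE(mod_rep$recall >= 0.9),
    module_precision = isTRUE(mod_rep$precision >= 0.9),
    sex_scan_exact = isTRUE(sex_scan_ok)
  )

  report <- structure(list(
    seed = seed, config = config, truth = truth,
    qc = qc, qc_summary = qc_sum,
    depth_baseline = baseline, collapse_calls = calls,
    collapse_recovery = col_rec, collapse_recovery_replicates = col_rep,
    corrected_lengths = corr_len,
    sex_candidates = candidates,
    sv_calls = svs, sv_recovery = sv_rec, sv_summary = sv_type_summary(svs),
    module_fit = fit, module_recovery = mod_rec,
    module_recovery_replicates = mod_rep,
    sex_biased = biased,
    checks = checks
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    utils::write.table(tbl, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(tidy(report$qc), "qc_per_chromosome.tsv")
  wr(to_report_coords(report$collapse_calls), "collapse_calls.tsv")
  wr(as_tibble(report$corrected_lengths), "corrected_lengths.tsv")
  wr(report$sex_candidates, "sex_candidates.tsv")
  wr(to_report_coords(report$sv_calls), "sv_calls.tsv")
  wr(report$sv_summary, "sv_summary.tsv")
  wr(tidy(report$module_fit), "module_assignments.tsv")
  wr(report$sex_biased, "sex_biased_genes.tsv")
  jsonlite::write_json(
    list(seed = report$seed,
         qc_summary = report$qc_summary,
         depth_baseline = report$depth_baseline,
         collapse_recovery = report$collapse_recovery,
         sv_recovery = report$sv_recovery,
         module_recovery = report$module_recovery,
         module_recovery_replicates = report$module_recovery_replicates,
         checks = as.list(report$checks)),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phasekit pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  chromosomes:", nrow(x$qc), " gaps:", x$qc_summary$gap_count,
      " T2T:", x$qc_summary$n_t2t, "\n")
  cat("  collapse calls:", nrow(x$collapse_calls),
      sprintf(" (sens %.2f, prec %.2f)\n",
              x$collapse_recovery$sensitivity, x$collapse_recovery$precision))
  cat("  SV calls:", nrow(x$sv_calls), "\n")
  cat("  sex-pair candidate: pair", x$sex_candidates$pair[1],
      "(W =", x$sex_candidates$w_chrom[1], ")\n")
  cat("  module:", length(x$module_fit$module$members), "genes;",
      "candidates:", length(x$module_fit$module$candidates), "\n")
  ok <- sum(x$checks); cat("  checks passed:", ok, "/", length(x$checks), "\n")
  if (ok < length(x$checks)) {
    cat("  failing:", paste(names(x$checks)[!x$checks], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method
glance.pipeline_report <- function(x, ...) {
  tibble(
    seed = x$seed,
    n_chrom = nrow(x$qc),
    gap_count = x$qc_summary$gap_count,
    n_t2t = x$qc_summary$n_t2t,
    n_collapse_calls = nrow(x$collapse_calls),
    collapse_sensitivity = x$collapse_recovery$sensitivity,
    collapse_precision = x$collapse_recovery$precision,
    n_sv_calls = nrow(x$sv_calls),
    sex_pair = x$sex_candidates$pair[1],
    module_recall = x$module_recovery$recall,
    module_precision = x$module_recovery$precision,
    n_checks_passed = sum(x$checks),
    n_checks = length(x$checks)
  )
}
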