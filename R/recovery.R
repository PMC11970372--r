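#' Compare SV calls against planted truth
#'
#' Matches calls to planted SVs of the same type on the same chromosome
#' pair requiring reciprocal overlap of at least `min_reciprocal` on the
#' coordinate system the type is anchored in (target side for INV, TRANS
#' and DUP; query side for INS; truth INS rows arise from the planted
#' sex-pair insertion).
#'
#' @param calls SV calls from [classify_svs()].
#' @param truth Truth from [simulate_truth()].
#' @param min_reciprocal Minimum reciprocal overlap fraction.
#' @return A tibble per SV type: `sv_type`, `n_truth`, `n_called`,
#'   `n_matched`, `recall`, `precision`.
#' @export
sv_recovery <- function(calls, truth, min_reciprocal = 0.9) {
  tr <- truth$svs
  types <- sort(unique(c(tr$type, calls$sv_type)))
  reciprocal <- function(s1, e1, s2, e2) {
    ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    len1 <- pmax(e1 - s1, 1)
    len2 <- pmax(e2 - s2, 1)
    pmin(ov / len1, ov / len2)
  }
  purrr::map_dfr(types, function(tp) {
    t_tp <- tr[tr$type == tp, , drop = FALSE]
    c_tp <- calls[calls$sv_type == tp, , drop = FALSE]
    side <- if (tp == "INS") "q" else "t"
    matched_truth <- rep(FALSE, nrow(t_tp))
    matched_call <- rep(FALSE, nrow(c_tp))
    for (i in seq_len(nrow(t_tp))) {
      for (j in seq_len(nrow(c_tp))) {
        if (matched_call[j]) next
        if (side == "t") {
          same <- t_tp$tchrom[i] == c_tp$tchrom[j]
          rec <- reciprocal(t_tp$tstart[i], t_tp$tend[i],
                            c_tp$tstart[j], c_tp$tend[j])
        } else {
          same <- t_tp$qchrom[i] == c_tp$qchrom[j]
          rec <- reciprocal(t_tp$qstart[i], t_tp$qend[i],
                            c_tp$qstart[j], c_tp$qend[j])
        }
        if (same && rec >= min_reciprocal) {
          matched_truth[i] <- TRUE
          matched_call[j] <- TRUE
          break
        }
      }
    }
    tibble(
      sv_type = tp, n_truth = nrow(t_tp), n_called = nrow(c_tp),
      n_matched = sum(matched_truth),
      recall = if (nrow(t_tp) > 0) sum(matched_truth) / nrow(t_tp) else NA_real_,
      precision = if (nrow(c_tp) > 0) sum(matched_call) / nrow(c_tp) else NA_real_
    )
  })
}

#' Window-level sensitivity and precision of collapse calls
#'
#' Flags each depth window by whether it falls inside a collapse call and
#' inside a planted collapsed interval, and scores the agreement.
#'
#' @param windows Depth tibble the calls were made from.
#' @param calls Collapse calls from [call_collapsed()].
#' @param truth Truth carrying the planted `collapse` tibble.
#' @return One-row tibble: `n_true`, `n_called`, `n_hit`, `sensitivity`,
#'   `precision`.
#' @export
collapse_recovery <- function(windows, calls, truth) {
  mid <- (windows$start + windows$end) / 2
  in_set <- function(set) {
    hit <- rep(FALSE, nrow(windows))
    for (j in seq_len(nrow(set))) {
      hit <- hit | (windows$chrom == set$chrom[j] & mid >= set$start[j] &
                      mid < set$end[j])
    }
    hit
  }
  truth_w <- in_set(truth$collapse)
  call_w <- if (nrow(calls) > 0) in_set(calls) else rep(FALSE, nrow(windows))
  tibble(
    n_true = sum(truth_w), n_called = sum(call_w),
    n_hit = sum(truth_w & call_w),
    sensitivity = if (sum(truth_w) > 0) sum(truth_w & call_w) / sum(truth_w) else NA_real_,
    precision = if (sum(call_w) > 0) sum(truth_w & call_w) / sum(call_w) else NA_real_
  )
}

#' Collapse recovery aggregated over seeded replicates
#'
#' Window-level sensitivity and precision are rates; a single toy genome
#' holds only a handful of collapsed windows, so one missed boundary window
#' swings the per-run estimate by several percent. This re-simulates the
#' depth track under `n_seeds` seeds and pools the window counts.
#'
#' @param truth Truth from [simulate_truth()].
#' @param n_seeds Number of depth-track replicates.
#' @param base_seed Replicates use seeds `base_seed + 1:n_seeds`.
#' @param factor Calling threshold, see [call_collapsed()].
#' @return One-row tibble: `n_seeds`, `n_true`, `n_called`, `n_hit`,
#'   `sensitivity`, `precision` (pooled).
#' @export
collapse_recovery_replicates <- function(truth, n_seeds = 20, base_seed = 0,
                                         factor = 1.75) {
  res <- purrr::map_dfr(base_seed + seq_len(n_seeds), function(s) {
    d <- simulate_depth_track(truth, seed = s)
    calls <- call_collapsed(d, modal_depth(d), factor = factor)
    collapse_recovery(d, calls, truth)
  })
  tibble(
    n_seeds = n_seeds, n_true = sum(res$n_true),
    n_called = sum(res$n_called), n_hit = sum(res$n_hit),
    sensitivity = sum(res$n_hit) / sum(res$n_true),
    precision = sum(res$n_hit) / sum(res$n_called)
  )
}

#' Module recovery averaged over seeded replicates
#'
#' The module-recovery guarantee is a property of the procedure, not of one
#' draw: at 40 samples a single replicate's precision fluctuates by a few
#' percent through chance correlations of background genes with the module
#' factor. This runs [simulate_expression()] and [mine_candidates()] over
#' `n_seeds` consecutive seeds and averages recall and precision.
#'
#' @param expr_spec Expression specification, see [simulate_expression()].
#' @param n_seeds Number of replicates.
#' @param base_seed Replicates use seeds `base_seed + 1:n_seeds`.
#' @param k Cluster count forwarded to [mine_candidates()].
#' @return One-row tibble: `n_seeds`, `recall`, `precision` (means).
#' @export
module_recovery_replicates <- function(expr_spec, n_seeds = 20,
                                       base_seed = 0, k = NULL) {
  res <- purrr::map_dfr(base_seed + seq_len(n_seeds), function(s) {
    sim <- simulate_expression(expr_spec, seed = s)
    fit <- mine_candidates(sim$expr, sim$labels, k = k)
    module_recovery(fit, sim)
  })
  tibble(n_seeds = n_seeds, recall = mean(res$recall),
         precision = mean(res$precision))
}

#' Recall and precision of a mined module against planted membership
#'
#' Scores the selected module's family-gene list against the planted
#' module's family genes.
#'
#' @param fit A [mine_candidates()] fit.
#' @param sim Output of [simulate_expression()] (carries the planted
#'   module and family labels).
#' @return One-row tibble: `recall`, `precision`.
#' @export
module_recovery <- function(fit, sim) {
  planted <- intersect(sim$module_genes, sim$labels$family)
  called <- fit$module$candidates
  tibble(
    recall = length(intersect(called, planted)) / length(planted),
    precision = if (length(called) > 0)
      length(intersect(called, planted)) / length(called) else NA_real_
  )
}
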