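#' Modal window depth of a depth track
#'
#' Baseline single-copy depth, estimated as the midpoint of the tallest
#' histogram bin with Freedman–Diaconis bin widths. The mode is robust to
#' the right tail that collapsed (multi-copy) windows create, where a mean
#' would be dragged upward.
#'
#' @param windows Depth tibble (`chrom`, `start`, `end`, `depth`) from
#'   [read_depth_bed()] or [simulate_depth_track()]; at least 10 windows.
#' @return The modal depth (midpoint of the tallest bin).
#' @export
modal_depth <- function(windows) {
  d <- windows$depth
  if (length(d) < 10) abort("need at least 10 windows to estimate modal depth")
  if (all(d == 0)) abort("all window depths are zero")
  bw <- 2 * IQR(d) / length(d)^(1 / 3)
  if (bw <= 0) return(d[1])  # (near-)constant track: the mode is the value
  breaks <- seq(min(d), max(d) + bw, by = bw)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  h$mids[which.max(h$counts)]
}

#' Call collapsed regions from a windowed depth track
#'
#' Windows at or above `factor` times the baseline depth are flagged as
#' collapsed; adjacent flagged windows on one chromosome are merged into a
#' single call. The copy estimate is `round(depth / baseline)` clamped to a
#' minimum of 2, and `extra_len` is the sequence the assembly is missing:
#' `length * (est_copies - 1)`.
#'
#' @param windows Depth tibble (`chrom`, `start`, `end`, `depth`).
#' @param baseline Single-copy depth; default [modal_depth()] of the track.
#' @param factor Calling threshold as a multiple of baseline (> 1). A fully
#'   collapsed 2-copy region sits near 2x; the default 1.75 tolerates noise.
#' @param merge Merge adjacent flagged windows (default TRUE).
#' @return A tibble of collapse calls: `chrom`, `start`, `end`,
#'   `mean_depth`, `est_copies`, `extra_len`.
#' @export
call_collapsed <- function(windows, baseline = modal_depth(windows),
                           factor = 1.75, merge = TRUE) {
  if (baseline <= 0) abort("baseline must be > 0")
  if (factor <= 1) abort("factor must be > 1")
  w <- arrange(windows, .data$chrom, .data$start)
  w$flag <- w$depth >= factor * baseline
  flagged <- w[w$flag, , drop = FALSE]
  if (nrow(flagged) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  mean_depth = numeric(), est_copies = integer(),
                  extra_len = numeric()))
  }
  if (merge) {
    flagged <- flagged |>
      group_by(.data$chrom) |>
      mutate(run = cumsum(c(TRUE, .data$start[-1] != .data$end[-n()]))) |>
      group_by(.data$chrom, .data$run)
  } else {
    flagged <- flagged |> group_by(.data$chrom, .data$start)
  }
  calls <- flagged |>
    summarise(start = min(.data$start), end = max(.data$end),
              mean_depth = mean(.data$depth), .groups = "drop") |>
    select("chrom", "start", "end", "mean_depth") |>
    arrange(.data$chrom, .data$start)
  calls$est_copies <- pmax(2L, as.integer(round_half_up(calls$mean_depth / baseline)))
  calls$extra_len <- (calls$end - calls$start) * (calls$est_copies - 1)
  calls
}

#' Genome collapse rate
#'
#' Percent of the assembly lying inside collapse calls.
#'
#' @param calls Collapse-call tibble from [call_collapsed()] (or any tibble
#'   with `start`/`end`), or a single total collapsed length in bp.
#' @param genome_len Assembly length (bp, > 0).
#' @return Percent (full precision; reports round to 2 decimals).
#' @export
collapse_rate <- function(calls, genome_len) {
  if (genome_len <= 0) abort("genome_len must be > 0")
  collapsed <- if (is.data.frame(calls)) sum(calls$end - calls$start) else calls
  100 * collapsed / genome_len
}

#' Collapse-corrected chromosome lengths and haplotype length differences
#'
#' For every chromosome pair, the predicted true length is the assembled
#' length plus the extra (missing) length implied by its collapse calls.
#' The haplotype difference is computed on corrected lengths; each percent
#' difference uses that haplotype's own corrected length as denominator.
#'
#' @param chrom_pairs Tibble `(pair, chrom_h1, chrom_h2, len_h1, len_h2)`
#'   of assembled lengths (e.g. `truth$chrom_pairs`, or built from FASTA).
#' @param calls Collapse calls from [call_collapsed()]; chromosome names
#'   must match `chrom_h1`/`chrom_h2`.
#' @return A tibble of class `corrected_lengths`: one row per pair with
#'   assembled, extra and corrected lengths, `diff_bp`, `diff_pct_1`,
#'   `diff_pct_2`.
#' @export
corrected_lengths <- function(chrom_pairs, calls) {
  known <- c(chrom_pairs$chrom_h1, chrom_pairs$chrom_h2)
  if (nrow(calls) > 0 && !all(calls$chrom %in% known)) {
    abort(paste0("collapse call on unknown chromosome: ",
                 paste(setdiff(calls$chrom, known), collapse = ", ")))
  }
  extra <- calls |>
    group_by(.data$chrom) |>
    summarise(extra = sum(.data$extra_len), .groups = "drop")
  get_extra <- function(ch) {
    i <- match(ch, extra$chrom)
    ifelse(is.na(i), 0, extra$extra[i])
  }
  out <- chrom_pairs |>
    mutate(
      extra_1 = get_extra(.data$chrom_h1),
      extra_2 = get_extra(.data$chrom_h2),
      corrected_1 = .data$len_h1 + .data$extra_1,
      corrected_2 = .data$len_h2 + .data$extra_2,
      diff_bp = abs(.data$corrected_1 - .data$corrected_2),
      diff_pct_1 = 100 * .data$diff_bp / .data$corrected_1,
      diff_pct_2 = 100 * .data$diff_bp / .data$corrected_2
    )
  structure(out, class = c("corrected_lengths", class(out)))
}

#' Rank chromosome pairs as sex-chromosome candidates
#'
#' In a ZW system assembled from a female, the sex pair shows the largest
#' corrected-length difference between haplotypes once pairs whose
#' difference is explained by interchromosomal translocations are set
#' aside. Rows are ranked by percent difference (descending; ties broken by
#' pair id); in the top-ranked pair the longer haplotype is labelled W and
#' the shorter Z.
#'
#' @param rows A [corrected_lengths()] tibble.
#' @param excluded_pairs Pair ids to exclude (e.g. pairs carrying
#'   translocations, from [classify_svs()] calls).
#' @return The non-excluded rows sorted by `diff_pct` descending, with
#'   `rank`, `w_chrom` and `z_chrom` columns.
#' @export
rank_sex_candidates <- function(rows, excluded_pairs = integer(0)) {
  if (!all(excluded_pairs %in% rows$pair)) {
    abort("excluded_pairs contains unknown pair ids")
  }
  kept <- rows[!(rows$pair %in% excluded_pairs), , drop = FALSE]
  if (nrow(kept) == 0) abort("all chromosome pairs excluded")
  kept$diff_pct <- pmax(kept$diff_pct_1, kept$diff_pct_2)
  kept <- arrange(kept, desc(.data$diff_pct), .data$pair)
  kept$rank <- seq_len(nrow(kept))
  kept$w_chrom <- ifelse(kept$corrected_2 >= kept$corrected_1,
                         kept$chrom_h2, kept$chrom_h1)
  kept$z_chrom <- ifelse(kept$corrected_2 >= kept$corrected_1,
                         kept$chrom_h1, kept$chrom_h2)
  as_tibble(kept)
}

#' Plot a depth track with collapse calls
#'
#' @param windows Depth tibble.
#' @param calls Optional collapse calls from [call_collapsed()].
#' @param baseline Optional baseline depth drawn as a dashed line.
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_depth_track <- function(windows, calls = NULL, baseline = NULL) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "window depth (x)") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.25
    )
  }
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, linetype = "dashed")
  }
  p
}
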