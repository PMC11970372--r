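#' Scan a sequence for assembly gaps (N-runs)
#'
#' A gap is a maximal run of `N` of length at least `min_n_run`; the number
#' of such runs is the chromosome's gap count. Single ambiguous bases below
#' the threshold are not counted.
#'
#' @param sequence A character scalar (upper-case handled; lower case is
#'   tolerated).
#' @param min_n_run Minimum N-run length to call a gap (>= 1).
#' @return A tibble of gap intervals (`start`, `end`; 0-based half-open),
#'   sorted, disjoint.
#' @export
scan_gaps <- function(sequence, min_n_run = 10) {
  stopifnot(length(sequence) == 1, min_n_run >= 1)
  if (nchar(sequence) == 0) return(tibble(start = numeric(), end = numeric()))
  m <- gregexpr(paste0("N{", min_n_run, ",}"), toupper(sequence))[[1]]
  if (m[1] == -1) return(tibble(start = numeric(), end = numeric()))
  start <- as.numeric(m) - 1
  tibble(start = start, end = start + attr(m, "match.length"))
}

#' NX curve of a set of contig lengths
#'
#' NX is the length of the contig at which the cumulative sum of
#' descending-sorted lengths first reaches X% of the total — the convention
#' of common assembly-statistics tools. The curve is permutation-invariant
#' and non-increasing in X.
#'
#' @param contig_lengths Numeric vector of contig lengths (> 0).
#' @param fractions Integer percentages, default N10 through N90.
#' @return A tibble (`fraction`, `nx`).
#' @export
nx_curve <- function(contig_lengths, fractions = seq(10, 90, by = 10)) {
  if (length(contig_lengths) == 0) abort("empty contig length list")
  if (any(contig_lengths <= 0)) abort("contig lengths must be > 0")
  len <- sort(contig_lengths, decreasing = TRUE)
  cum <- cumsum(len)
  total <- cum[length(cum)]
  nx <- vapply(fractions, function(x) {
    len[which(cum >= x / 100 * total)[1]]
  }, numeric(1))
  tibble(fraction = fractions, nx = nx)
}

#' N50 of a set of contig lengths
#' @inheritParams nx_curve
#' @return The N50 length (bp).
#' @export
n50 <- function(contig_lengths) nx_curve(contig_lengths, 50)$nx

#' Detect telomeric repeat arrays at chromosome ends
#'
#' An end is telomeric when at least `min_copies` occurrences of the repeat
#' motif — or of its reverse complement, so that both strand orientations
#' are recognised — fall within the terminal window.
#'
#' @param sequence A character scalar.
#' @param motif Telomeric repeat unit (default the plant motif `TTTAGGG`).
#' @param terminal_window Window at each end to search (bp); must be at
#'   least the motif length.
#' @param min_copies Minimum motif occurrences to call an end telomeric.
#' @return A list with logical elements `left` and `right`.
#' @export
telomere_scan <- function(sequence, motif = "TTTAGGG",
                          terminal_window = 1e4, min_copies = 10) {
  stopifnot(length(sequence) == 1, nchar(motif) >= 1)
  if (terminal_window < nchar(motif)) {
    abort("terminal_window smaller than the motif")
  }
  s <- toupper(sequence)
  n <- nchar(s)
  w <- min(terminal_window, n)
  count_hits <- function(x) {
    hits <- 0
    for (m in unique(c(motif, revcomp(motif)))) {
      g <- gregexpr(m, x, fixed = TRUE)[[1]]
      if (g[1] != -1) hits <- hits + length(g)
    }
    hits
  }
  list(
    left = count_hits(substr(s, 1, w)) >= min_copies,
    right = count_hits(substr(s, n - w + 1, n)) >= min_copies
  )
}

#' Telomere-to-telomere status of a chromosome record
#'
#' A chromosome is T2T when it carries telomere arrays at both ends and has
#' zero gaps.
#'
#' @param record A one-row tibble (or list) with logical `telomere_left`,
#'   `telomere_right` and numeric `n_gaps`.
#' @return Logical.
#' @export
t2t_status <- function(record) {
  isTRUE(record$telomere_left) && isTRUE(record$telomere_right) &&
    record$n_gaps == 0
}

#' Convert a Phred-scaled consensus quality value to errors per Mbp
#'
#' `QV = -10 log10(error rate)`, so errors per Mbp is
#' `10^(-QV/10) * 1e6`: QV 60 is exactly 1 error per Mbp.
#'
#' @param qv Phred-scaled consensus quality (> 0, finite).
#' @return Expected base errors per Mbp.
#' @export
qv_to_errors_per_mbp <- function(qv) {
  if (any(!is.finite(qv)) || any(qv <= 0)) abort("qv must be finite and > 0")
  10^(-qv / 10) * 1e6
}

#' Anchoring rate of an assembly
#'
#' Percentage of the total assembly placed onto chromosomes.
#'
#' @param anchored_len Anchored length (bp), `0 <= anchored_len <= total_len`.
#' @param total_len Total assembly length (bp, > 0).
#' @return Percent (full precision; reports round to 1 decimal).
#' @export
anchoring_rate <- function(anchored_len, total_len) {
  if (total_len <= 0) abort("total_len must be > 0")
  if (anchored_len < 0 || anchored_len > total_len) {
    abort("need 0 <= anchored_len <= total_len")
  }
  100 * anchored_len / total_len
}

#' Ratio of two contig N50 values
#'
#' @param n50_a,n50_b N50 lengths (> 0), same units.
#' @return `n50_a / n50_b` rounded half-up to 1 decimal.
#' @export
n50_ratio <- function(n50_a, n50_b) {
  if (any(c(n50_a, n50_b) <= 0)) abort("N50 values must be > 0")
  round_half_up(n50_a / n50_b, 1)
}

#' Percent of the genome in a nested fraction
#'
#' Composes two percentages: e.g. if repeats are 84% of the genome and a
#' repeat class is 69% of repeats, that class is 58% of the genome.
#'
#' @param outer_pct,inner_pct Percentages in `[0, 100]`.
#' @return `outer_pct * inner_pct / 100` (percent of the whole).
#' @export
nested_percent <- function(outer_pct, inner_pct) {
  outer_pct * inner_pct / 100
}

#' Per-chromosome and whole-assembly QC of a haplotype assembly
#'
#' Runs gap scanning, telomere detection and T2T calling over every
#' chromosome record and aggregates assembly totals.
#'
#' @param records Tibble from [read_fasta()] (columns `id`, `seq`).
#' @param min_n_run Gap threshold, see [scan_gaps()].
#' @param motif,terminal_window,min_copies See [telomere_scan()].
#' @return A tibble of class `assembly_qc`: one row per chromosome with
#'   `chrom`, `length`, `n_gaps`, `gap_len`, `telomere_left`,
#'   `telomere_right`, `t2t`. Assembly totals are available via
#'   [glance.assembly_qc()].
#' @export
qc_assembly <- function(records, min_n_run = 10, motif = "TTTAGGG",
                        terminal_window = 1e4, min_copies = 10) {
  rows <- purrr::pmap_dfr(list(records$id, records$seq), function(id, seq) {
    gaps <- scan_gaps(seq, min_n_run)
    tel <- telomere_scan(seq, motif, terminal_window, min_copies)
    tibble(
      chrom = id, length = nchar(seq), n_gaps = nrow(gaps),
      gap_len = sum(gaps$end - gaps$start),
      telomere_left = tel$left, telomere_right = tel$right
    )
  })
  rows$t2t <- rows$telomere_left & rows$telomere_right & rows$n_gaps == 0
  structure(rows, class = c("assembly_qc", class(rows)))
}

#' @exportS3Method
glance.assembly_qc <- function(x, ...) {
  tibble(
    n_chrom = nrow(x),
    total_len = sum(x$length),
    gap_count = sum(x$n_gaps),
    gap_len = sum(x$gap_len),
    n_telomeres = sum(x$telomere_left) + sum(x$telomere_right),
    n_t2t = sum(x$t2t)
  )
}

#' @exportS3Method
tidy.assembly_qc <- function(x, ...) {
  as_tibble(x)
}

#' Plot an NX curve
#'
#' @param nx A tibble from [nx_curve()], or a named list of such tibbles to
#'   compare assemblies.
#' @return A ggplot object.
#' @export
plot_nx_curve <- function(nx) {
  if (is.data.frame(nx)) nx <- list(assembly = nx)
  df <- purrr::imap_dfr(nx, ~ mutate(.x, assembly = .y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$nx,
                                   colour = .data$assembly)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "NX fraction (%)", y = "contig length (bp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
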