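# Brute-force oracles, deliberately independent of the package internals.

# character-by-character N-run scanner
oracle_scan_gaps <- function(sequence, min_n_run) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  runs <- rle(chars == "N")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values & runs$lengths >= min_n_run
  data.frame(start = starts[keep], end = ends[keep])
}

# sliding-window motif counter (fixed-string, non-overlapping like gregexpr)
oracle_count_motif <- function(x, motif) {
  n <- 0L
  i <- 1L
  while (i <= nchar(x) - nchar(motif) + 1L) {
    if (substr(x, i, i + nchar(motif) - 1L) == motif) {
      n <- n + 1L
      i <- i + nchar(motif)
    } else {
      i <- i + 1L
    }
  }
  n
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

# two-pass covariance Pearson correlation
oracle_correlation <- function(m) {
  n <- nrow(m)
  r <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      xi <- m[i, ] - mean(m[i, ])
      xj <- m[j, ] - mean(m[j, ])
      r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

# per-base bitmap coverage of a region by intervals
oracle_uncovered_bp <- function(region_start, region_end, starts, ends) {
  bitmap <- rep(FALSE, region_end - region_start)
  for (k in seq_along(starts)) {
    s <- max(starts[k], region_start)
    e <- min(ends[k], region_end)
    if (e > s) bitmap[(s - region_start + 1):(e - region_start)] <- TRUE
  }
  sum(!bitmap)
}

random_string <- function(n, alphabet = c("A", "C", "G", "T", "N")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small, fast simulation config shared across tests
toy_config <- function(...) {
  sim_config(...)
}

# wrap a numeric matrix as a gene-by-sample expression tibble
mk_expr <- function(m, genes = paste0("g", seq_len(nrow(m)))) {
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}
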