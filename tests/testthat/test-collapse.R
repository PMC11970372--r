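mk_windows <- function(depths, chrom = "c1", window = 1e4) {
  tibble::tibble(chrom = chrom,
                 start = (seq_along(depths) - 1) * window,
                 end = seq_along(depths) * window,
                 depth = depths)
}

test_that("modal depth finds the dominant mixture component", {
  expect_equal(modal_depth(mk_windows(rep(30, 50))), 30)
  withr::local_seed(8)
  d <- c(rnorm(900, 30, 2), rnorm(100, 60, 3))
  w <- mk_windows(d)
  expect_lt(abs(modal_depth(w) - 30), 2)
  expect_equal(modal_depth(w), modal_depth(mk_windows(rev(d))))
  expect_error(modal_depth(mk_windows(rep(0, 20))), "zero")
  expect_error(modal_depth(mk_windows(rep(30, 5))), "at least 10")
})

test_that("collapse calling flags, merges and estimates copies", {
  flat <- mk_windows(rep(30, 40))
  expect_equal(nrow(call_collapsed(flat, baseline = 30)), 0L)

  d <- rep(30, 40)
  d[11:13] <- 60
  calls <- call_collapsed(mk_windows(d), baseline = 30)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 10 * 1e4)
  expect_equal(calls$end, 13 * 1e4)
  expect_equal(calls$est_copies, 2L)
  expect_equal(calls$extra_len, 3 * 1e4)

  # boundary: a window at exactly factor x baseline is included
  d <- rep(30, 40)
  d[5] <- 1.75 * 30
  calls <- call_collapsed(mk_windows(d), baseline = 30)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 4 * 1e4)
  expect_equal(calls$est_copies, 2L)  # clamped to >= 2

  # non-adjacent flagged windows stay separate calls
  d <- rep(30, 40)
  d[c(5, 20)] <- 60
  expect_equal(nrow(call_collapsed(mk_windows(d), baseline = 30)), 2L)
  expect_error(call_collapsed(flat, baseline = 30, factor = 1), "factor")
})

test_that("collapse rate and extra length satisfy the accounting identity", {
  expect_equal(collapse_rate(218e6, 20348291365), 100 * 218e6 / 20348291365)
  d <- rep(30, 100)
  d[41:45] <- 60  # 2-copy: extra equals called length
  w <- mk_windows(d)
  calls <- call_collapsed(w, baseline = 30)
  rate <- collapse_rate(calls, sum(w$end - w$start))
  expect_equal(sum(calls$extra_len), rate * sum(w$end - w$start) / 100)
  expect_equal(collapse_rate(tibble::tibble(start = numeric(), end = numeric()),
                             100), 0)
})

test_that("corrected lengths close the gap a collapse explains", {
  pairs <- tibble::tibble(pair = 1L, chrom_h1 = "c1_h1", chrom_h2 = "c1_h2",
                          len_h1 = 1.0e6, len_h2 = 1.1e6)
  no_calls <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), mean_depth = numeric(),
                             est_copies = integer(), extra_len = numeric())
  rows <- corrected_lengths(pairs, no_calls)
  expect_equal(rows$corrected_1, 1.0e6)
  expect_equal(rows$diff_bp, 1e5)

  one_call <- tibble::tibble(chrom = "c1_h1", start = 2e5, end = 3e5,
                             mean_depth = 60, est_copies = 2L, extra_len = 1e5)
  rows <- corrected_lengths(pairs, one_call)
  expect_equal(rows$corrected_1, 1.1e6)
  expect_equal(rows$diff_bp, 0)
  expect_equal(rows$diff_pct_1, 0)

  # each haplotype's own corrected length is the denominator
  pairs2 <- tibble::tibble(pair = 1L, chrom_h1 = "c1_h1", chrom_h2 = "c1_h2",
                           len_h1 = 4.2e8, len_h2 = 4.127e8)
  rows2 <- corrected_lengths(pairs2, no_calls)
  expect_false(rows2$diff_pct_1 == rows2$diff_pct_2)
  expect_equal(rows2$diff_pct_1, 100 * rows2$diff_bp / rows2$corrected_1)
  expect_error(corrected_lengths(pairs, dplyr::mutate(one_call, chrom = "zz")),
               "unknown chromosome")
})

test_that("sex-candidate ranking recovers the planted pair and honours exclusions", {
  pairs <- tibble::tibble(
    pair = 1:4,
    chrom_h1 = paste0("chr", 1:4, "_h1"), chrom_h2 = paste0("chr", 1:4, "_h2"),
    len_h1 = rep(4.2e8, 4),
    len_h2 = c(4.2e8, 4.2e8, 4.5e8, 4.27e8)  # pair 3 translocation, pair 4 sex
  )
  no_calls <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), mean_depth = numeric(),
                             est_copies = integer(), extra_len = numeric())
  rows <- corrected_lengths(pairs, no_calls)
  ranked <- rank_sex_candidates(rows, excluded_pairs = 3L)
  expect_equal(ranked$pair[1], 4L)
  expect_equal(ranked$w_chrom[1], "chr4_h2")
  expect_equal(ranked$z_chrom[1], "chr4_h1")
  expect_false(3L %in% ranked$pair)

  # identical haplotypes: all-zero differences, stable tie-break by pair id
  flat <- corrected_lengths(dplyr::mutate(pairs, len_h2 = len_h1), no_calls)
  ranked <- rank_sex_candidates(flat)
  expect_equal(ranked$pair, 1:4)
  expect_error(rank_sex_candidates(rows, excluded_pairs = 1:4), "excluded")
  expect_error(rank_sex_candidates(rows, excluded_pairs = 9L), "unknown")
})

test_that("collapse calling recovers planted intervals from simulated depth", {
  truth <- simulate_truth(toy_config())
  d <- simulate_depth_track(truth, noise_sd = 0, seed = 1)
  calls <- call_collapsed(d, modal_depth(d))
  rec <- collapse_recovery(d, calls, truth)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$precision, 1)
  # noise-free calls align exactly with the planted intervals
  got <- dplyr::arrange(calls[, c("chrom", "start", "end")], chrom, start)
  want <- dplyr::arrange(truth$collapse[, c("chrom", "start", "end")],
                         chrom, start)
  expect_equal(as.data.frame(got), as.data.frame(want))
  expect_equal(sort(calls$est_copies), sort(truth$collapse$copies))
})
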