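empty_svs <- tibble::tibble(type = character(), pair = integer(),
                            start = numeric(), length = numeric(),
                            dest_pair = integer())
empty_gaps <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric())
empty_collapse <- tibble::tibble(chrom = character(), start = numeric(),
                                 end = numeric(), copies = integer())

small_cfg <- function(extra_len = 5e3, sv_spec = empty_svs) {
  sim_config(n_chrom = 2, chrom_len = 1e5, telomere_copies = 20,
             gap_spec = empty_gaps, sv_spec = sv_spec,
             collapse_spec = empty_collapse,
             sex_pair = list(pair = 2, extra_len = extra_len,
                             insert_at = 2e3),
             window = 1e3)
}

test_that("without SVs the haplotypes differ only by the sex-pair insertion", {
  g <- simulate_diploid_genome(small_cfg(), seed = 3)
  expect_identical(g$hap2$seq[1], g$hap1$seq[1])
  h1 <- g$hap1$seq[2]
  h2 <- g$hap2$seq[2]
  sp <- g$truth$sex_pair
  expect_equal(nchar(h2), nchar(h1) + sp$extra_len)
  expect_identical(substr(h2, 1, sp$insert_at), substr(h1, 1, sp$insert_at))
  expect_identical(substr(h2, sp$insert_at + sp$extra_len + 1, nchar(h2)),
                   substr(h1, sp$insert_at + 1, nchar(h1)))
})

test_that("planted inversions are exact reverse complements at truth coordinates", {
  g <- simulate_diploid_genome(toy_config(), seed = 5)
  inv <- dplyr::filter(g$truth$svs, type == "INV")
  expect_gt(nrow(inv), 0)
  for (i in seq_len(nrow(inv))) {
    src <- substr(g$hap1$seq[g$hap1$id == inv$tchrom[i]],
                  inv$tstart[i] + 1, inv$tend[i])
    dst <- substr(g$hap2$seq[g$hap2$id == inv$qchrom[i]],
                  inv$qstart[i] + 1, inv$qend[i])
    expect_identical(dst, oracle_revcomp(src))
  }
})

test_that("genome simulation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- simulate_diploid_genome(cfg, seed = 11)
  b <- simulate_diploid_genome(cfg, seed = 11)
  expect_identical(a$hap1$seq, b$hap1$seq)
  expect_identical(a$hap2$seq, b$hap2$seq)
  c <- simulate_diploid_genome(cfg, seed = 12)
  expect_false(identical(a$hap1$seq, c$hap1$seq))
})

test_that("generator refuses overlapping planted SVs", {
  sv <- tibble::tibble(type = c("INV", "DUP"), pair = c(1L, 1L),
                       start = c(5e4, 5.2e4), length = c(5e3, 5e3),
                       dest_pair = c(NA_integer_, NA_integer_))
  expect_error(sim_config(n_chrom = 2, chrom_len = 1e5, sv_spec = sv,
                          gap_spec = empty_gaps,
                          collapse_spec = empty_collapse,
                          sex_pair = list(pair = 2, extra_len = 0,
                                          insert_at = 1e3)),
               "overlap")
})

test_that("noise-free depth tracks hit the exact expected depth", {
  cfg <- toy_config()
  truth <- simulate_truth(cfg)
  d <- simulate_depth_track(truth, noise_sd = 0, seed = 1)
  mid <- (d$start + d$end) / 2
  in_collapse <- rep(FALSE, nrow(d))
  copies <- rep(1, nrow(d))
  for (j in seq_len(nrow(truth$collapse))) {
    hit <- d$chrom == truth$collapse$chrom[j] &
      mid >= truth$collapse$start[j] & mid < truth$collapse$end[j]
    in_collapse <- in_collapse | hit
    copies[hit] <- truth$collapse$copies[j]
  }
  expect_true(all(d$depth[!in_collapse] == cfg$mean_depth))
  expect_true(all(d$depth[in_collapse] == copies[in_collapse] * cfg$mean_depth))
  expect_error(simulate_depth_track(truth, mean_depth = 0), "mean_depth")
})

test_that("empirical mean depth matches the law of large numbers", {
  truth <- simulate_truth(toy_config())
  d <- simulate_depth_track(truth, seed = 9)
  mid <- (d$start + d$end) / 2
  in_collapse <- rep(FALSE, nrow(d))
  for (j in seq_len(nrow(truth$collapse))) {
    in_collapse <- in_collapse | (d$chrom == truth$collapse$chrom[j] &
                                    mid >= truth$collapse$start[j] &
                                    mid < truth$collapse$end[j])
  }
  x <- d$depth[!in_collapse]
  expect_gt(length(x), 1000)
  se <- truth$params$depth_noise_sd / sqrt(length(x))
  expect_lt(abs(mean(x) - truth$params$mean_depth), 3 * se)
})

test_that("alignment blocks are one clean + block per pair when nothing is planted", {
  truth <- simulate_truth(small_cfg(extra_len = 0))
  b <- simulate_alignment_blocks(truth)
  expect_equal(nrow(b), 2L)
  expect_true(all(b$strand == "+"))
  expect_equal(b$tstart, c(0, 0))
  expect_equal(b$tend, truth$chrom_pairs$len_h1)
  expect_equal(b$qstart, c(0, 0))
  expect_equal(b$qend, truth$chrom_pairs$len_h2)
})

test_that("a single planted inversion yields exactly one minus-strand block at truth coordinates", {
  sv <- tibble::tibble(type = "INV", pair = 1L, start = 4e4, length = 5e3,
                       dest_pair = NA_integer_)
  truth <- simulate_truth(small_cfg(extra_len = 0, sv_spec = sv))
  b <- simulate_alignment_blocks(truth)
  minus <- b[b$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$tstart, 4e4)
  expect_equal(minus$tend, 4.5e4)
  expect_equal(minus$qstart, 4e4)
  expect_equal(minus$qend, 4.5e4)
})

test_that("expression module correlation hits the degenerate noise-free limit", {
  es <- list(n_genes = 60, n_samples = 20, k_known = 5, m_family = 10,
             n_family_total = 20, module_corr = 0.9, noise_sd = 0)
  sim <- simulate_expression(es, seed = 2)
  norm <- normalize_expression(sim$expr)
  r <- correlation_matrix(norm, genes = sim$module_genes)
  expect_true(all(r[upper.tri(r)] >= 0.99))
})

test_that("off-module genes sit at the null correlation level", {
  es <- sim_config()$expr_spec
  sim <- simulate_expression(es, seed = 4)
  norm <- normalize_expression(sim$expr)
  bg <- setdiff(norm$gene, sim$module_genes)[1:100]
  r <- correlation_matrix(norm, genes = bg)
  off <- r[upper.tri(r)]
  # null Pearson at n = 40: E|r| = sqrt(2/pi)/sqrt(39) ~ 0.128
  expect_lt(mean(abs(off)), 0.16)
  expect_lt(abs(mean(off)), 0.05)
})

test_that("expression simulation is deterministic and validates module_corr", {
  es <- list(n_genes = 50, n_samples = 10, k_known = 4, m_family = 8,
             n_family_total = 12, module_corr = 0.8, noise_sd = 1)
  a <- simulate_expression(es, seed = 6)
  b <- simulate_expression(es, seed = 6)
  expect_identical(a$expr, b$expr)
  es$module_corr <- 1.2
  expect_error(simulate_expression(es, seed = 1), "module_corr")
})

test_that("random SV specifications are valid and non-overlapping", {
  cfg <- sim_config(n_chrom = 8)
  for (s in 1:5) {
    sv <- random_sv_spec(cfg, seed = s)
    expect_true(all(sv$length >= 500 & sv$length <= 5e4))
    # placing them in a config must not trigger the overlap guard
    cfg2 <- sim_config(n_chrom = 8, sv_spec = sv)
    expect_s3_class(cfg2, "phasekit_sim_config")
    tr <- simulate_truth(cfg2)
    expect_equal(nrow(tr$svs), nrow(sv) + 1L)  # + the sex-pair insertion
  }
})
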