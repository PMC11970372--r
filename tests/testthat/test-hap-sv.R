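mk_blocks <- function(qstart, qend, tstart, tend, strand = "+",
                      qname = "q1", tname = "t1", qlen = 1e6, tlen = 1e6) {
  tibble::tibble(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
                 strand = strand, tname = tname, tlen = tlen,
                 tstart = tstart, tend = tend, nmatch = qend - qstart,
                 alen = qend - qstart, mapq = 60)
}

test_that("syntenic chaining keeps the heaviest collinear subset", {
  one <- chain_syntenic(mk_blocks(0, 100, 0, 100))
  expect_true(one$in_backbone)

  # two crossing blocks: the longer wins, the other is left unchained
  crossing <- mk_blocks(c(300, 0), c(400, 200), c(0, 200), c(100, 400))
  ch <- chain_syntenic(crossing)
  expect_equal(sum(ch$in_backbone), 1L)
  expect_equal(ch$tstart[ch$in_backbone], 200)

  # deterministic under input permutation
  ch2 <- chain_syntenic(crossing[2:1, ])
  expect_identical(as.data.frame(ch), as.data.frame(ch2))
})

test_that("classification recovers planted SV types at truth coordinates", {
  truth <- simulate_truth(toy_config())
  blocks <- simulate_alignment_blocks(truth)
  calls <- classify_svs(blocks)
  rec <- sv_recovery(calls, truth)
  expect_true(all(rec$recall == 1))
  expect_true(all(rec$precision == 1))
  expect_equal(sort(calls$sv_type), sort(truth$svs$type))
  # coordinates are exact, not merely overlapping
  key <- function(x, a, b, c) paste(x[[a]], x[[b]], x[[c]])
  expect_setequal(key(calls, "tchrom", "tstart", "tend")[calls$sv_type != "INS"],
                  key(truth$svs, "tchrom", "tstart", "tend")[truth$svs$type != "INS"])
})

test_that("perfect collinearity yields no SV calls and short events are dropped", {
  clean <- mk_blocks(c(0, 500), c(400, 900), c(0, 500), c(400, 900))
  expect_equal(nrow(classify_svs(clean)), 0L)

  # a 40 bp inversion sits below the (inclusive) 50 bp floor
  with_inv <- dplyr::bind_rows(
    mk_blocks(0, 400, 0, 400),
    mk_blocks(400, 440, 400, 440, strand = "-"),
    mk_blocks(440, 900, 440, 900)
  )
  expect_equal(nrow(classify_svs(with_inv)), 0L)
  # at exactly 50 bp it is called
  with_inv50 <- dplyr::bind_rows(
    mk_blocks(0, 400, 0, 400),
    mk_blocks(400, 450, 400, 450, strand = "-"),
    mk_blocks(450, 900, 450, 900)
  )
  expect_equal(classify_svs(with_inv50)$sv_type, "INV")
})

test_that("classification is invariant to block input order", {
  truth <- simulate_truth(toy_config())
  blocks <- simulate_alignment_blocks(truth)
  calls <- classify_svs(blocks)
  withr::local_seed(3)
  shuffled <- blocks[sample(nrow(blocks)), ]
  expect_identical(as.data.frame(classify_svs(shuffled)),
                   as.data.frame(calls))
})

test_that("one-sided alignment gaps classify as insertion or deletion", {
  # query gap of 200 bp, target contiguous -> INS
  ins <- dplyr::bind_rows(mk_blocks(0, 400, 0, 400),
                          mk_blocks(600, 1000, 400, 800))
  calls <- classify_svs(ins)
  expect_equal(calls$sv_type, "INS")
  expect_equal(calls$qstart, 400)
  expect_equal(calls$qend, 600)
  # target gap of 200 bp, query contiguous -> DEL
  del <- dplyr::bind_rows(mk_blocks(0, 400, 0, 400),
                          mk_blocks(400, 800, 600, 1000))
  expect_equal(classify_svs(del)$sv_type, "DEL")
})

test_that("unaligned fraction matches a per-base bitmap oracle", {
  region <- list(chrom = "q1", start = 0, end = 1e5)
  withr::local_seed(21)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    s <- sort(sample(0:9e4, n))
    e <- pmin(s + sample(1e3:2e4, n, replace = TRUE), 1e5)
    blocks <- mk_blocks(s, e, s, e)
    got <- unaligned_fraction(region, blocks)
    want <- oracle_uncovered_bp(0, 1e5, s, e)
    expect_equal(got$unaligned_bp, want)
    expect_equal(got$percent, 100 * want / 1e5)
  }
  full <- unaligned_fraction(region, mk_blocks(0, 1e5, 0, 1e5))
  expect_equal(full$unaligned_bp, 0)
  expect_equal(full$percent, 0)
  expect_error(unaligned_fraction(list(chrom = "q1", start = 5, end = 5),
                                  mk_blocks(0, 100, 0, 100)), "length")
})

test_that("SV genome fraction is additive over types", {
  truth <- simulate_truth(toy_config())
  calls <- classify_svs(simulate_alignment_blocks(truth))
  total <- sv_genome_fraction(calls, 8e6)
  by_type <- sapply(split(calls, calls$sv_type), sv_genome_fraction,
                    genome_len = 8e6)
  expect_equal(sum(by_type), total)
  expect_equal(sv_genome_fraction(calls[0, ], 8e6), 0)
  expect_equal(sv_genome_fraction(tibble::tibble(length = 134), 1000), 13.4)
})
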