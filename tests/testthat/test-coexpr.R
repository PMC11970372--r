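test_that("normalization log-transforms and filters weakly expressed genes", {
  m <- rbind(c(0, 1, 3, 7),        # expressed in 3 of 4 samples at >= 1
             c(0, 0, 2, 0))        # expressed in 1 of 4
  norm <- normalize_expression(mk_expr(m), min_expressed_samples = 3)
  expect_equal(norm$gene, "g1")
  expect_equal(unlist(norm[1, -1], use.names = FALSE), c(0, 1, 2, 3))
  expect_error(normalize_expression(mk_expr(m), min_expressed_samples = 4),
               "filter")
  # a gene expressed in 2 of 40 samples is dropped at the default threshold
  wide <- matrix(0, 1, 40)
  wide[1, 1:2] <- 5
  expect_error(normalize_expression(mk_expr(wide)), "filter")
})

test_that("correlation matrix matches the brute-force covariance oracle", {
  withr::local_seed(17)
  for (i in 1:5) {
    m <- matrix(rnorm(200), 20, 10)
    r <- correlation_matrix(mk_expr(m))
    expect_equal(unclass(r), oracle_correlation(m),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  hand <- matrix(c(1, 2, 3, 4,
                   4, 3, 2, 1,
                   1, 3, 2, 4), 3, 4, byrow = TRUE)
  r <- correlation_matrix(mk_expr(hand))
  expect_equal(diag(r), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(r[1, 2], -1)
  expect_equal(r, t(r))
  expect_error(correlation_matrix(mk_expr(hand[, 1:2])), "3 samples")
})

test_that("constant-expression genes get r = 0 and are flagged", {
  m <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(4, 3, 2, 1))
  r <- correlation_matrix(mk_expr(m))
  expect_equal(attr(r, "constant_genes"), "g2")
  expect_equal(r["g2", "g1"], 0)
  expect_equal(r["g2", "g2"], 1)
})

test_that("clustering recovers block-diagonal structure deterministically", {
  n <- 10
  r <- matrix(0.05, n, n)
  r[1:5, 1:5] <- 0.9
  r[6:10, 6:10] <- 0.9
  diag(r) <- 1
  dimnames(r) <- list(paste0("g", 1:n), paste0("g", 1:n))
  cl <- cluster_modules(r, 2)
  expect_equal(length(unique(cl$cluster[cl$gene %in% paste0("g", 1:5)])), 1L)
  expect_equal(length(unique(cl$cluster[cl$gene %in% paste0("g", 6:10)])), 1L)
  expect_equal(length(unique(cl$cluster)), 2L)

  singletons <- cluster_modules(r, n)
  expect_equal(length(unique(singletons$cluster)), n)
  expect_identical(cluster_modules(r, 2), cl)
  # gene order in the matrix does not change the assignment
  perm <- sample(n)
  cl2 <- cluster_modules(r[perm, perm], 2)
  expect_identical(dplyr::arrange(cl2, gene), dplyr::arrange(cl, gene))
  expect_error(cluster_modules(r, 1), "k must")
  expect_error(cluster_modules(r, n + 1), "k must")
})

test_that("module selection takes the known-richest cluster with correlation tie-break", {
  assignments <- tibble::tibble(gene = paste0("g", 1:8),
                                cluster = rep(1:2, each = 4))
  labels <- list(known = c("g1", "g5"), family = c("g2", "g3", "g6", "g7"))
  r <- diag(1, 8)
  dimnames(r) <- list(assignments$gene, assignments$gene)
  # cluster 2's family genes correlate more strongly with its known gene
  r["g2", "g1"] <- r["g1", "g2"] <- 0.2
  r["g3", "g1"] <- r["g1", "g3"] <- 0.2
  r["g6", "g5"] <- r["g5", "g6"] <- 0.8
  r["g7", "g5"] <- r["g5", "g7"] <- 0.8
  mod <- select_candidate_module(assignments, labels, r)
  expect_equal(mod$cluster, 2L)
  expect_equal(mod$candidates, c("g6", "g7"))
  expect_equal(mod$n_known, 1L)

  single <- tibble::tibble(gene = paste0("g", 1:8), cluster = 1L)
  expect_equal(select_candidate_module(single, labels, r)$cluster, 1L)
  none <- list(known = "g9", family = "g2")
  expect_error(select_candidate_module(assignments, none, r), "not in")
})

test_that("the planted module is recovered on simulated expression panels", {
  es <- sim_config()$expr_spec
  sim <- simulate_expression(es, seed = 12)
  fit <- mine_candidates(sim$expr, sim$labels)
  expect_equal(fit$module$n_known, es$k_known)
  rec <- module_recovery(fit, sim)
  expect_equal(rec$recall, 1)
  expect_gte(rec$precision, 0.85)
  td <- tidy(fit)
  expect_equal(sum(td$candidate), length(fit$module$candidates))
  gl <- glance(fit)
  expect_equal(gl$module_size, length(fit$module$members))
})

test_that("mining output is invariant to gene row order", {
  es <- list(n_genes = 120, n_samples = 30, k_known = 6, m_family = 20,
             n_family_total = 40, module_corr = 0.8, noise_sd = 1)
  sim <- simulate_expression(es, seed = 3)
  fit1 <- mine_candidates(sim$expr, sim$labels)
  withr::local_seed(1)
  fit2 <- mine_candidates(sim$expr[sample(nrow(sim$expr)), ], sim$labels)
  expect_identical(fit1$module$members, fit2$module$members)
  expect_identical(fit1$k, fit2$k)
})

test_that("shortlisting spreads picks across clades and positions", {
  cand <- paste0("g", 1:9)
  clades <- tibble::tibble(gene = cand, clade = rep(c("A", "B", "C"), each = 3))
  positions <- tibble::tibble(gene = cand, chrom = "chr9",
                              pos = c(1, 2, 3, 10, 20, 30, 100, 200, 300) * 1e5)
  picks <- shortlist_candidates(cand, clades, positions, 3)
  expect_equal(length(picks), 3L)
  expect_equal(sort(clades$clade[match(picks, clades$gene)]), c("A", "B", "C"))
  expect_identical(picks, shortlist_candidates(cand, clades, positions, 3))
  expect_equal(sort(shortlist_candidates(cand, clades, positions, 9)), cand)
  expect_warning(out <- shortlist_candidates(cand, clades, positions, 12),
                 "n_target")
  expect_equal(sort(out), cand)
  expect_error(shortlist_candidates(c(cand, "gX"), clades,
                                    positions, 3), "clade")
})

test_that("gene cluster fraction counts members inside the region", {
  pos <- tibble::tibble(gene = paste0("g", 1:10), chrom = "chr9",
                        pos = c(1:7 * 1e5, 5e7, 6e7, 7e7))
  region <- list(chrom = "chr9", start = 0, end = 1e6)
  got <- gene_cluster_fraction(pos, region)
  expect_equal(got$count_in, 7L)
  expect_equal(got$percent, 70)
  expect_equal(gene_cluster_fraction(pos, list(chrom = "chr1", start = 0,
                                               end = 1e6))$percent, 0)
  expect_equal(gene_cluster_fraction(pos, list(chrom = "chr9", start = 0,
                                               end = 1e8))$percent, 100)
})
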