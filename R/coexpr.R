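expr_to_matrix <- function(expr) {
  stopifnot(names(expr)[1] == "gene")
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  storage.mode(m) <- "double"
  m
}

#' Normalize a TPM-scale expression matrix
#'
#' Values go to `log2(value + 1)`; genes expressed (value >= `min_value`)
#' in fewer than `min_expressed_samples` samples are dropped. The sample
#' set is unchanged.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param min_expressed_samples Minimum number of expressing samples.
#' @param min_value TPM threshold defining "expressed".
#' @return The filtered, log-transformed expression tibble.
#' @export
normalize_expression <- function(expr, min_expressed_samples = 3,
                                 min_value = 1.0) {
  m <- expr_to_matrix(expr)
  keep <- rowSums(m >= min_value) >= min_expressed_samples
  if (!any(keep)) abort("all genes fall below the expression filter")
  m <- log2(m[keep, , drop = FALSE] + 1)
  out <- as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}

#' Pairwise Pearson correlation of gene expression profiles
#'
#' Pearson correlation across samples for the requested genes. Genes with
#' constant expression have undefined correlation; they are assigned r = 0
#' against every other gene (diagonal stays 1) and listed in the
#' `constant_genes` attribute.
#'
#' @param expr Expression tibble (`gene` + sample columns), usually after
#'   [normalize_expression()].
#' @param genes Genes to include (default all); must be present in `expr`.
#' @return A symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @export
correlation_matrix <- function(expr, genes = NULL) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 3) abort("need at least 3 samples for correlation")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("genes absent from matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  const <- rownames(m)[apply(m, 1, sd) == 0]
  r <- suppressWarnings(cor(t(m), method = "pearson"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "constant_genes") <- const
  r
}

#' Cut a correlation matrix into coexpression clusters
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' correlation distance `d = 1 - r`, cut into `k` clusters. The procedure
#' is fully deterministic; gene order does not affect the assignment.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param k Number of clusters, `2 <= k <= n_genes`.
#' @return A tibble (`gene`, `cluster`); cluster ids are renumbered by
#'   first gene id so the labelling is order-invariant.
#' @export
cluster_modules <- function(corr, k) {
  n <- nrow(corr)
  if (k < 2 || k > n) abort("k must lie in [2, n_genes]")
  o <- order(rownames(corr))
  corr <- corr[o, o]
  hc <- hclust(stats::as.dist(1 - corr), method = "average")
  cl <- cutree(hc, k = k)
  # renumber clusters by order of first appearance over sorted gene ids
  cl <- as.integer(factor(cl, levels = unique(cl)))
  tibble(gene = rownames(corr), cluster = cl)
}

#' Choose the cluster count by mean silhouette width
#'
#' Scans `k` over a range and returns the cut maximizing the mean
#' silhouette width on the correlation distance. The default range scales
#' with the gene count (up to one cluster per three genes, at least 2:20):
#' a tightly correlated module survives deep cuts intact, while genes that
#' attached to it through chance correlation split off as singletons, so
#' the scan must be allowed to go deep enough to expose them.
#'
#' @param corr Correlation matrix.
#' @param k_range Candidate cluster counts (clipped to valid values);
#'   default `2:max(20, n/3)`.
#' @return The selected `k` (integer), with the silhouette profile attached
#'   as attribute `profile`.
#' @export
choose_k <- function(corr, k_range = NULL) {
  n <- nrow(corr)
  if (is.null(k_range)) k_range <- 2:max(20, floor(n / 3))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("no valid k in range")
  o <- order(rownames(corr))
  d <- stats::as.dist(1 - corr[o, o])
  hc <- hclust(d, method = "average")
  widths <- vapply(k_range, function(k) {
    sil <- cluster::silhouette(cutree(hc, k = k), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  k <- k_range[which.max(widths)]
  attr(k, "profile") <- tibble(k = k_range, mean_silhouette = widths)
  k
}

#' Select the candidate coexpression module
#'
#' The candidate module is the cluster holding the largest number of known
#' pathway genes; its family-gene members are the enzyme candidates. Ties
#' are broken by the higher mean correlation between the cluster's family
#' genes and its known genes.
#'
#' @param assignments Tibble (`gene`, `cluster`) from [cluster_modules()].
#' @param labels List with `known` and `family` gene-id sets; every
#'   labelled gene must be assigned.
#' @param corr Correlation matrix (needed for tie-breaking and the module's
#'   mean intra-module correlation).
#' @return A list of class `coexpr_module`: `cluster`, `members`,
#'   `n_known`, `n_family`, `candidates` (family genes in the module) and
#'   `mean_intra_corr`.
#' @export
select_candidate_module <- function(assignments, labels, corr) {
  lab <- unique(c(labels$known, labels$family))
  missing <- setdiff(lab, assignments$gene)
  if (length(missing) > 0) {
    abort(paste0("labelled genes not in assignments: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  counts <- assignments |>
    mutate(known = .data$gene %in% labels$known) |>
    group_by(.data$cluster) |>
    summarise(n_known = sum(.data$known), .groups = "drop")
  if (all(counts$n_known == 0)) abort("no known pathway gene was clustered")
  top <- counts$cluster[counts$n_known == max(counts$n_known)]
  if (length(top) > 1) {
    # tie-break: mean family-to-known correlation inside each tied cluster
    score <- vapply(top, function(cl) {
      g <- assignments$gene[assignments$cluster == cl]
      fam <- intersect(g, labels$family)
      kn <- intersect(g, labels$known)
      if (length(fam) == 0 || length(kn) == 0) return(-Inf)
      mean(corr[fam, kn, drop = FALSE])
    }, numeric(1))
    top <- top[which.max(score)]
  }
  members <- sort(assignments$gene[assignments$cluster == top])
  sub <- corr[members, members, drop = FALSE]
  structure(list(
    cluster = top,
    members = members,
    n_known = length(intersect(members, labels$known)),
    n_family = length(intersect(members, labels$family)),
    candidates = sort(intersect(members, labels$family)),
    mean_intra_corr = if (length(members) > 1)
      mean(sub[upper.tri(sub)]) else 1
  ), class = "coexpr_module")
}

#' Mine candidate enzyme genes by coexpression with a known pathway
#'
#' The full mining pipeline: expression filter and log transform, Pearson
#' correlation over the labelled genes (known pathway plus enzyme family),
#' average-linkage clustering (with silhouette-selected `k` when not
#' given), and selection of the known-gene-richest module.
#'
#' @param expr Raw TPM-scale expression tibble (`gene` + samples).
#' @param labels List with `known` and `family` gene-id sets.
#' @param k Cluster count; `NULL` selects it by [choose_k()].
#' @param min_expressed_samples,min_value Passed to
#'   [normalize_expression()].
#' @return An object of class `coexpr_fit` with the normalized matrix,
#'   correlation matrix, assignments, chosen `k` and selected module.
#' @export
mine_candidates <- function(expr, labels, k = NULL,
                            min_expressed_samples = 3, min_value = 1.0) {
  norm <- normalize_expression(expr, min_expressed_samples, min_value)
  lab <- unique(c(labels$known, labels$family))
  kept <- intersect(lab, norm$gene)
  if (length(kept) < 3) abort("fewer than 3 labelled genes pass the filter")
  labels <- list(known = intersect(labels$known, kept),
                 family = intersect(labels$family, kept))
  corr <- correlation_matrix(norm, genes = sort(kept))
  if (is.null(k)) k <- choose_k(corr)
  assignments <- cluster_modules(corr, as.integer(k))
  module <- select_candidate_module(assignments, labels, corr)
  structure(list(
    normalized = norm, corr = corr, assignments = assignments,
    k = as.integer(k), labels = labels, module = module
  ), class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, ...) {
  cat("coexpression mining fit\n")
  cat("  labelled genes:", nrow(x$corr), "  clusters:", x$k, "\n")
  cat("  selected module:", length(x$module$members), "genes (",
      x$module$n_known, "known pathway,", x$module$n_family, "family )\n")
  cat("  mean intra-module r:", round(x$module$mean_intra_corr, 3), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.coexpr_fit <- function(x, ...) {
  x$assignments |>
    mutate(
      known = .data$gene %in% x$labels$known,
      family = .data$gene %in% x$labels$family,
      in_module = .data$gene %in% x$module$members,
      candidate = .data$gene %in% x$module$candidates
    )
}

#' @exportS3Method
glance.coexpr_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$corr), k = x$k,
    module_size = length(x$module$members),
    n_known = x$module$n_known, n_family = x$module$n_family,
    n_candidates = length(x$module$candidates),
    mean_intra_corr = x$module$mean_intra_corr
  )
}

#' @exportS3Method
autoplot.coexpr_fit <- function(object, ...) {
  ord <- arrange(object$assignments, .data$cluster, .data$gene)$gene
  df <- as_tibble(as.data.frame.table(object$corr[ord, ord],
                                      responseName = "r"))
  names(df)[1:2] <- c("gene_a", "gene_b")
  df$gene_a <- factor(df$gene_a, levels = ord)
  df$gene_b <- factor(df$gene_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_a, .data$gene_b,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Shortlist candidates across clades and chromosomal positions
#'
#' Formalizes a diversity-driven expert shortlist: clades are visited in
#' rounds by descending size, and within each clade the gene maximizing the
#' minimum genomic distance to the genes already picked is chosen (genes on
#' different chromosomes count as infinitely distant; remaining ties break
#' by gene id). Deterministic.
#'
#' @param candidates Candidate gene ids (e.g. `module$candidates`).
#' @param clades Tibble (`gene`, `clade`) covering every candidate.
#' @param positions Tibble (`gene`, `chrom`, `pos`) covering every
#'   candidate.
#' @param n_target Number of genes to select; if larger than the candidate
#'   set, all candidates are returned with a warning.
#' @return Character vector of selected gene ids, in pick order.
#' @export
shortlist_candidates <- function(candidates, clades, positions, n_target) {
  if (n_target >= length(candidates)) {
    if (n_target > length(candidates)) {
      warn("n_target exceeds candidate count; returning all candidates")
    }
    return(sort(candidates))
  }
  missing <- setdiff(candidates, clades$gene)
  if (length(missing) > 0) abort("candidate without clade assignment")
  missing <- setdiff(candidates, positions$gene)
  if (length(missing) > 0) abort("candidate without genomic position")
  info <- tibble(gene = candidates) |>
    left_join(clades, by = "gene") |>
    left_join(positions, by = "gene")
  clade_sizes <- sort(table(info$clade), decreasing = TRUE)
  clade_order <- names(clade_sizes)[order(-clade_sizes, names(clade_sizes))]
  picked <- character(0)
  min_dist <- function(g) {
    if (length(picked) == 0) return(Inf)
    gi <- info[info$gene == g, ]
    pi <- info[info$gene %in% picked, ]
    same <- pi$chrom == gi$chrom
    if (!any(same)) return(Inf)
    min(abs(pi$pos[same] - gi$pos))
  }
  repeat {
    for (cl in clade_order) {
      if (length(picked) >= n_target) break
      pool <- setdiff(info$gene[info$clade == cl], picked)
      if (length(pool) == 0) next
      d <- vapply(pool, min_dist, numeric(1))
      pool <- pool[order(-d, pool)]
      picked <- c(picked, pool[1])
    }
    if (length(picked) >= n_target) break
  }
  picked
}

#' Fraction of a gene family falling inside a genomic region
#'
#' The clustering statistic for a gene family: how many members lie inside
#' one region (e.g. a biosynthetic gene cluster on one chromosome).
#'
#' @param positions Tibble (`gene`, `chrom`, `pos`) for every family
#'   member.
#' @param region One-row tibble or list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return One-row tibble: `count_in`, `total`, `percent` (rounded half-up
#'   to integer, the convention of published family statistics).
#' @export
gene_cluster_fraction <- function(positions, region) {
  if (nrow(positions) == 0) abort("empty gene family")
  inside <- positions$chrom == region$chrom &
    positions$pos >= region$start & positions$pos < region$end
  tibble(
    count_in = sum(inside), total = nrow(positions),
    percent = round_half_up(100 * sum(inside) / nrow(positions))
  )
}
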