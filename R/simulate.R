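#' Simulation configuration for a toy phased diploid genome
#'
#' Builds the configuration consumed by [simulate_diploid_genome()],
#' [simulate_depth_track()] and [simulate_alignment_blocks()]. The defaults
#' describe a small diploid genome — 4 chromosome pairs of 2 Mb with
#' plant-type telomere arrays (`TTTAGGG`), N-gaps, a handful of planted
#' structural variants, 2- and 3-copy collapsed intervals, and one
#' length-asymmetric chromosome pair (the ZW candidate) carrying a 100 kb
#' haplotype-2-specific insertion — at a scale where the whole simulate →
#' analyse → recover loop runs in seconds. Depth is parameterised at a 10 kb
#' window and 30x mean coverage, a scaled-down rendering of a 100 kb-window,
#' ~72x HiFi depth screen.
#'
#' Chromosomes are named `chr<i>_h1` / `chr<i>_h2` for pair `i`. All
#' coordinates are 0-based half-open. `sv_spec` positions are in haplotype-1
#' coordinates; `gap_spec` and `collapse_spec` positions are in the final
#' coordinates of the named chromosome.
#'
#' @param n_chrom Number of chromosome pairs.
#' @param chrom_len Length of each haplotype-1 chromosome (bp).
#' @param telomere_motif Telomeric repeat unit (forward strand, 3' end).
#' @param telomere_copies Tandem copies of the motif planted at each end.
#' @param gap_spec Tibble `(chrom, start, end)` of N-gap placements, or
#'   `NULL` for the default (two 500 bp gaps per chromosome, none on
#'   `chr2_h1` so that one chromosome is telomere-to-telomere).
#' @param sv_spec Tibble `(type, pair, start, length, dest_pair)` of planted
#'   SVs (`type` in INV/TRANS/DUP; `dest_pair` only for TRANS), or `NULL`
#'   for the default set of 2 inversions, 1 translocation and 1 duplication.
#' @param collapse_spec Tibble `(chrom, start, end, copies)` of collapsed
#'   intervals, or `NULL` for the default (two 2-copy and one 3-copy
#'   interval, window-aligned).
#' @param sex_pair List `(pair, extra_len, insert_at)`: which pair carries
#'   the W-specific insertion in haplotype 2, its length, and the insertion
#'   point in haplotype-1 coordinates.
#' @param mean_depth Mean read depth of single-copy windows.
#' @param depth_noise_sd Standard deviation of window depth noise.
#' @param window Depth window width (bp).
#' @param expr_spec List passed to [simulate_expression()]; see there.
#' @return A list of class `phasekit_sim_config`.
#' @export
sim_config <- function(n_chrom = 4,
                       chrom_len = 2e6,
                       telomere_motif = "TTTAGGG",
                       telomere_copies = 100,
                       gap_spec = NULL,
                       sv_spec = NULL,
                       collapse_spec = NULL,
                       sex_pair = list(pair = n_chrom, extra_len = 1e5, insert_at = 1e4),
                       mean_depth = 30,
                       depth_noise_sd = 3,
                       window = 1e4,
                       expr_spec = list(n_genes = 500, n_samples = 40,
                                        k_known = 16, m_family = 70,
                                        n_family_total = 158,
                                        module_corr = 0.8, noise_sd = 1)) {
  chrom_h1 <- paste0("chr", seq_len(n_chrom), "_h1")
  chrom_h2 <- paste0("chr", seq_len(n_chrom), "_h2")
  if (is.null(gap_spec)) {
    gchrom <- c(chrom_h1, chrom_h2)
    gchrom <- setdiff(gchrom, "chr2_h1")  # keep one T2T chromosome
    gap_spec <- bind_rows(
      tibble(chrom = gchrom, start = 0.30 * chrom_len, end = 0.30 * chrom_len + 500),
      tibble(chrom = gchrom, start = 0.65 * chrom_len, end = 0.65 * chrom_len + 500)
    )
  }
  if (is.null(sv_spec)) {
    sv_spec <- tibble(
      type = c("INV", "INV", "TRANS", "DUP"),
      pair = c(1L, 2L, 3L, 1L),
      start = c(0.40, 0.60, 0.45, 0.75) * chrom_len,
      length = c(5e3, 8e3, 6e3, 4e3),
      dest_pair = c(NA, NA, 1L, NA)
    )
    sv_spec <- sv_spec[sv_spec$pair <= n_chrom & (is.na(sv_spec$dest_pair) |
                                                    sv_spec$dest_pair <= n_chrom), ]
  }
  if (is.null(collapse_spec)) {
    # balanced per pair: both haplotype assemblies collapse the same amount
    # of repeat (at different positions), so corrected lengths close the
    # apparent asymmetry and only the sex pair keeps a real difference
    collapse_spec <- tibble(
      chrom = c("chr1_h1", "chr1_h2", "chr3_h1", "chr3_h2"),
      start = c(4e5, 1.0e6, 5e5, 1.2e6),
      end = c(4.3e5, 1.03e6, 5.4e5, 1.24e6),
      copies = c(3L, 3L, 2L, 2L)
    )
    collapse_spec <- collapse_spec[as.integer(sub("^chr([0-9]+)_h[12]$", "\\1",
                                                  collapse_spec$chrom)) <= n_chrom, ]
  }
  cfg <- structure(list(
    n_chrom = as.integer(n_chrom), chrom_len = chrom_len,
    telomere_motif = telomere_motif, telomere_copies = as.integer(telomere_copies),
    gap_spec = gap_spec, sv_spec = sv_spec, collapse_spec = collapse_spec,
    sex_pair = sex_pair, mean_depth = mean_depth,
    depth_noise_sd = depth_noise_sd, window = window, expr_spec = expr_spec
  ), class = "phasekit_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  telo_len <- cfg$telomere_copies * nchar(cfg$telomere_motif)
  if (2 * telo_len >= cfg$chrom_len) abort("telomere arrays exceed chromosome length")
  sv <- cfg$sv_spec
  if (nrow(sv) > 0) {
    if (!all(sv$type %in% c("INV", "TRANS", "DUP"))) {
      abort("sv_spec type must be INV, TRANS or DUP")
    }
    if (any(sv$start < 0) || any(sv$start + sv$length > cfg$chrom_len)) {
      abort("planted SV outside chromosome bounds")
    }
    # refuse ambiguous (overlapping) planted truth, per chromosome pair
    ends <- split(sv[, c("start", "length")], sv$pair)
    for (grp in ends) {
      o <- order(grp$start)
      s <- grp$start[o]; e <- grp$start[o] + grp$length[o]
      if (any(s[-1] < e[-length(e)])) abort("overlapping planted SVs on one chromosome")
    }
    sp <- cfg$sex_pair
    on_sex <- sv$pair == sp$pair
    if (any(on_sex & sv$start < sp$insert_at + 1 & sv$start + sv$length > sp$insert_at)) {
      abort("planted SV overlaps the sex-pair insertion point")
    }
  }
  if (any(cfg$gap_spec$end <= cfg$gap_spec$start)) abort("invalid gap interval")
  if (nrow(cfg$collapse_spec) > 0 && any(cfg$collapse_spec$copies < 2)) {
    abort("collapsed intervals must have copies >= 2")
  }
  es <- cfg$expr_spec
  if (es$module_corr <= 0 || es$module_corr >= 1) abort("module_corr must lie in (0,1)")
  if (es$k_known + es$m_family > es$n_genes) abort("k_known + m_family exceeds n_genes")
  invisible(cfg)
}

#' Coordinate-level simulation truth (no sequences)
#'
#' Computes the planted-truth bookkeeping — per-pair chromosome lengths in
#' both haplotypes, every planted SV in both coordinate systems, the sex-pair
#' insertion (recorded as an INS structural variant), gap, telomere and
#' collapse placements — without generating any sequence. This is what large
#' replicate studies use; [simulate_diploid_genome()] produces the same truth
#' plus the actual FASTA records.
#'
#' @param config A [sim_config()] object.
#' @return A truth list of class `phasekit_truth`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_chrom
  chrom_h1 <- paste0("chr", seq_len(n), "_h1")
  chrom_h2 <- paste0("chr", seq_len(n), "_h2")
  sp <- config$sex_pair

  # events per pair in haplotype-1 coordinates; the sex insertion is a
  # degenerate-target INS event
  ev <- config$sv_spec
  ev$tstart <- ev$start
  ev$tend <- ev$start + ev$length
  ins <- tibble(type = "INS", pair = as.integer(sp$pair), start = sp$insert_at,
                length = sp$extra_len, dest_pair = NA_integer_,
                tstart = sp$insert_at, tend = sp$insert_at)
  if (sp$extra_len <= 0) ins <- ins[0, ]  # no asymmetry planted
  ev <- bind_rows(ev[, names(ins)], ins)

  svs <- list()
  len_h2 <- setNames(rep(config$chrom_len, n), chrom_h2)
  pending_trans <- list()
  for (i in seq_len(n)) {
    e_i <- ev[ev$pair == i, , drop = FALSE]
    e_i <- e_i[order(e_i$tstart), , drop = FALSE]
    off <- 0
    for (j in seq_len(nrow(e_i))) {
      e <- e_i[j, ]
      L <- e$length
      row <- tibble(
        type = e$type, tchrom = chrom_h1[i], tstart = e$tstart, tend = e$tend,
        qchrom = chrom_h2[i], qstart = NA_real_, qend = NA_real_, length = L
      )
      if (e$type == "INV") {
        row$qstart <- e$tstart + off; row$qend <- e$tend + off
      } else if (e$type == "DUP") {
        # q interval records the extra (novel) copy, placed right after the
        # collinear first copy
        row$qstart <- e$tend + off; row$qend <- e$tend + off + L
        off <- off + L
      } else if (e$type == "INS") {
        row$qstart <- e$tstart + off; row$qend <- e$tstart + off + L
        off <- off + L
      } else if (e$type == "TRANS") {
        dest <- as.integer(e$dest_pair)
        row$qchrom <- chrom_h2[dest]
        pending_trans[[length(pending_trans) + 1]] <- list(row = row, dest = dest)
        row <- NULL
        off <- off - L
      }
      if (!is.null(row)) svs[[length(svs) + 1]] <- row
    }
    len_h2[i] <- config$chrom_len + off
  }
  # translocated segments are appended at the end of the destination
  # haplotype-2 chromosome, in sv_spec order
  for (pt in pending_trans) {
    row <- pt$row
    row$qstart <- unname(len_h2[pt$dest])
    row$qend <- row$qstart + row$length
    len_h2[pt$dest] <- row$qend
    svs[[length(svs) + 1]] <- row
  }
  svs <- if (length(svs)) bind_rows(svs) else
    tibble(type = character(), tchrom = character(), tstart = numeric(),
           tend = numeric(), qchrom = character(), qstart = numeric(),
           qend = numeric(), length = numeric())

  truth <- structure(list(
    params = list(
      n_chrom = n, chrom_len = config$chrom_len, window = config$window,
      mean_depth = config$mean_depth, depth_noise_sd = config$depth_noise_sd,
      telomere_motif = config$telomere_motif,
      telomere_copies = config$telomere_copies
    ),
    chrom_pairs = tibble(
      pair = seq_len(n), chrom_h1 = chrom_h1, chrom_h2 = chrom_h2,
      len_h1 = rep(config$chrom_len, n), len_h2 = unname(len_h2)
    ),
    svs = svs,
    sex_pair = list(pair = as.integer(sp$pair), chrom_z = chrom_h1[sp$pair],
                    chrom_w = chrom_h2[sp$pair], extra_len = sp$extra_len,
                    insert_at = sp$insert_at),
    gaps = config$gap_spec,
    telomeres = tibble(chrom = c(chrom_h1, chrom_h2), left = TRUE, right = TRUE),
    collapse = config$collapse_spec
  ), class = "phasekit_truth")
  truth
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a phased diploid genome with planted truth
#'
#' Haplotype 1 is drawn at random (telomere arrays at both ends, N-gaps at
#' the configured positions); haplotype 2 is derived from it by applying the
#' planted inversions (reverse-complemented in place), duplications (tandem
#' extra copy), translocations (segment moved to the end of another
#' chromosome) and the sex-pair insertion. Every planted feature is recorded
#' exactly once in the returned truth, which [simulate_alignment_blocks()]
#' and the recovery tests consume.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A list with elements `hap1`, `hap2` (tibbles as from
#'   [read_fasta()]) and `truth` (class `phasekit_truth`).
#' @export
simulate_diploid_genome <- function(config, seed = 1L) {
  truth <- simulate_truth(config)
  n <- config$n_chrom
  telo <- strrep(config$telomere_motif, config$telomere_copies)
  telo_left <- revcomp(telo)  # CCCTAAA-type array on the 5' end
  telo_len <- nchar(telo)
  withr::with_seed(seed, {
    hap1_seq <- vapply(seq_len(n), function(i) {
      paste0(telo_left, random_dna(config$chrom_len - 2 * telo_len), telo)
    }, character(1))
    names(hap1_seq) <- truth$chrom_pairs$chrom_h1

    # haplotype 2: walk haplotype-1 events in target order
    sv <- truth$svs
    hap2_seq <- setNames(character(n), truth$chrom_pairs$chrom_h2)
    pending <- sv[sv$type == "TRANS", , drop = FALSE]
    for (i in seq_len(n)) {
      S <- hap1_seq[i]
      e_i <- sv[sv$tchrom == truth$chrom_pairs$chrom_h1[i] & sv$type != "TRANS", ,
                drop = FALSE]
      # translocations leave a gap on the source target side
      t_i <- pending[pending$tchrom == truth$chrom_pairs$chrom_h1[i], ,
                     drop = FALSE]
      ev <- bind_rows(e_i, t_i)
      ev <- ev[order(ev$tstart), , drop = FALSE]
      pieces <- character(0)
      cur <- 0
      for (j in seq_len(nrow(ev))) {
        e <- ev[j, ]
        if (e$tstart > cur) pieces <- c(pieces, substr(S, cur + 1, e$tstart))
        seg <- if (e$tend > e$tstart) substr(S, e$tstart + 1, e$tend) else ""
        pieces <- c(pieces, switch(
          e$type,
          INV = revcomp(seg),
          DUP = paste0(seg, seg),
          INS = random_dna(e$length),
          TRANS = ""  # removed here, appended to destination below
        ))
        cur <- e$tend
      }
      if (cur < nchar(S)) pieces <- c(pieces, substr(S, cur + 1, nchar(S)))
      hap2_seq[i] <- paste(pieces, collapse = "")
    }
    for (j in seq_len(nrow(pending))) {
      e <- pending[j, ]
      seg <- substr(hap1_seq[e$tchrom], e$tstart + 1, e$tend)
      hap2_seq[e$qchrom] <- paste0(hap2_seq[e$qchrom], seg)
    }
  })
  stopifnot(nchar(hap2_seq) == truth$chrom_pairs$len_h2)

  # N-gap masking in final coordinates of the named chromosome
  all_seq <- c(hap1_seq, hap2_seq)
  g <- truth$gaps
  for (j in seq_len(nrow(g))) {
    ch <- g$chrom[j]
    if (!ch %in% names(all_seq)) abort(paste0("gap_spec names unknown chromosome ", ch))
    substr(all_seq[ch], g$start[j] + 1, g$end[j]) <- strrep("N", g$end[j] - g$start[j])
  }

  hap1 <- tibble(id = truth$chrom_pairs$chrom_h1,
                 seq = unname(all_seq[truth$chrom_pairs$chrom_h1]))
  hap2 <- tibble(id = truth$chrom_pairs$chrom_h2,
                 seq = unname(all_seq[truth$chrom_pairs$chrom_h2]))
  hap1$length <- nchar(hap1$seq)
  hap2$length <- nchar(hap2$seq)
  list(hap1 = hap1, hap2 = hap2, truth = truth)
}

#' Simulate a windowed HiFi-depth track
#'
#' Windows tile every chromosome of both haplotypes; a window whose midpoint
#' falls inside a planted collapsed interval of `c` assembly-collapsed copies
#' is drawn from Normal(`c * mean_depth`, `sqrt(c) * noise_sd`), all other
#' windows from Normal(`mean_depth`, `noise_sd`), truncated at 0.
#'
#' @param truth Truth from [simulate_truth()] or [simulate_diploid_genome()].
#' @param mean_depth Mean single-copy depth (> 0).
#' @param noise_sd Window depth standard deviation (0 gives exact depths).
#' @param window Window width (bp); the last window of a chromosome is
#'   truncated.
#' @param seed Integer seed.
#' @return A depth tibble (`chrom`, `start`, `end`, `depth`).
#' @export
simulate_depth_track <- function(truth, mean_depth = truth$params$mean_depth,
                                 noise_sd = truth$params$depth_noise_sd,
                                 window = truth$params$window, seed = 1L) {
  if (mean_depth <= 0) abort("mean_depth must be > 0")
  cp <- truth$chrom_pairs
  chroms <- c(setNames(cp$len_h1, cp$chrom_h1), setNames(cp$len_h2, cp$chrom_h2))
  wins <- purrr::map2_dfr(names(chroms), unname(chroms), function(ch, len) {
    start <- seq(0, len - 1, by = window)
    tibble(chrom = ch, start = start, end = pmin(start + window, len))
  })
  mid <- (wins$start + wins$end) / 2
  copies <- rep(1, nrow(wins))
  cl <- truth$collapse
  for (j in seq_len(nrow(cl))) {
    hit <- wins$chrom == cl$chrom[j] & mid >= cl$start[j] & mid < cl$end[j]
    copies[hit] <- cl$copies[j]
  }
  withr::with_seed(seed, {
    depth <- pmax(0, rnorm(nrow(wins), copies * mean_depth, sqrt(copies) * noise_sd))
  })
  wins$depth <- depth
  wins
}

#' Project planted truth into haplotype-to-haplotype alignment blocks
#'
#' Deterministic projection of the truth into PAF space (query = haplotype 2,
#' target = haplotype 1): a collinear plus-strand backbone per chromosome
#' pair, one minus-strand block per planted inversion, cross-chromosome
#' blocks for translocations, and two query blocks onto one target interval
#' for duplications (the collinear copy and the novel copy). The sex-pair
#' insertion has no block — it is the unaligned W-specific region. Blocks
#' shorter than 50 bp are dropped.
#'
#' @param truth Truth from [simulate_truth()] or [simulate_diploid_genome()].
#' @return An alignment-block tibble in the layout of [read_paf()].
#' @export
simulate_alignment_blocks <- function(truth) {
  cp <- truth$chrom_pairs
  qlen <- setNames(cp$len_h2, cp$chrom_h2)
  tlen <- setNames(cp$len_h1, cp$chrom_h1)
  sv <- truth$svs
  out <- list()
  emit <- function(qn, qs, qe, st, tn, ts, te) {
    out[[length(out) + 1]] <<- tibble(
      qname = qn, qlen = unname(qlen[qn]), qstart = qs, qend = qe, strand = st,
      tname = tn, tlen = unname(tlen[tn]), tstart = ts, tend = te,
      nmatch = qe - qs, alen = qe - qs, mapq = 60
    )
  }
  for (i in seq_len(nrow(cp))) {
    tch <- cp$chrom_h1[i]; qch <- cp$chrom_h2[i]
    ev <- sv[sv$tchrom == tch, , drop = FALSE]
    ev <- ev[order(ev$tstart, ev$tend), , drop = FALSE]
    cur <- 0; off <- 0
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      if (e$tstart > cur) emit(qch, cur + off, e$tstart + off, "+", tch, cur, e$tstart)
      if (e$type == "INV") {
        emit(qch, e$qstart, e$qend, "-", tch, e$tstart, e$tend)
      } else if (e$type == "DUP") {
        emit(qch, e$qstart - e$length, e$qstart, "+", tch, e$tstart, e$tend)
        emit(qch, e$qstart, e$qend, "+", tch, e$tstart, e$tend)
        off <- off + e$length
      } else if (e$type == "INS") {
        off <- off + e$length
      } else if (e$type == "TRANS") {
        emit(e$qchrom, e$qstart, e$qend, "+", tch, e$tstart, e$tend)
        off <- off - e$length
      }
      cur <- e$tend
    }
    if (cur < cp$len_h1[i]) emit(qch, cur + off, cp$len_h1[i] + off, "+", tch, cur, cp$len_h1[i])
  }
  blocks <- bind_rows(out)
  blocks <- blocks[blocks$qend - blocks$qstart >= 50, , drop = FALSE]
  blocks[order(blocks$tname, blocks$tstart, blocks$qname, blocks$qstart), ]
}

#' Simulate an expression panel with a planted coexpression module
#'
#' A latent-factor model: module genes share one factor with loadings set so
#' that pairwise correlation on the log2 scale is `module_corr`; all other
#' genes are independent noise. Values are exponentiated to a non-negative
#' TPM-like scale (`2^z - 1`), so `log2(value + 1)` recovers the linear
#' model. Labels mark `k_known` pathway genes (all inside the module) and
#' `n_family_total` family genes of which `m_family` are inside the module —
#' emulating a 40-sample panel where 16 known pathway genes co-express with
#' 70 of 158 enzyme-family genes.
#'
#' @param expr_spec List with `n_genes`, `n_samples`, `k_known`, `m_family`,
#'   `n_family_total`, `module_corr` (in (0,1)) and `noise_sd`.
#' @param seed Integer seed.
#' @return List with `expr` (tibble, `gene` + one column per sample),
#'   `labels` (list with `known` and `family` gene-id sets) and
#'   `module_genes` (the planted module membership).
#' @export
simulate_expression <- function(expr_spec, seed = 1L) {
  es <- expr_spec
  if (es$module_corr <= 0 || es$module_corr >= 1) abort("module_corr must lie in (0,1)")
  n_family_total <- es$n_family_total %||% es$m_family
  if (n_family_total < es$m_family) abort("n_family_total < m_family")
  if (es$k_known + n_family_total > es$n_genes) {
    abort("k_known + n_family_total exceeds n_genes")
  }
  known <- sprintf("PWY%02d", seq_len(es$k_known))
  family <- sprintf("ODD%03d", seq_len(n_family_total))
  n_bg <- es$n_genes - es$k_known - n_family_total
  background <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  genes <- c(known, family, background)
  module <- c(known, family[seq_len(es$m_family)])
  in_module <- genes %in% module

  rho <- es$module_corr
  sigma <- es$noise_sd
  loading <- if (sigma > 0) sigma * sqrt(rho / (1 - rho)) else 1
  withr::with_seed(seed, {
    f <- rnorm(es$n_samples)
    mu <- runif(length(genes), 3, 8)
    z <- matrix(0, length(genes), es$n_samples)
    z[in_module, ] <- mu[in_module] +
      loading * matrix(rep(f, each = sum(in_module)), ncol = es$n_samples) +
      rnorm(sum(in_module) * es$n_samples, 0, sigma)
    z[!in_module, ] <- mu[!in_module] + rnorm(sum(!in_module) * es$n_samples, 0, 1)
  })
  vals <- pmax(2^z - 1, 0)
  expr <- as_tibble(as.data.frame(vals))
  names(expr) <- sprintf("S%02d", seq_len(es$n_samples))
  expr <- dplyr::bind_cols(tibble(gene = genes), expr)
  list(expr = expr,
       labels = list(known = known, family = family),
       module_genes = module)
}

#' Simulate a tissue-by-sex expression panel with planted sex-biased genes
#'
#' Builds the input for [sex_biased_genes()]: genes positioned on
#' chromosomes, a per-(tissue, sex) TPM table over root/leaf/bark/flower,
#' and planted truth. Biased genes inside the designated nonhomologous
#' regions are expressed in the flower of one sex only; unbiased genes are
#' expressed equally in both sexes; `n_outside` genes carry a biased profile
#' but lie outside every region (they must be filtered out by position).
#'
#' @param regions Tibble `(chrom, start, end)` of nonhomologous Z/W regions.
#' @param n_biased Planted sex-biased genes inside the regions.
#' @param n_unbiased Unbiased genes (half inside, half outside the regions).
#' @param n_outside Biased-profile genes outside all regions.
#' @param expr_high TPM of the expressed sex in the flower.
#' @param expr_low TPM of the silent sex in the flower.
#' @param noise_sd Multiplicative-free additive noise on every value
#'   (truncated at 0); 0 gives exact values.
#' @param seed Integer seed.
#' @return List with `expr` (tibble `gene`, `tissue`, `sex`, `tpm`),
#'   `positions` (tibble `gene`, `chrom`, `pos`) and `truth` (tibble
#'   `gene`, `bias`).
#' @export
simulate_sex_expression <- function(regions, n_biased = 7, n_unbiased = 50,
                                    n_outside = 5, expr_high = 10,
                                    expr_low = 0, noise_sd = 0, seed = 1L) {
  stopifnot(nrow(regions) >= 1)
  tissues <- c("root", "leaf", "bark", "flower")
  ids <- list(
    biased = sprintf("SB%03d", seq_len(n_biased)),
    unbiased = sprintf("UB%03d", seq_len(n_unbiased)),
    outside = if (n_outside > 0) sprintf("OB%03d", seq_len(n_outside)) else character(0)
  )
  withr::with_seed(seed, {
    place_in <- function(k) {
      ri <- sample(nrow(regions), k, replace = TRUE)
      tibble(chrom = regions$chrom[ri],
             pos = floor(runif(k, regions$start[ri], regions$end[ri])))
    }
    place_out <- function(k) {
      far <- max(regions$end)
      tibble(chrom = regions$chrom[sample(nrow(regions), k, replace = TRUE)],
             pos = floor(runif(k, far + 1e6, far + 2e6)))
    }
    n_in_ub <- ceiling(n_unbiased / 2)
    positions <- bind_rows(
      dplyr::bind_cols(tibble(gene = ids$biased), place_in(n_biased)),
      dplyr::bind_cols(tibble(gene = ids$unbiased[seq_len(n_in_ub)]), place_in(n_in_ub)),
      dplyr::bind_cols(tibble(gene = ids$unbiased[-seq_len(n_in_ub)]),
                       place_out(n_unbiased - n_in_ub)),
      if (n_outside > 0)
        dplyr::bind_cols(tibble(gene = ids$outside), place_out(n_outside))
    )
    bias <- sample(c("female", "male"), n_biased + n_outside, replace = TRUE)
    grid <- tidyr::expand_grid(
      gene = c(ids$biased, ids$unbiased, ids$outside),
      tissue = tissues, sex = c("female", "male")
    )
    biased_of <- setNames(bias, c(ids$biased, ids$outside))
    base <- runif(n_biased + n_unbiased + n_outside, 3, 6)
    names(base) <- c(ids$biased, ids$unbiased, ids$outside)
    tpm <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      g <- grid$gene[r]
      if (g %in% names(biased_of)) {
        tpm[r] <- if (grid$tissue[r] == "flower") {
          if (grid$sex[r] == biased_of[[g]]) expr_high else expr_low
        } else base[[g]] / 2
      } else {
        tpm[r] <- base[[g]]
      }
    }
    if (noise_sd > 0) tpm <- pmax(0, tpm + rnorm(length(tpm), 0, noise_sd))
  })
  grid$tpm <- tpm
  truth <- tibble(gene = ids$biased,
                  bias = paste0(bias[seq_len(n_biased)], "-biased"))
  list(expr = grid, positions = positions, truth = truth)
}

#' Draw a random non-overlapping planted-SV specification
#'
#' Used by replicate studies: draws per-type SV counts and lengths and
#' places them without overlap, clear of telomeres and of the sex-pair
#' insertion point, with at least `min_sep` bp between events so that
#' backbone blocks between neighbours stay above the 50 bp block floor.
#'
#' @param config A [sim_config()] object (placement bounds come from it).
#' @param n_per_type Integer range (length 2) of SV counts per type.
#' @param len_range Length range (bp) of each SV.
#' @param min_sep Minimum separation between planted events (bp).
#' @param seed Integer seed.
#' @return An `sv_spec` tibble suitable for [sim_config()].
#' @export
random_sv_spec <- function(config, n_per_type = c(3L, 20L),
                           len_range = c(500, 5e4), min_sep = 500, seed = 1L) {
  withr::with_seed(seed, {
    types <- c("INV", "TRANS", "DUP")
    counts <- sample(seq(n_per_type[1], n_per_type[2]), 3, replace = TRUE)
    sv <- tibble(
      type = rep(types, counts),
      pair = sample(config$n_chrom, sum(counts), replace = TRUE),
      length = floor(runif(sum(counts), len_range[1], len_range[2]))
    )
    sv$dest_pair <- NA_integer_
    is_tr <- sv$type == "TRANS"
    sv$dest_pair[is_tr] <- vapply(sv$pair[is_tr], function(p) {
      sample(setdiff(seq_len(config$n_chrom), p), 1)
    }, integer(1))
    telo <- config$telomere_copies * nchar(config$telomere_motif)
    lo <- telo + config$sex_pair$insert_at + min_sep
    hi <- config$chrom_len - telo - min_sep
    sv$start <- NA_real_
    for (p in unique(sv$pair)) {
      idx <- which(sv$pair == p)
      lens <- sv$length[idx]
      span <- hi - lo
      slack <- span - sum(lens) - length(idx) * min_sep
      if (slack <= 0) abort("chromosome too small for requested SV load")
      cuts <- sort(runif(length(idx), 0, slack))
      sv$start[idx] <- lo + cuts + cumsum(c(0, head(lens, -1))) +
        min_sep * seq_along(idx)
    }
    sv$start <- floor(sv$start)
  })
  sv[, c("type", "pair", "start", "length", "dest_pair")]
}
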