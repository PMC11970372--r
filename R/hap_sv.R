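# sorted-sweep union of half-open intervals; returns merged intervals
union_intervals <- function(start, end) {
  if (length(start) == 0) return(tibble(start = numeric(), end = numeric()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  k <- 1
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1
      out_s[k] <- start[i]; out_e[k] <- end[i]
    }
  }
  tibble(start = out_s, end = out_e)
}

#' Chain collinear alignment blocks into a syntenic backbone
#'
#' For every (query chromosome, target chromosome) combination, finds the
#' highest-coverage set of plus-strand blocks that is collinear in both
#' coordinate systems — a longest-increasing-subsequence chain weighted by
#' block length. The chains of mutually best-covering chromosome pairs form
#' the syntenic backbone against which structural variants are classified.
#'
#' @param blocks Alignment blocks as from [read_paf()].
#' @param min_block Minimum block length (bp) considered for chaining.
#' @param max_gap Maximum coordinate gap between consecutive blocks of one
#'   chain; larger gaps start a new chain id (backbone membership is
#'   unaffected). Default unlimited.
#' @return The blocks tibble, canonically sorted, with added columns
#'   `in_backbone` (logical) and `chain` (chain id or NA). The
#'   query-to-target partner map is attached as attribute `partners`.
#' @export
chain_syntenic <- function(blocks, min_block = 50, max_gap = Inf) {
  b <- arrange(blocks, .data$qname, .data$tname, .data$tstart, .data$tend,
               .data$qstart, .data$qend)
  b$in_backbone <- FALSE
  b$chain <- NA_integer_
  chain_id <- 0L
  groups <- split(seq_len(nrow(b)), paste(b$qname, b$tname, sep = "\r"))
  for (idx in groups) {
    sub <- b[idx, ]
    ok <- sub$strand == "+" & (sub$tend - sub$tstart) >= min_block
    cand <- idx[ok]
    if (length(cand) == 0) next
    s <- b[cand, ]
    n <- nrow(s)
    w <- s$tend - s$tstart
    best <- w            # best chain weight ending at i
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1)) {
        # collinear in both coordinates, non-overlapping
        if (s$tstart[i] >= s$tend[j] && s$qstart[i] >= s$qend[j]) {
          cand_w <- best[j] + w[i]
          if (cand_w > best[i]) {
            best[i] <- cand_w
            prev[i] <- j
          }
        }
      }
    }
    path <- which.max(best)
    members <- integer(0)
    while (!is.na(path)) {
      members <- c(path, members)
      path <- prev[path]
    }
    # split the chain wherever the gap exceeds max_gap
    chain_id <- chain_id + 1L
    ids <- rep(chain_id, length(members))
    if (is.finite(max_gap) && length(members) > 1) {
      m <- s[members, ]
      brk <- which(m$tstart[-1] - m$tend[-nrow(m)] > max_gap |
                     m$qstart[-1] - m$qend[-nrow(m)] > max_gap)
      for (x in brk) {
        chain_id <- chain_id + 1L
        ids[(x + 1):length(ids)] <- chain_id
      }
    }
    b$in_backbone[cand[members]] <- TRUE
    b$chain[cand[members]] <- ids
  }
  # the backbone is restricted to mutually best-covering chromosome pairs:
  # a lone cross-chromosome block can form a chain, but it is not synteny
  partners <- backbone_partners(b)
  is_partner <- paste(b$qname, b$tname, sep = "\r") %in%
    paste(partners$qname, partners$tname, sep = "\r")
  b$chain[b$in_backbone & !is_partner] <- NA_integer_
  b$in_backbone <- b$in_backbone & is_partner
  attr(b, "partners") <- partners
  b
}

# mutual best-coverage pairing of query and target chromosomes from the
# chained blocks
backbone_partners <- function(chained) {
  bb <- chained[chained$in_backbone, , drop = FALSE]
  if (nrow(bb) == 0) {
    return(tibble(qname = character(), tname = character()))
  }
  cov <- bb |>
    group_by(.data$qname, .data$tname) |>
    summarise(cov = sum(.data$tend - .data$tstart), .groups = "drop")
  best_q <- cov |> group_by(.data$qname) |>
    slice(which.max(.data$cov)) |> ungroup()
  best_t <- cov |> group_by(.data$tname) |>
    slice(which.max(.data$cov)) |> ungroup()
  dplyr::inner_join(best_q[, c("qname", "tname")],
                    best_t[, c("qname", "tname")],
                    by = c("qname", "tname"))
}

#' Classify structural variants between two haplotypes
#'
#' Classifies alignment blocks against the syntenic backbone into the five
#' SV classes:
#' * **INV** — minus-strand blocks embedded in a backbone chromosome pair;
#' * **TRANS** — blocks aligning a query chromosome to a target chromosome
#'   that is not its backbone partner;
#' * **DUP** — off-backbone plus-strand blocks whose target interval lies
#'   (>= 50% of its length) inside backbone-covered target sequence;
#' * **INS / DEL** — gaps between consecutive backbone blocks present on
#'   only the query (INS) or only the target (DEL) side.
#'
#' Overlapping candidates are resolved deterministically by precedence
#' INV > TRANS > DUP > INS/DEL, longest first; calls shorter than
#' `min_sv_len` are discarded (50 bp, inclusive).
#'
#' @param blocks Alignment blocks as from [read_paf()].
#' @param chains Output of [chain_syntenic()]; computed from `blocks` when
#'   `NULL`.
#' @param min_sv_len Minimum SV length (bp, inclusive).
#' @param dup_overlap Minimum fraction of a candidate duplication's target
#'   interval that must be backbone-covered.
#' @return A tibble of SV calls: `sv_type`, `qchrom`, `qstart`, `qend`,
#'   `tchrom`, `tstart`, `tend`, `length` (0-based half-open; INS/DEL have
#'   a degenerate interval on the absent side).
#' @export
classify_svs <- function(blocks, chains = NULL, min_sv_len = 50,
                         dup_overlap = 0.5) {
  if (is.null(chains)) chains <- chain_syntenic(blocks, min_block = min_sv_len)
  partners <- attr(chains, "partners")
  partner_of <- setNames(partners$tname, partners$qname)
  bb <- chains[chains$in_backbone, , drop = FALSE]
  cand <- list()
  add <- function(sv_type, qchrom, qstart, qend, tchrom, tstart, tend, length) {
    cand[[length(cand) + 1]] <<- tibble(
      sv_type = sv_type, qchrom = qchrom, qstart = qstart, qend = qend,
      tchrom = tchrom, tstart = tstart, tend = tend, length = length
    )
  }

  off <- chains[!chains$in_backbone, , drop = FALSE]
  for (i in seq_len(nrow(off))) {
    x <- off[i, ]
    tl <- x$tend - x$tstart
    p <- partner_of[x$qname]
    if (x$strand == "-") {
      add("INV", x$qname, x$qstart, x$qend, x$tname, x$tstart, x$tend, tl)
    } else if (is.na(p) || p != x$tname) {
      add("TRANS", x$qname, x$qstart, x$qend, x$tname, x$tstart, x$tend, tl)
    } else {
      # duplication test: target interval against backbone target coverage
      covt <- bb[bb$tname == x$tname, , drop = FALSE]
      u <- union_intervals(covt$tstart, covt$tend)
      ov <- sum(pmax(0, pmin(u$end, x$tend) - pmax(u$start, x$tstart)))
      if (tl > 0 && ov / tl >= dup_overlap) {
        add("DUP", x$qname, x$qstart, x$qend, x$tname, x$tstart, x$tend, tl)
      }
    }
  }

  # one-sided gaps between consecutive backbone blocks
  for (key in unique(paste(bb$qname, bb$tname, sep = "\r"))) {
    m <- bb[paste(bb$qname, bb$tname, sep = "\r") == key, , drop = FALSE]
    m <- arrange(m, .data$tstart)
    if (nrow(m) < 2) next
    for (i in seq_len(nrow(m) - 1)) {
      qgap <- m$qstart[i + 1] - m$qend[i]
      tgap <- m$tstart[i + 1] - m$tend[i]
      if (qgap >= min_sv_len && tgap < min_sv_len) {
        add("INS", m$qname[i], m$qend[i], m$qstart[i + 1],
            m$tname[i], m$tend[i], m$tend[i], qgap)
      } else if (tgap >= min_sv_len && qgap < min_sv_len) {
        add("DEL", m$qname[i], m$qend[i], m$qend[i],
            m$tname[i], m$tend[i], m$tstart[i + 1], tgap)
      }
    }
  }

  if (length(cand) == 0) {
    return(tibble(sv_type = character(), qchrom = character(),
                  qstart = numeric(), qend = numeric(), tchrom = character(),
                  tstart = numeric(), tend = numeric(), length = numeric()))
  }
  calls <- bind_rows(cand)
  calls <- calls[calls$length >= min_sv_len, , drop = FALSE]

  # precedence resolution: INV > TRANS > DUP > INS/DEL, longest first; a
  # candidate overlapping an accepted call on either coordinate system is
  # dropped
  prec <- c(INV = 4, TRANS = 3, DUP = 2, INS = 1, DEL = 1)
  calls <- calls[order(-prec[calls$sv_type], -calls$length, calls$tchrom,
                       calls$tstart, calls$qchrom, calls$qstart), ]
  accepted <- calls[0, ]
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    clash_q <- accepted$qchrom == x$qchrom &
      accepted$qstart < x$qend & x$qstart < accepted$qend
    clash_t <- accepted$tchrom == x$tchrom &
      accepted$tstart < x$tend & x$tstart < accepted$tend
    if (!any(clash_q | clash_t)) accepted <- bind_rows(accepted, x)
  }
  arrange(accepted, .data$tchrom, .data$tstart, .data$qchrom, .data$qstart)
}

#' Unaligned (nonhomologous) fraction of a region
#'
#' How much of a region is covered by no alignment block — on real sex
#' chromosomes, the W- or Z-specific sequence of the candidate pair.
#'
#' @param region One-row tibble or list with `chrom`, `start`, `end`.
#' @param blocks Alignment blocks as from [read_paf()].
#' @param coord Whether `region` is in query (`"query"`, default) or target
#'   coordinates.
#' @return One-row tibble: `unaligned_bp`, `percent` (full precision;
#'   reports round to 1 decimal).
#' @export
unaligned_fraction <- function(region, blocks, coord = c("query", "target")) {
  coord <- match.arg(coord)
  rlen <- region$end - region$start
  if (rlen <= 0) abort("region has non-positive length")
  if (coord == "query") {
    sel <- blocks$qname == region$chrom
    s <- blocks$qstart[sel]; e <- blocks$qend[sel]
  } else {
    sel <- blocks$tname == region$chrom
    s <- blocks$tstart[sel]; e <- blocks$tend[sel]
  }
  u <- union_intervals(pmax(s, region$start), pmin(e, region$end))
  u <- u[u$end > u$start, , drop = FALSE]
  covered <- sum(u$end - u$start)
  tibble(unaligned_bp = rlen - covered, percent = 100 * (rlen - covered) / rlen)
}

#' Fraction of the genome covered by structural-variant calls
#'
#' @param svcalls SV calls from [classify_svs()].
#' @param genome_len Genome length (bp, > 0).
#' @return Percent (full precision; reports round to 1 decimal).
#' @export
sv_genome_fraction <- function(svcalls, genome_len) {
  if (genome_len <= 0) abort("genome_len must be > 0")
  100 * sum(svcalls$length) / genome_len
}

#' Per-type SV count summary
#'
#' @param svcalls SV calls from [classify_svs()].
#' @return A tibble (`sv_type`, `n`, `total_len`).
#' @export
sv_type_summary <- function(svcalls) {
  svcalls |>
    group_by(.data$sv_type) |>
    summarise(n = n(), total_len = sum(.data$length), .groups = "drop") |>
    arrange(.data$sv_type)
}
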