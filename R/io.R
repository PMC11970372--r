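#' Read a FASTA file of chromosome sequences
#'
#' Sequences are upper-cased on read and record order is preserved, so
#' `write_fasta(read_fasta(x))` round-trips any FASTA after canonical
#' formatting (60-column wrapping, upper case).
#'
#' @param path Path to a FASTA file. IUPAC letters including `N` are accepted.
#' @return A tibble with one row per record: `id` (the full header line),
#'   `seq` (upper-case sequence) and `length` (bp).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty FASTA file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- names(set)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  tibble(id = ids, seq = unname(seqs), length = unname(nchar(seqs)))
}

#' Write chromosome records to FASTA
#'
#' Sequences are written upper-case, wrapped at 60 columns.
#'
#' @param records Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(toupper(records$seq), records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

paf_cols <- c(
  "qname", "qlen", "qstart", "qend", "strand",
  "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq"
)

#' Read alignment blocks from a PAF file
#'
#' Standard 12+ column PAF; optional SAM-style tag columns beyond the twelfth
#' are ignored. Coordinates are kept verbatim in PAF convention: 0-based,
#' half-open, with query coordinates of minus-strand blocks given on the
#' forward query strand.
#'
#' @param path Path to a PAF file.
#' @return A tibble of alignment blocks with columns `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`,
#'   `alen`, `mapq`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) abort(paste0("PAF file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      qname = character(), qlen = integer(), qstart = integer(),
      qend = integer(), strand = character(), tname = character(),
      tlen = integer(), tstart = integer(), tend = integer(),
      nmatch = integer(), alen = integer(), mapq = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 12L)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed PAF: line ", bad[1], " has ",
      length(fields[[bad[1]]]), " column(s), need >= 12"
    ))
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  strand <- m[, 5]
  strand[strand == "−"] <- "-"  # tolerate typographic minus
  if (!all(strand %in% c("+", "-"))) {
    abort(paste0("invalid strand at line ", which(!strand %in% c("+", "-"))[1]))
  }
  num <- function(j) as.numeric(m[, j])
  out <- tibble(
    qname = m[, 1], qlen = num(2), qstart = num(3), qend = num(4),
    strand = strand, tname = m[, 6], tlen = num(7), tstart = num(8),
    tend = num(9), nmatch = num(10), alen = num(11), mapq = num(12)
  )
  if (any(out$qend - out$qstart < 1) || any(out$tend - out$tstart < 1)) {
    abort("PAF block with non-positive interval length")
  }
  out
}

#' Write alignment blocks to PAF
#'
#' @param blocks Tibble as returned by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  stopifnot(all(paf_cols %in% names(blocks)))
  m <- blocks[, paf_cols]
  lines <- do.call(paste, c(lapply(m, function(x) format(x, scientific = FALSE, trim = TRUE)),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a windowed depth track (BED4)
#'
#' BED with 0-based half-open intervals and a fourth numeric column holding
#' the window mean depth. Depth values must be finite and non-negative.
#'
#' @param path Path to a 4-column BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_depth_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad) > 0) abort(paste0("malformed BED4 at line ", bad[1]))
  out <- tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.numeric(vapply(fields, `[`, "", 2L)),
    end   = as.numeric(vapply(fields, `[`, "", 3L)),
    depth = as.numeric(vapply(fields, `[`, "", 4L))
  )
  if (any(!is.finite(out$depth)) || any(out$depth < 0)) {
    abort("depth values must be finite and >= 0")
  }
  if (any(out$start < 0) || any(out$end <= out$start)) {
    abort("BED intervals must satisfy 0 <= start < end")
  }
  out
}

#' Write a windowed depth track to BED4
#' @param windows Tibble with `chrom`, `start`, `end`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(windows, path) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(windows)))
  lines <- sprintf(
    "%s\t%s\t%s\t%s",
    windows$chrom,
    format(windows$start, scientific = FALSE, trim = TRUE),
    format(windows$end, scientific = FALSE, trim = TRUE),
    format(windows$depth, scientific = FALSE, trim = TRUE)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene identifiers, the header row holds sample names.
#' The matrix must be rectangular with no missing or non-numeric cells.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("TSV file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("expression TSV needs a header row and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, 1L)
  if (length(unique(ncols)) != 1L) {
    abort(paste0("ragged TSV: line ", which(ncols != ncols[1])[1], " has ",
                 ncols[which(ncols != ncols[1])[1]], " columns, expected ", ncols[1]))
  }
  header <- fields[[1]]
  samples <- header[-1]
  genes <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(genes)) abort("duplicate gene ids in expression matrix")
  vals <- t(vapply(fields[-1], function(f) suppressWarnings(as.numeric(f[-1])),
                   numeric(length(samples))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  if (any(is.na(vals))) abort("NaN or non-numeric cell in expression matrix")
  out <- as_tibble(as.data.frame(vals))
  names(out) <- samples
  bind_cols_gene <- tibble(gene = genes)
  dplyr::bind_cols(bind_cols_gene, out)
}

#' Write a genes-by-samples expression matrix to TSV
#' @param mat Tibble with a `gene` column followed by sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(names(mat)[1] == "gene")
  header <- paste(c("gene", names(mat)[-1]), collapse = "\t")
  body <- do.call(paste, c(lapply(mat, function(x)
    if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else x), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write planted simulation truth
#'
#' The truth object is the recovery-test oracle: planted structural variants
#' (in both haplotype coordinate systems), collapsed intervals with copy
#' numbers, gap and telomere placements, the designated sex pair, and
#' coexpression-module membership. It serializes losslessly to JSON.
#'
#' @param path Path to a truth JSON file.
#' @return For `read_truth_json()`, a truth list (class `phasekit_truth`).
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) abort(paste0("truth JSON not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- raw
  for (nm in c("chrom_pairs", "svs", "gaps", "telomeres", "collapse")) {
    if (!is.null(truth[[nm]])) truth[[nm]] <- as_tibble(truth[[nm]])
  }
  validate_truth(truth)
  structure(truth, class = "phasekit_truth")
}

#' @rdname read_truth_json
#' @param truth A truth object as produced by [simulate_diploid_genome()].
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

validate_truth <- function(truth) {
  check_iv <- function(tbl, what) {
    if (is.null(tbl) || nrow(tbl) == 0) return(invisible())
    if (any(tbl$start < 0) || any(tbl$end <= tbl$start)) {
      abort(paste0("invalid interval in truth ", what, ": need 0 <= start < end"))
    }
  }
  check_iv(truth$gaps, "gaps")
  check_iv(truth$collapse, "collapse")
  if (!is.null(truth$svs) && nrow(truth$svs) > 0) {
    sv <- truth$svs
    if (any(sv$tend < sv$tstart) || any(sv$qend < sv$qstart)) {
      abort("invalid interval in truth svs")
    }
  }
  invisible(truth)
}

#' Convert between internal and report coordinates
#'
#' All internal coordinates in this package are 0-based half-open
#' (BED/PAF convention). Human-readable reports use 1-based inclusive
#' coordinates. These two functions are the only place the conversion
#' happens: `to_report_coords()` adds 1 to every `*start` column, and
#' `from_report_coords()` undoes it.
#'
#' @param tbl A tibble whose column names include `start`, `qstart` and/or
#'   `tstart` (with matching `end` columns).
#' @return The tibble with start coordinates shifted.
#' @export
to_report_coords <- function(tbl) {
  for (col in intersect(c("start", "qstart", "tstart"), names(tbl))) {
    tbl[[col]] <- tbl[[col]] + 1
  }
  tbl
}

#' @rdname to_report_coords
#' @export
from_report_coords <- function(tbl) {
  for (col in intersect(c("start", "qstart", "tstart"), names(tbl))) {
    tbl[[col]] <- tbl[[col]] - 1
  }
  tbl
}
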