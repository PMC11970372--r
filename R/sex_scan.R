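#' Sex-biased expressed genes inside nonhomologous regions
#'
#' Scans genes located inside the designated nonhomologous Z/W regions for
#' sex-specific expression in one tissue: a gene is called biased when its
#' expression in that tissue is at least `tau_on` in one sex and at most
#' `tau_off` in the other. Swapping the sex labels of the input swaps the
#' bias directions exactly.
#'
#' @param expr Long expression tibble (`gene`, `tissue`, `sex`, `tpm`);
#'   sexes are `"female"` and `"male"`.
#' @param regions Tibble (`chrom`, `start`, `end`) of nonhomologous
#'   regions, 0-based half-open.
#' @param positions Tibble (`gene`, `chrom`, `pos`); every scanned gene
#'   needs a position.
#' @param tau_on Minimum TPM of the expressed sex.
#' @param tau_off Maximum TPM of the silent sex.
#' @param tissue Tissue in which the contrast is evaluated; must occur in
#'   `expr`.
#' @return A tibble of biased genes: `gene`, `chrom`, `pos`,
#'   `expr_female`, `expr_male`, `bias` (`"female-biased"` or
#'   `"male-biased"`).
#' @export
sex_biased_genes <- function(expr, regions, positions, tau_on = 1.0,
                             tau_off = 0.1, tissue = "flower") {
  if (!tissue %in% unique(expr$tissue)) {
    abort(paste0("unknown tissue label: ", tissue))
  }
  stopifnot(all(c("gene", "tissue", "sex", "tpm") %in% names(expr)))
  in_region <- function(chrom, pos) {
    hit <- rep(FALSE, length(chrom))
    for (j in seq_len(nrow(regions))) {
      hit <- hit | (chrom == regions$chrom[j] & pos >= regions$start[j] &
                      pos < regions$end[j])
    }
    hit
  }
  pos_in <- positions[in_region(positions$chrom, positions$pos), , drop = FALSE]
  if (nrow(pos_in) == 0) {
    return(tibble(gene = character(), chrom = character(), pos = numeric(),
                  expr_female = numeric(), expr_male = numeric(),
                  bias = character()))
  }
  wide <- expr |>
    filter(.data$tissue == !!tissue, .data$gene %in% pos_in$gene) |>
    group_by(.data$gene, .data$sex) |>
    summarise(tpm = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sex", values_from = "tpm",
                       names_prefix = "expr_")
  out <- pos_in |>
    dplyr::inner_join(wide, by = "gene") |>
    mutate(bias = case_when(
      .data$expr_female >= tau_on & .data$expr_male <= tau_off ~ "female-biased",
      .data$expr_male >= tau_on & .data$expr_female <= tau_off ~ "male-biased",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$bias)) |>
    arrange(.data$gene)
  out[, c("gene", "chrom", "pos", "expr_female", "expr_male", "bias")]
}
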