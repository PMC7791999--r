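#' Pool allele counts across cells
#'
#' Sums reference- and variant-supporting read counts per locus over all
#' cells, emulating the pooled alignment in which biallelic candidate loci
#' are selected.
#'
#' @param counts Allele-count tibble (see [read_allele_counts()]).
#' @return A tibble with one row per locus: `chrom`, `pos`, `ref`, `alt`,
#'   `n_ref`, `n_var` (pooled sums).
#' @export
pool_allele_counts <- function(counts) {
  counts |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(n_ref = sum(.data$n_ref), n_var = sum(.data$n_var),
                     .groups = "drop")
}

#' Select biallelic loci from pooled counts
#'
#' A locus qualifies as confidently heterozygous when the pooled data carry
#' at least `min_reads_per_allele` reads supporting each of the reference
#' and the alternate allele (threshold inclusive). This deliberately drops
#' loci with strong monoallelic expression in the pool.
#'
#' @param pooled Output of [pool_allele_counts()].
#' @param min_reads_per_allele Minimum pooled reads per allele. Default 50.
#' @return Tibble of kept loci (`chrom`, `pos`, `ref`, `alt`).
#' @export
select_biallelic_loci <- function(pooled, min_reads_per_allele = 50) {
  keep <- pooled$n_ref >= min_reads_per_allele &
    pooled$n_var >= min_reads_per_allele
  pooled[keep, c("chrom", "pos", "ref", "alt")]
}

#' Build the loci-by-cells VAF_RNA matrix
#'
#' VAF_RNA = n_var / (n_var + n_ref) per (locus, cell). An entry is
#' "informative" when its total deduplicated coverage meets the minR
#' threshold (coverage >= minR); VAF is defined only there. (locus, cell)
#' pairs absent from the table count as zero coverage.
#'
#' @param counts Allele-count tibble.
#' @param cells Barcodes to include (the QC-passing cells of one
#'   (sample, cell type) group). Records for other cells are ignored.
#' @param loci Tibble of loci to include (e.g. from
#'   [select_biallelic_loci()]); `NULL` uses every locus in `counts`.
#' @param minR Minimum per-cell coverage for an informative VAF. Default 10.
#' @return A `vaf_matrix` object: list with `vaf`, `coverage`, `mask`
#'   (loci x cells matrices; rownames are locus ids), `loci` (tibble), and
#'   `cells`.
#' @export
build_vaf_matrix <- function(counts, cells, loci = NULL, minR = 10) {
  if (!is.numeric(minR) || minR < 1) stop_param("minR must be >= 1")
  if (is.null(loci)) {
    loci <- dplyr::distinct(counts[c("chrom", "pos", "ref", "alt")])
  }
  loci <- dplyr::arrange(loci, .data$chrom, .data$pos, .data$ref, .data$alt)
  ids <- locus_id(loci$chrom, loci$pos, loci$ref, loci$alt)
  cells <- as.character(cells)
  sub <- counts[counts$barcode %in% cells, , drop = FALSE]
  key <- locus_id(sub$chrom, sub$pos, sub$ref, sub$alt)
  sub <- sub[key %in% ids, , drop = FALSE]
  key <- key[key %in% ids]

  cov <- matrix(0L, nrow = length(ids), ncol = length(cells),
                dimnames = list(ids, cells))
  nv <- cov
  i <- match(key, ids)
  j <- match(sub$barcode, cells)
  idx <- cbind(i, j)
  cov[idx] <- sub$n_ref + sub$n_var
  nv[idx] <- sub$n_var
  mask <- cov >= minR
  vaf <- matrix(NA_real_, nrow = length(ids), ncol = length(cells),
                dimnames = list(ids, cells))
  vaf[mask] <- nv[mask] / cov[mask]
  structure(list(vaf = vaf, coverage = cov, mask = mask,
                 loci = dplyr::mutate(loci, locus_id = ids), cells = cells,
                 minR = minR),
            class = "vaf_matrix")
}

#' @export
print.vaf_matrix <- function(x, ...) {
  cat("VAF matrix:", nrow(x$vaf), "loci x", ncol(x$vaf), "cells; minR =",
      x$minR, "\n")
  cat("Informative entries:", sum(x$mask), "of", length(x$mask), "\n")
  invisible(x)
}

#' Subset a VAF matrix by loci and/or cells
#'
#' @param x A `vaf_matrix`.
#' @param i Locus ids (character) or indices.
#' @param j Barcodes (character) or indices.
#' @param ... Ignored.
#' @return A `vaf_matrix` restricted to the requested loci and cells.
#' @export
`[.vaf_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$vaf))
  if (missing(j)) j <- seq_len(ncol(x$vaf))
  if (is.character(i)) i <- match(i, rownames(x$vaf))
  if (is.character(j)) j <- match(j, x$cells)
  structure(list(vaf = x$vaf[i, j, drop = FALSE],
                 coverage = x$coverage[i, j, drop = FALSE],
                 mask = x$mask[i, j, drop = FALSE],
                 loci = x$loci[i, , drop = FALSE],
                 cells = x$cells[j], minR = x$minR),
            class = "vaf_matrix")
}

#' VAF variability bands
#'
#' The band definitions behind the non-variable-locus filter: a stable
#' biallelic band of 0.5 +/- 0.1, and monoallelic/skewed bands 0-0.25 and
#' 0.75-1. All intervals are closed. A locus is non-variable when strictly
#' more than `frac` of its informative VAFs fall in the stable band, or in
#' the union of the monoallelic bands.
#'
#' @param stable Closed interval for stable biallelic expression.
#'   Default `c(0.4, 0.6)`.
#' @param mono_low,mono_high Closed intervals for monoallelic/skewed
#'   expression. Defaults `c(0, 0.25)` and `c(0.75, 1)`.
#' @param frac Dominance fraction; removal requires strictly more than this
#'   fraction of informative VAFs in a band. Default 0.75.
#' @return A `vaf_bands` list.
#' @export
vaf_bands <- function(stable = c(0.4, 0.6), mono_low = c(0, 0.25),
                      mono_high = c(0.75, 1), frac = 0.75) {
  stopifnot(length(stable) == 2, length(mono_low) == 2, length(mono_high) == 2)
  if (frac <= 0 || frac >= 1) stop_param("frac must be in (0, 1)")
  structure(list(stable = stable, mono_low = mono_low, mono_high = mono_high,
                 frac = frac),
            class = "vaf_bands")
}

#' Filter non-variable VAF loci
#'
#' Removes loci dominated by stable biallelic expression (VAF in the stable
#' band) or by monoallelic/skewed expression (VAF near 0 or 1), keeping the
#' loci whose allelic fraction genuinely varies across cells. Fractions are
#' computed over informative entries only; loci with no informative entry
#' are removed. `mode = "strict"` instead keeps a locus only when more than
#' `frac` of its VAFs fall in the complementary variable bands
#' (0.25-0.4 or 0.6-0.75), an alternative, stricter reading of variability.
#'
#' @param m A `vaf_matrix`.
#' @param bands A [vaf_bands()] object.
#' @param mode `"exclusion"` (default: remove band-dominated loci) or
#'   `"strict"`.
#' @return Character vector of surviving locus ids, with attribute
#'   `removed`: a tibble of removed loci and the rule that removed each.
#' @export
filter_nonvariable_loci <- function(m, bands = vaf_bands(),
                                    mode = c("exclusion", "strict")) {
  mode <- match.arg(mode)
  in_band <- function(x, b) !is.na(x) & x >= b[1] & x <= b[2]
  n_inf <- rowSums(m$mask)
  n_stable <- rowSums(in_band(m$vaf, bands$stable))
  n_mono <- rowSums(in_band(m$vaf, bands$mono_low) |
                      in_band(m$vaf, bands$mono_high))
  frac_stable <- ifelse(n_inf > 0, n_stable / n_inf, 0)
  frac_mono <- ifelse(n_inf > 0, n_mono / n_inf, 0)
  if (mode == "exclusion") {
    rule <- dplyr::case_when(
      n_inf == 0 ~ "no_informative_cells",
      frac_stable > bands$frac ~ "stable_biallelic",
      frac_mono > bands$frac ~ "monoallelic_or_skewed",
      TRUE ~ NA_character_
    )
  } else {
    lo <- c(bands$mono_low[2], bands$stable[1])
    hi <- c(bands$stable[2], bands$mono_high[1])
    n_var_band <- rowSums(in_band(m$vaf, lo) | in_band(m$vaf, hi))
    frac_var <- ifelse(n_inf > 0, n_var_band / n_inf, 0)
    rule <- dplyr::case_when(
      n_inf == 0 ~ "no_informative_cells",
      frac_var < bands$frac ~ "not_variable_band_dominated",
      TRUE ~ NA_character_
    )
  }
  ids <- rownames(m$vaf)
  removed <- tibble(locus_id = ids[!is.na(rule)], rule = rule[!is.na(rule)])
  structure(ids[is.na(rule)], removed = removed)
}

#' Filter loci by informative-cell count
#'
#' A locus qualifies for correlation analysis only when its VAF is
#' informative in at least `min_cells` cells of the analysis group
#' (inclusive).
#'
#' @param m A `vaf_matrix`.
#' @param loci Candidate locus ids; default all loci in `m`.
#' @param min_cells Minimum informative cells. Default 20.
#' @return Character vector of surviving locus ids.
#' @export
filter_min_cells <- function(m, loci = rownames(m$vaf), min_cells = 20) {
  n_inf <- rowSums(m$mask[loci, , drop = FALSE])
  loci[n_inf >= min_cells]
}

#' Probability of chance variability under a binomial null
#'
#' The minimum-cells rule is justified by a binomial computation: if each
#' cell's VAF lands in the "variable" range independently with probability
#' `p`, the chance that at least `ceil(frac * n_cells)` of `n_cells` cells
#' do so by accident is `P(X >= ceil(frac * n))` for X ~ Binomial(n, p),
#' computed exactly. At the defaults this is 21700/2^20 ~= 0.0207 for 20
#' cells and 56/1024 = 0.0546875 for 10 cells; the probability decreases as
#' the number of cells grows.
#'
#' @param n_cells Number of cells (positive integer).
#' @param frac Required fraction of cells in the variable range.
#'   Default 0.75.
#' @param p Per-cell success probability under the null. Default 0.5.
#' @return The exact upper-tail binomial probability.
#' @examples
#' chance_variability_probability(20) # ~0.0206
#' chance_variability_probability(10) # 0.0546875
#' @export
chance_variability_probability <- function(n_cells, frac = 0.75, p = 0.5) {
  if (length(n_cells) != 1 || !is.numeric(n_cells) ||
      n_cells != round(n_cells) || n_cells < 1) {
    stop_param("n_cells must be a positive integer")
  }
  if (p <= 0 || p >= 1) stop_param("p must be in (0, 1)")
  k <- ceiling(frac * n_cells)
  pbinom(k - 1, n_cells, p, lower.tail = FALSE)
}
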