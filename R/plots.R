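#' Cell QC diagnostic plot
#'
#' Mitochondrial fraction and detected-gene count against total counts per
#' cell, with the threshold lines that the QC filter applies.
#'
#' @param metrics Tibble from [compute_cell_qc()].
#' @param thresholds A [qc_thresholds()] object drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_cell_qc <- function(metrics, thresholds = qc_thresholds()) {
  long <- tidyr::pivot_longer(metrics, c("mito_fraction", "n_genes"),
                              names_to = "metric", values_to = "value")
  cuts <- tibble(
    metric = c("mito_fraction", "n_genes", "n_genes"),
    value = c(thresholds$max_mito_fraction, thresholds$min_genes,
              thresholds$max_genes))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$total_counts, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_hline(data = cuts, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = thresholds$max_total_counts,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Total counts", y = NULL,
                  title = "Cell QC metrics and thresholds")
}

#' Per-locus VAF distribution plot
#'
#' Informative VAF values per locus, loci ordered by decreasing fraction of
#' cells with VAF below 0.2, with the stable and monoallelic bands shaded —
#' the view in which non-variable loci stand out.
#'
#' @param m A `vaf_matrix`.
#' @param bands A [vaf_bands()] object for the shaded regions.
#' @return A ggplot object.
#' @export
plot_vaf_distribution <- function(m, bands = vaf_bands()) {
  long <- tidy(m, informative_only = TRUE)
  ord <- long |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(frac_low = mean(.data$vaf < 0.2), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$frac_low))
  long$locus_id <- factor(long$locus_id, levels = ord$locus_id)
  shade <- tibble(ymin = c(bands$stable[1], bands$mono_low[1], bands$mono_high[1]),
                  ymax = c(bands$stable[2], bands$mono_low[2], bands$mono_high[2]),
                  band = c("stable", "monoallelic", "monoallelic"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus_id, y = .data$vaf)) +
    ggplot2::geom_rect(data = shade, inherit.aes = FALSE,
                       ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$band),
                       xmin = -Inf, xmax = Inf, alpha = 0.15) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.4, size = 0.6) +
    ggplot2::scale_fill_manual(values = c(stable = "steelblue",
                                          monoallelic = "firebrick")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6)) +
    ggplot2::labs(x = "SNV locus", y = "VAF_RNA",
                  title = "Per-cell VAF_RNA by locus")
}

#' QQ plot of scReQTL p-values
#'
#' Observed against expected -log10 p under the uniform null; a calibrated
#' analysis hugs the diagonal with departures only in the significant tail.
#'
#' @param object A `reqtl_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot reqtl_result
#' @export
autoplot.reqtl_result <- function(object, ...) {
  p <- sort(object$p_value[object$status == "ok"])
  df <- tibble(expected = -log10(stats::ppoints(length(p))),
               observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Expected -log10(p)", y = "Observed -log10(p)",
                  title = "scReQTL p-value QQ plot")
}

#' Permutation enrichment histogram
#'
#' Null distribution of overlap counts across permutations with the
#' observed overlap marked.
#'
#' @param object An `enrichment_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_overlap,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "Pairs found in interaction set",
                  y = "Permutations",
                  title = paste0("Permutation enrichment (observed = ",
                                 object$observed_overlap, ")"))
}

#' Scatter plot of one SNV-gene correlation
#'
#' Expression against VAF_RNA for the informative cells of one pair, with
#' the fitted marginal regression line — the standard view of a single
#' scReQTL.
#'
#' @param m A `vaf_matrix`.
#' @param norm A `normalized_expression`.
#' @param snv Locus id.
#' @param gene Gene id.
#' @return A ggplot object.
#' @export
plot_snv_gene <- function(m, norm, snv, gene) {
  vaf <- m$vaf[snv, ]
  expr <- norm$scaled[gene, m$cells]
  df <- tibble(vaf = vaf, expr = expr)[!is.na(vaf), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vaf, y = .data$expr)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "red") +
    ggplot2::labs(x = paste0("VAF_RNA (", snv, ")"),
                  y = paste0("Normalized expression (", gene, ")"),
                  title = paste(snv, "vs", gene))
}
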