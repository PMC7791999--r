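#' Per-cell quality-control metrics
#'
#' Computes, per cell, the total count, the number of detected genes, and the
#' fraction of counts attributable to a designated mitochondrial gene set.
#' All-zero cells get `mito_fraction = 0`; they fall to the QC filter later.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param mito_genes Character vector of mitochondrial gene ids; ids absent
#'   from the matrix are ignored with a message.
#' @return A tibble with columns `barcode`, `total_counts`, `n_genes`,
#'   `mito_fraction`.
#' @export
compute_cell_qc <- function(counts, mito_genes = character()) {
  absent <- setdiff(mito_genes, rownames(counts))
  if (length(absent) > 0) {
    inform(paste0(length(absent), " mitochondrial gene id(s) not in matrix; ignored"))
  }
  mito <- intersect(mito_genes, rownames(counts))
  total <- colSums(counts)
  mito_counts <- if (length(mito) > 0) {
    colSums(counts[mito, , drop = FALSE])
  } else rep(0, ncol(counts))
  tibble(
    barcode = colnames(counts),
    total_counts = as.integer(total),
    n_genes = as.integer(colSums(counts > 0)),
    mito_fraction = unname(ifelse(total > 0, mito_counts / total, 0))
  )
}

#' Cell quality-control thresholds
#'
#' Defaults remove cells with mitochondrial expression over 6%, fewer than
#' 3000 detected genes, more than 8000 detected genes, or more than 12,500
#' total UMI counts (the latter two target doublets/multiplets). All
#' comparisons are strict, so a cell sitting exactly on a boundary is kept.
#'
#' @param max_mito_fraction Remove cells with `mito_fraction` strictly above
#'   this. Default 0.06.
#' @param min_genes Remove cells with `n_genes` strictly below this.
#'   Default 3000.
#' @param max_genes Remove cells with `n_genes` strictly above this.
#'   Default 8000.
#' @param max_total_counts Remove cells with `total_counts` strictly above
#'   this. Default 12500.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.06, min_genes = 3000,
                          max_genes = 8000, max_total_counts = 12500) {
  if (min_genes >= max_genes) stop_param("min_genes must be < max_genes")
  if (max_mito_fraction <= 0 || min_genes <= 0 || max_total_counts <= 0) {
    stop_param("QC thresholds must be positive")
  }
  structure(list(max_mito_fraction = max_mito_fraction, min_genes = min_genes,
                 max_genes = max_genes, max_total_counts = max_total_counts),
            class = "qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' A cell is kept iff it violates none of the threshold rules; per-rule
#' removal counts are attached as the `"removed"` attribute (a tibble of
#' barcode and the first rule each cell failed).
#'
#' @param metrics Tibble from [compute_cell_qc()].
#' @param thresholds A [qc_thresholds()] object.
#' @return Character vector of kept barcodes, with attribute `removed`.
#' @export
filter_cells <- function(metrics, thresholds = qc_thresholds()) {
  th <- thresholds
  rule <- dplyr::case_when(
    metrics$mito_fraction > th$max_mito_fraction ~ "mito_fraction",
    metrics$n_genes < th$min_genes ~ "min_genes",
    metrics$n_genes > th$max_genes ~ "max_genes",
    metrics$total_counts > th$max_total_counts ~ "max_total_counts",
    TRUE ~ NA_character_
  )
  kept <- metrics$barcode[is.na(rule)]
  removed <- tibble(barcode = metrics$barcode[!is.na(rule)],
                    rule = rule[!is.na(rule)])
  if (length(kept) == 0) {
    stop_invalid("No cells survive QC; review thresholds (",
                 nrow(removed), " cells removed)")
  }
  if (nrow(removed) > 0) {
    counts <- table(removed$rule)
    inform(paste0("QC removed ", nrow(removed), " cell(s): ",
                  paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  structure(kept, removed = removed)
}

#' Normalize and scale an expression matrix
#'
#' Per-cell depth normalization to the median total count, `log1p`
#' transform, then per-gene centering and unit-variance scaling. Genes with
#' zero variance scale to all-zero rows. The pre-scaling (depth-normalized,
#' log) values are retained: the variable-gene range rule operates on them,
#' and planted-effect slopes are interpretable on that scale.
#'
#' @param counts QC-filtered genes x cells count matrix (>= 2 cells).
#' @return A `normalized_expression` object: list with `logcounts` (genes x
#'   cells, pre-scaling), `scaled` (genes x cells, z-scored), and
#'   `variable_genes` (initially `NULL`; see [select_variable_genes()]).
#' @export
normalize_expression <- function(counts) {
  if (ncol(counts) < 2) {
    stop_invalid("Normalization needs at least 2 cells (variance undefined)")
  }
  total <- colSums(counts)
  target <- median(total)
  size <- ifelse(total > 0, total / target, 1)
  logcounts <- log1p(sweep(counts, 2, size, "/"))
  mu <- rowMeans(logcounts)
  s <- apply(logcounts, 1, sd)
  scaled <- (logcounts - mu) / ifelse(s > 0, s, 1)
  scaled[s == 0, ] <- 0
  structure(list(logcounts = logcounts, scaled = scaled, variable_genes = NULL),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("Normalized expression:", nrow(x$logcounts), "genes x",
      ncol(x$logcounts), "cells\n")
  if (!is.null(x$variable_genes)) {
    cat("Variable genes:", length(x$variable_genes), "\n")
  }
  invisible(x)
}

#' Select variable genes by the range-tail rule
#'
#' A gene is removed when, in at least `frac_cells` of the cells, its
#' (pre-scaling) value lies within `frac_range` of the gene's own range from
#' the gene's minimum or from its maximum — i.e. genes saturated at their
#' floor or ceiling carry no usable variation. Constant genes (range 0) are
#' always removed. The rule is range-relative, so it is invariant to
#' per-gene affine transforms.
#'
#' @param norm A `normalized_expression` object.
#' @param frac_cells Removal threshold on the fraction of cells in the tails
#'   (inclusive). Default 0.80.
#' @param frac_range Tail width as a fraction of the per-gene range.
#'   Default 0.20.
#' @return Character vector of surviving gene ids.
#' @export
select_variable_genes <- function(norm, frac_cells = 0.80, frac_range = 0.20) {
  x <- norm$logcounts
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  rng <- hi - lo
  in_tail <- (x <= lo + frac_range * rng) | (x >= hi - frac_range * rng)
  tail_frac <- rowMeans(in_tail)
  keep <- rng > 0 & tail_frac < frac_cells
  rownames(x)[keep]
}

#' Principal-component covariates of gene expression
#'
#' Computes per-cell scores of the top `k` principal components of the
#' scaled expression of the variable genes, used as covariates in the
#' SNV-gene regressions to absorb global expression structure. Scores come
#' from the singular-value decomposition of the gene-centered matrix; each
#' component's sign is fixed by making its largest-magnitude gene loading
#' positive, so results are deterministic. If `k` exceeds the matrix rank it
#' is reduced with a warning.
#'
#' @param norm A `normalized_expression` object.
#' @param k Number of components. Default 15.
#' @param genes Genes to use; defaults to `norm$variable_genes`, falling
#'   back to all genes.
#' @return Cells x k numeric matrix of scores (rownames = barcodes,
#'   colnames `PC1..PCk`).
#' @export
compute_pc_covariates <- function(norm, k = 15, genes = NULL) {
  genes <- genes %||% norm$variable_genes %||% rownames(norm$scaled)
  x <- t(norm$scaled[genes, , drop = FALSE])  # cells x genes
  if (k >= min(dim(x))) {
    warn(paste0("k = ", k, " >= min(genes, cells); reducing"))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  tol <- pc$sdev[1] * 1e-8
  rank <- sum(pc$sdev > tol)
  if (k > rank) {
    warn(paste0("Requested ", k, " components but rank is ", rank,
                "; returning ", rank))
    k <- rank
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(norm$scaled)
  scores
}
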