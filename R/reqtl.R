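#' Fit one SNV-gene linear model
#'
#' Ordinary least squares of normalized expression on an intercept, the
#' VAF, and the covariates, restricted to the cells where the VAF is
#' informative (complete-case; VAF dropouts are structural at minR and are
#' never imputed). The reported effect is the VAF coefficient, with a
#' two-sided p from the t distribution on `n - (k + 2)` degrees of freedom
#' (k = number of covariates).
#'
#' @param vaf Numeric VAF vector, `NA` at masked (uninformative) cells.
#' @param expr Numeric expression vector, same cells in the same order.
#' @param covars Optional cells x k covariate matrix (same cell order), e.g.
#'   from [compute_pc_covariates()].
#' @param min_cells Minimum informative cells to attempt the fit.
#'   Default 20.
#' @return One-row tibble: `beta`, `t_stat`, `p_value`, `n_cells`, `status`
#'   (`"ok"` or a skip reason; statistics are `NA` for skipped fits).
#' @export
fit_snv_gene <- function(vaf, expr, covars = NULL, min_cells = 20) {
  f <- fit_core(vaf, expr, covars, min_cells)
  tibble(beta = f$beta, t_stat = f$t_stat, p_value = f$p_value,
         n_cells = f$n_cells, status = f$status)
}

# QR-based OLS of expr on [1, vaf, covars]; returns a plain list so the
# all-pairs loop avoids per-fit tibble overhead.
fit_core <- function(vaf, expr, covars = NULL, min_cells = 20) {
  use <- which(!is.na(vaf) & !is.na(expr))
  n <- length(use)
  skip <- function(reason) list(beta = NA_real_, t_stat = NA_real_,
                                p_value = NA_real_, n_cells = n,
                                status = reason)
  if (n < min_cells) return(skip("insufficient cells"))
  v <- vaf[use]
  if (max(v) == min(v)) return(skip("degenerate regressor"))
  x <- if (is.null(covars)) {
    cbind(1, v)
  } else {
    cbind(1, v, covars[use, , drop = FALSE])
  }
  df <- n - ncol(x)
  if (df <= 0) return(skip("insufficient cells for covariates"))
  y <- expr[use]
  qf <- qr(x)
  if (qf$rank < ncol(x)) {
    # rank-deficient design: drop dependent columns, keep intercept + VAF
    keep <- qf$pivot[seq_len(qf$rank)]
    if (!all(c(1L, 2L) %in% keep)) return(skip("degenerate regressor"))
    x <- x[, sort(keep), drop = FALSE]
    df <- n - ncol(x)
    if (df <= 0) return(skip("insufficient cells for covariates"))
    qf <- qr(x)
  }
  coefs <- qr.coef(qf, y)
  res <- y - drop(x %*% coefs)
  s2 <- sum(res^2) / df
  Ri <- backsolve(qr.R(qf), diag(ncol(x)))
  pos <- match(2L, qf$pivot)  # VAF column under any pivoting
  se <- sqrt(s2 * sum(Ri[pos, ]^2))
  beta <- unname(coefs[2L])
  t_stat <- beta / se
  list(beta = beta, t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df),
       n_cells = n, status = "ok")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment under independence or positive dependence,
#' returned in input order. Thin, validated front to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Run all SNV-gene correlations for one analysis group
#'
#' Tests every surviving locus against every variable gene within one
#' (sample, cell type) group: per-pair OLS of expression on VAF with the PC
#' covariates, then BH FDR across the group's valid tests. No significance
#' threshold is applied here; records are returned for every pair (skipped
#' fits carry their reason and `NA` statistics). Rows are ordered by
#' (q, snv, gene).
#'
#' @param m A `vaf_matrix` restricted to the group's cells, already
#'   locus-filtered.
#' @param norm A `normalized_expression` on the same cells.
#' @param covars Cells x k covariate matrix (or `NULL`), same cells.
#' @param group Named character vector `c(sample_id = , cell_type = )`.
#' @param genes Genes to test; default `norm$variable_genes`.
#' @param loci Locus ids to test; default all loci of `m`.
#' @param min_cells Minimum informative cells per fit. Default 20.
#' @return A `reqtl_result` tibble: `snv`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `beta`, `t_stat`, `p_value`, `q_value`, `n_cells`, `status`,
#'   `sample_id`, `cell_type`.
#' @export
run_reqtl <- function(m, norm, covars = NULL,
                      group = c(sample_id = "sample", cell_type = "all"),
                      genes = NULL, loci = NULL, min_cells = 20) {
  genes <- genes %||% norm$variable_genes %||% rownames(norm$scaled)
  loci <- loci %||% rownames(m$vaf)
  cells <- m$cells
  stopifnot(all(cells %in% colnames(norm$scaled)))
  expr <- norm$scaled[, cells, drop = FALSE]
  if (!is.null(covars)) covars <- covars[cells, , drop = FALSE]
  if (length(loci) == 0 || length(genes) == 0) {
    warn("Empty locus or gene set; returning no records")
  }
  grid <- tidyr::expand_grid(snv = loci, gene_id = genes)
  np <- nrow(grid)
  beta <- t_stat <- p_value <- rep(NA_real_, np)
  n_cells <- integer(np)
  status <- character(np)
  for (r in seq_len(np)) {
    f <- fit_core(m$vaf[grid$snv[r], cells], expr[grid$gene_id[r], ],
                  covars, min_cells = min_cells)
    beta[r] <- f$beta; t_stat[r] <- f$t_stat; p_value[r] <- f$p_value
    n_cells[r] <- f$n_cells; status[r] <- f$status
  }
  out <- dplyr::bind_cols(grid["snv"],
                          if (np > 0) parse_locus_id(grid$snv) else
                            tibble(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0)),
                          grid["gene_id"])
  out$beta <- beta; out$t_stat <- t_stat; out$p_value <- p_value
  out$q_value <- NA_real_
  ok <- status == "ok"
  if (any(ok)) out$q_value[ok] <- bh_fdr(p_value[ok])
  out$n_cells <- n_cells
  out$status <- status
  out$sample_id <- unname(group[["sample_id"]])
  out$cell_type <- unname(group[["cell_type"]])
  out <- dplyr::arrange(out, is.na(.data$q_value), .data$q_value, .data$snv,
                        .data$gene_id)
  class(out) <- c("reqtl_result", class(out))
  out
}

#' Annotate cis/trans classes by gene residence
#'
#' A pair is cis when the SNV locus lies within the transcribed interval of
#' the correlated gene (chromosome match and `start <= pos <= end`, closed;
#' strand ignored); every other pair is trans. Records whose gene has no
#' model are flagged `NA` (unannotated), never dropped.
#'
#' @param records A `reqtl_result` tibble (needs `chrom`, `pos`, `gene_id`).
#' @param gene_models Tibble from [read_gene_models()].
#' @return The records with a `cls` column (`"cis"`, `"trans"`, or `NA`).
#' @export
annotate_cis_trans <- function(records, gene_models) {
  gm <- gene_models[c("gene_id", "chrom", "start", "end")]
  names(gm) <- c("gene_id", "gene_chrom", "gene_start", "gene_end")
  old_class <- class(records)
  out <- dplyr::left_join(as_tibble(records), gm, by = "gene_id")
  if (anyNA(out$gene_start)) {
    miss <- unique(out$gene_id[is.na(out$gene_start)])
    warn(paste0(length(miss), " gene(s) without a model left unannotated: ",
                paste(head(miss, 3), collapse = ", ")))
  }
  out$cls <- ifelse(
    is.na(out$gene_start), NA_character_,
    ifelse(out$chrom == out$gene_chrom & out$pos >= out$gene_start &
             out$pos <= out$gene_end, "cis", "trans"))
  out <- out[setdiff(names(out), c("gene_chrom", "gene_start", "gene_end"))]
  class(out) <- old_class
  out
}
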