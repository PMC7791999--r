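#' Pipeline parameters
#'
#' One object holding every tunable threshold of the workflow, at the
#' method's defaults: pooled biallelic selection at 50 reads per allele,
#' informative coverage at minR = 10, at least 20 informative cells per
#' locus, the 75% variability bands, QC thresholds, 15 PC covariates, and a
#' 0.05 FDR for downstream significance calls.
#'
#' @param min_reads_per_allele Pooled reads per allele for biallelic loci.
#' @param minR Minimum per-cell coverage for an informative VAF.
#' @param min_cells Minimum informative cells per locus and per fit.
#' @param bands [vaf_bands()] for the variability filter.
#' @param qc [qc_thresholds()] for cell filtering.
#' @param n_pcs Number of expression PCs used as covariates.
#' @param fdr Significance threshold on q-values.
#' @param frac_cells,frac_range Variable-gene rule parameters.
#' @param n_perm Permutations for the optional enrichment test.
#' @param seed Seed for the enrichment permutations.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(min_reads_per_allele = 50, minR = 10,
                            min_cells = 20, bands = vaf_bands(),
                            qc = qc_thresholds(), n_pcs = 15, fdr = 0.05,
                            frac_cells = 0.8, frac_range = 0.2,
                            n_perm = 10000, seed = 1) {
  structure(list(min_reads_per_allele = min_reads_per_allele, minR = minR,
                 min_cells = min_cells, bands = bands, qc = qc,
                 n_pcs = n_pcs, fdr = fdr, frac_cells = frac_cells,
                 frac_range = frac_range, n_perm = n_perm, seed = seed),
            class = "pipeline_params")
}

# First gene model containing each SNV position (NA if none).
locate_snv_genes <- function(loci, gene_models) {
  vapply(seq_len(nrow(loci)), function(i) {
    hit <- gene_models$chrom == loci$chrom[i] &
      gene_models$start <= loci$pos[i] & gene_models$end >= loci$pos[i]
    if (any(hit)) gene_models$gene_id[which(hit)[1]] else NA_character_
  }, character(1))
}

#' Gene pairs implied by significant scReQTLs
#'
#' Maps each significant record to the unordered pair (gene harboring the
#' SNV, correlated gene), the unit intersected with known gene-gene
#' interaction sets. Records whose SNV falls in no modeled gene, and cis
#' records (self-pairs), are dropped.
#'
#' @param results A `reqtl_result` with q-values.
#' @param gene_models Gene model tibble.
#' @param fdr Keep records with `q_value <= fdr`. Default 0.05.
#' @return A canonical pair tibble (`gene_a`, `gene_b`).
#' @export
snv_gene_pairs <- function(results, gene_models, fdr = 0.05) {
  sig <- results[!is.na(results$q_value) & results$q_value <= fdr, ,
                 drop = FALSE]
  if (nrow(sig) == 0) return(tibble(gene_a = character(0), gene_b = character(0)))
  harbor <- locate_snv_genes(sig, gene_models)
  ok <- !is.na(harbor) & harbor != sig$gene_id
  if (!any(ok)) return(tibble(gene_a = character(0), gene_b = character(0)))
  canonical_pairs(tibble(gene_a = harbor[ok], gene_b = sig$gene_id[ok]))
}

#' Run the scReQTL workflow end to end
#'
#' For each (sample, cell type) group: cell QC, normalization,
#' variable-gene selection, PC covariates, pooled biallelic locus selection
#' (pooled over all cells of the sample, before QC), VAF matrix at minR,
#' variability and minimum-cells filters, per-pair regression, BH FDR, and
#' cis/trans annotation; optionally, permutation enrichment of the
#' significant trans gene pairs against a known-interaction set. Every
#' removal decision (cell or locus, with its rule) is collected in an audit
#' table, and a per-group summary records survivor counts at each stage.
#'
#' Groups with fewer than `n_pcs + min_cells` cells are skipped with a
#' warning rather than aborting the run.
#'
#' @param allele_counts Allele-count tibble ([read_allele_counts()]).
#' @param expression Genes x cells count matrix
#'   ([read_expression_matrix()]).
#' @param gene_models Gene model tibble ([read_gene_models()]).
#' @param cell_annotations Tibble ([read_cell_annotations()]).
#' @param interactions Optional interaction pair tibble
#'   ([read_interactions()]); enables the enrichment test.
#' @param params A [pipeline_params()] object.
#' @param mito_genes Mitochondrial gene ids for QC. Default: gene ids
#'   starting `"MT-"`.
#' @param out_dir If non-NULL, write `reqtl.tsv`, `summary.tsv`,
#'   `audit.tsv` there.
#' @return An `screqtl_run` list: `results` (combined annotated
#'   `reqtl_result`), `summary` (per-group stage counts), `audit` (removal
#'   log), `enrichment` (an `enrichment_result` or `NULL`), `params`.
#' @export
run_screqtl_pipeline <- function(allele_counts, expression, gene_models,
                                 cell_annotations, interactions = NULL,
                                 params = pipeline_params(),
                                 mito_genes = grep("^MT-", rownames(expression),
                                                   value = TRUE),
                                 out_dir = NULL) {
  ann <- cell_annotations
  unknown <- setdiff(colnames(expression), ann$barcode)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown),
                " expression barcode(s) missing from annotations; dropped"))
  }
  ann <- ann[ann$barcode %in% colnames(expression), , drop = FALSE]

  audit <- list()
  summaries <- list()
  results <- list()

  for (smp in unique(ann$sample_id)) {
    smp_ann <- ann[ann$sample_id == smp, , drop = FALSE]
    smp_expr <- expression[, smp_ann$barcode, drop = FALSE]
    smp_counts <- allele_counts[allele_counts$barcode %in% smp_ann$barcode, ,
                                drop = FALSE]
    # pooled over all cells of the sample, before cell QC
    pooled <- pool_allele_counts(smp_counts)
    biallelic <- select_biallelic_loci(pooled, params$min_reads_per_allele)
    dropped_pool <- dplyr::anti_join(pooled, biallelic,
                                     by = c("chrom", "pos", "ref", "alt"))
    if (nrow(dropped_pool) > 0) {
      audit[[length(audit) + 1]] <- tibble(
        sample_id = smp, cell_type = NA_character_, entity = "locus",
        id = locus_id(dropped_pool$chrom, dropped_pool$pos,
                      dropped_pool$ref, dropped_pool$alt),
        rule = "pooled_biallelic")
    }
    qc <- compute_cell_qc(smp_expr, mito_genes)
    kept_cells <- filter_cells(qc, params$qc)
    rm_cells <- attr(kept_cells, "removed")
    if (nrow(rm_cells) > 0) {
      audit[[length(audit) + 1]] <- tibble(
        sample_id = smp, cell_type = NA_character_, entity = "cell",
        id = rm_cells$barcode, rule = rm_cells$rule)
    }

    for (ct in unique(smp_ann$cell_type)) {
      cells <- intersect(kept_cells,
                         smp_ann$barcode[smp_ann$cell_type == ct])
      if (length(cells) < params$n_pcs + params$min_cells) {
        warn(paste0("Group ", smp, ":", ct, " has ", length(cells),
                    " cells (< n_pcs + min_cells); skipped"))
        next
      }
      norm <- normalize_expression(smp_expr[, cells, drop = FALSE])
      norm$variable_genes <- select_variable_genes(norm, params$frac_cells,
                                                   params$frac_range)
      if (length(norm$variable_genes) == 0) {
        warn(paste0("Group ", smp, ":", ct, " has no variable genes; skipped"))
        next
      }
      covars <- compute_pc_covariates(norm, k = params$n_pcs)
      vm <- build_vaf_matrix(smp_counts, cells, biallelic, params$minR)
      variable_loci <- filter_nonvariable_loci(vm, params$bands)
      rm_loci <- attr(variable_loci, "removed")
      if (nrow(rm_loci) > 0) {
        audit[[length(audit) + 1]] <- tibble(
          sample_id = smp, cell_type = ct, entity = "locus",
          id = rm_loci$locus_id, rule = rm_loci$rule)
      }
      final_loci <- filter_min_cells(vm, variable_loci, params$min_cells)
      dropped_few <- setdiff(variable_loci, final_loci)
      if (length(dropped_few) > 0) {
        audit[[length(audit) + 1]] <- tibble(
          sample_id = smp, cell_type = ct, entity = "locus",
          id = dropped_few, rule = "min_cells")
      }
      summaries[[length(summaries) + 1]] <- tibble(
        sample_id = smp, cell_type = ct,
        n_cells_input = sum(smp_ann$cell_type == ct),
        n_cells_qc = length(cells),
        n_genes_input = nrow(smp_expr),
        n_genes_variable = length(norm$variable_genes),
        n_loci_input = nrow(dplyr::distinct(
          smp_counts[c("chrom", "pos", "ref", "alt")])),
        n_loci_biallelic = nrow(biallelic),
        n_loci_variable = length(variable_loci),
        n_loci_final = length(final_loci),
        n_screqtl = NA_integer_)
      if (length(final_loci) == 0) {
        warn(paste0("Group ", smp, ":", ct,
                    " has no loci after filtering; no tests run"))
        next
      }
      res <- run_reqtl(vm[final_loci, cells], norm, covars,
                       group = c(sample_id = smp, cell_type = ct),
                       min_cells = params$min_cells)
      res <- annotate_cis_trans(res, gene_models)
      summaries[[length(summaries)]]$n_screqtl <-
        sum(!is.na(res$q_value) & res$q_value <= params$fdr)
      results[[length(results) + 1]] <- res
    }
  }

  combined <- if (length(results) > 0) {
    out <- dplyr::bind_rows(lapply(results, as_tibble))
    class(out) <- c("reqtl_result", class(out))
    out
  } else {
    warn("No group produced results")
    tibble()
  }
  summary_tbl <- dplyr::bind_rows(summaries)
  audit_tbl <- if (length(audit) > 0) dplyr::bind_rows(audit) else
    tibble(sample_id = character(0), cell_type = character(0),
           entity = character(0), id = character(0), rule = character(0))

  enr <- NULL
  if (!is.null(interactions) && nrow(combined) > 0) {
    pairs <- snv_gene_pairs(combined, gene_models, params$fdr)
    if (nrow(pairs) > 0) {
      universe <- union(unique(combined$gene_id),
                        stats::na.omit(locate_snv_genes(
                          dplyr::distinct(combined[c("chrom", "pos")]),
                          gene_models)))
      enr <- permutation_enrichment(pairs, universe, interactions,
                                    n_perm = params$n_perm,
                                    seed = params$seed)
    } else {
      inform("No significant trans gene pairs; enrichment skipped")
    }
  }

  run <- structure(list(results = combined, summary = summary_tbl,
                        audit = audit_tbl, enrichment = enr,
                        params = params),
                   class = "screqtl_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(combined) > 0) {
      write_reqtl_table(combined, file.path(out_dir, "reqtl.tsv"))
    }
    readr::write_tsv(summary_tbl, file.path(out_dir, "summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(audit_tbl, file.path(out_dir, "audit.tsv"),
                     progress = FALSE)
  }
  run
}

#' @export
print.screqtl_run <- function(x, ...) {
  cat("scReQTL run:", nrow(x$summary), "group(s),",
      nrow(x$results), "tested pair-records\n")
  if (nrow(x$results) > 0) {
    sig <- sum(!is.na(x$results$q_value) &
                 x$results$q_value <= x$params$fdr)
    cat("Significant at q <=", x$params$fdr, ":", sig, "\n")
  }
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}
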