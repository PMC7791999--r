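# Fixture builders shared across test files. All randomness is seeded by the
# caller so fixtures are reproducible.

# Random allele-count table over n_loci x n_cells with a given observation
# probability; counts Poisson around `mean_cov` split binomially.
random_allele_table <- function(n_loci = 10, n_cells = 8, p_obs = 0.8,
                                mean_cov = 20) {
  grid <- expand.grid(locus = seq_len(n_loci), cell = seq_len(n_cells))
  grid <- grid[runif(nrow(grid)) < p_obs, , drop = FALSE]
  cov <- rpois(nrow(grid), mean_cov)
  nv <- rbinom(nrow(grid), cov, runif(nrow(grid), 0.2, 0.8))
  tibble::tibble(
    chrom = paste0("chr", 1 + (grid$locus %% 3)),
    pos = 1000L + grid$locus * 7L,
    ref = "A", alt = "G",
    barcode = sprintf("BC%03d", grid$cell),
    n_ref = as.integer(cov - nv), n_var = as.integer(nv))
}

# VAF matrix built directly from per-locus VAF vectors (full coverage).
vaf_matrix_from_values <- function(vaf_rows, coverage = 50, minR = 10) {
  n_cells <- length(vaf_rows[[1]])
  cells <- sprintf("BC%03d", seq_len(n_cells))
  recs <- lapply(seq_along(vaf_rows), function(i) {
    v <- vaf_rows[[i]]
    cov <- rep(coverage, n_cells)
    tibble::tibble(chrom = "chr1", pos = 100L + i * 10L,
                   ref = "A", alt = "G", barcode = cells,
                   n_ref = as.integer(cov - round(cov * v)),
                   n_var = as.integer(round(cov * v)))
  })
  counts <- dplyr::bind_rows(recs)
  screqtl::build_vaf_matrix(counts, cells, minR = minR)
}

# Minimal GTF file for gene-model tests; returns its path.
write_test_gtf <- function(path, genes) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$chrom[i], "test", "gene", genes$start[i], genes$end[i], ".",
          genes$strand[i], ".",
          sprintf('gene_id "%s"; gene_name "%s";',
                  genes$gene_id[i], genes$gene_name[i]),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
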