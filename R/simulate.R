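#' Configuration for the synthetic scReQTL dataset generator
#'
#' Defines a complete in-silico study: per-(locus, cell) sequencing coverage
#' (negative binomial with dropout), latent per-cell allelic fractions drawn
#' around per-locus archetype means (stable biallelic at 0.5; monoallelic or
#' skewed at 0.05 / 0.95; variable with a locus mean spread over
#' 0.25-0.75), observed allele counts binomial in the latent VAF, log-normal
#' baseline expression, and planted linear VAF-to-log-expression effects.
#' Archetypes are assigned deterministically by locus index (stable loci
#' first, then monoallelic, then variable), so planted effects can target
#' variable loci by index.
#'
#' @param n_cells,n_genes,n_loci Dataset dimensions.
#' @param archetype_props Named proportions of `stable`, `monoallelic`,
#'   `variable` loci; must sum to 1.
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   for per-(locus, cell) total reads.
#' @param dropout_rate Probability that a (locus, cell) pair is unobserved.
#' @param vaf_concentration Named beta-concentration per archetype of the
#'   per-cell latent VAF around the locus mean (larger = tighter).
#' @param planted_effects Tibble with columns `locus` (index), `gene`
#'   (index), `beta` (slope on log expression per unit VAF), `noise_sd`.
#' @param expression_meanlog,expression_sdlog Log-normal parameters of the
#'   per-gene baseline expression level.
#' @param noise_sd Per-(gene, cell) Gaussian noise on log expression for
#'   unplanted genes.
#' @param n_cell_types Number of cell types; cells split evenly, each type
#'   generated with the same machinery.
#' @param sample_id Donor label for the cell annotations.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 200, n_genes = 100, n_loci = 20,
                       archetype_props = c(stable = 0.5, monoallelic = 0.25,
                                           variable = 0.25),
                       coverage_mean = 25, coverage_dispersion = 5,
                       dropout_rate = 0.1,
                       vaf_concentration = c(stable = 200, monoallelic = 20,
                                             variable = 2),
                       planted_effects = NULL,
                       expression_meanlog = 4, expression_sdlog = 0.5,
                       noise_sd = 0.5, n_cell_types = 1,
                       sample_id = "S1", seed = 1) {
  if (abs(sum(archetype_props) - 1) > 1e-8) {
    stop_param("archetype_props must sum to 1")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_param("dropout_rate must be in [0, 1]")
  }
  if (coverage_mean <= 0 || coverage_dispersion <= 0) {
    stop_param("Coverage parameters must be positive")
  }
  need <- c("stable", "monoallelic", "variable")
  if (!all(need %in% names(archetype_props)) ||
      !all(need %in% names(vaf_concentration))) {
    stop_param("archetype_props and vaf_concentration need names ",
               paste(need, collapse = ", "))
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble(locus = integer(0), gene = integer(0),
                              beta = numeric(0), noise_sd = numeric(0))
  }
  structure(list(n_cells = n_cells, n_genes = n_genes, n_loci = n_loci,
                 archetype_props = archetype_props,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 dropout_rate = dropout_rate,
                 vaf_concentration = vaf_concentration,
                 planted_effects = as_tibble(planted_effects),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 noise_sd = noise_sd, n_cell_types = n_cell_types,
                 sample_id = sample_id, seed = seed),
            class = "sim_config")
}

# Deterministic archetype assignment by locus index.
sim_archetypes <- function(config) {
  n <- config$n_loci
  n_stable <- round(config$archetype_props[["stable"]] * n)
  n_mono <- round(config$archetype_props[["monoallelic"]] * n)
  n_mono <- min(n_mono, n - n_stable)
  rep(c("stable", "monoallelic", "variable"),
      c(n_stable, n_mono, n - n_stable - n_mono))
}

#' Generate a complete synthetic scReQTL dataset
#'
#' Emits every input the pipeline reads — per-cell allele counts, a
#' genes x cells expression count matrix, gene models tiling a toy
#' chromosome (each locus placed inside a harboring gene so cis pairs
#' exist), and cell annotations — plus a ground-truth ledger of locus
#' archetypes, latent per-cell VAFs, and planted SNV-gene slopes.
#'
#' Generative model, per cell type: locus archetype means are 0.5
#' (stable), 0.05 or 0.95 alternating (monoallelic/skewed), or uniform on
#' 0.25-0.75 (variable); per-cell latent VAF ~ Beta(mean, concentration);
#' total coverage ~ NegBinom(mean, size), set to 0 with probability
#' `dropout_rate`; n_var ~ Binomial(coverage, latent VAF); log expression =
#' gene baseline + planted beta x latent VAF + Gaussian noise, exponentiated
#' and rounded to a count.
#'
#' @param config A [sim_config()].
#' @return A list: `allele_counts` (tibble), `expression` (genes x cells
#'   matrix), `gene_models` (tibble), `cell_annotations` (tibble), `truth`
#'   (list with `archetypes`, `planted`, `latent_vaf`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- sim_archetypes(config)
  pe <- config$planted_effects
  if (nrow(pe) > 0) {
    if (any(pe$locus < 1 | pe$locus > config$n_loci) ||
        any(pe$gene < 1 | pe$gene > config$n_genes)) {
      stop_param("Planted effect indices out of range")
    }
    if (any(arch[pe$locus] == "monoallelic")) {
      stop_param("Planted effect targets a monoallelic locus; ",
                 "its VAF carries no variation to detect")
    }
  }
  set.seed(config$seed)

  n_types <- config$n_cell_types
  type_of <- sort(rep_len(paste0("type", seq_len(n_types)), config$n_cells))
  barcodes <- sprintf("cell_%04d", seq_len(config$n_cells))

  gene_ids <- sprintf("G%03d", seq_len(config$n_genes))
  # genes tile a toy chromosome; locus l sits inside gene ((l-1) %% n_genes) + 1
  gene_start <- (seq_len(config$n_genes) - 1L) * 1000L + 1L
  gene_models <- tibble(gene_id = gene_ids, gene_name = gene_ids,
                        chrom = "chrS", start = gene_start,
                        end = gene_start + 799L,
                        strand = rep(c("+", "-"),
                                     length.out = config$n_genes))
  harbor <- ((seq_len(config$n_loci) - 1L) %% config$n_genes) + 1L
  loci <- tibble(chrom = "chrS",
                 pos = gene_start[harbor] + 100L + (seq_len(config$n_loci) - 1L) %/%
                   config$n_genes,
                 ref = "A", alt = "G")
  locus_ids <- locus_id(loci$chrom, loci$pos, loci$ref, loci$alt)

  # per-locus archetype means
  mono_mean <- rep(c(0.05, 0.95), length.out = sum(arch == "monoallelic"))
  mean_vaf <- numeric(config$n_loci)
  mean_vaf[arch == "stable"] <- 0.5
  mean_vaf[arch == "monoallelic"] <- mono_mean
  mean_vaf[arch == "variable"] <- runif(sum(arch == "variable"), 0.25, 0.75)

  conc <- unname(config$vaf_concentration[arch])
  nl <- config$n_loci
  nc <- config$n_cells
  latent <- matrix(rbeta(nl * nc, rep(mean_vaf * conc, nc),
                         rep((1 - mean_vaf) * conc, nc)),
                   nrow = nl, ncol = nc, dimnames = list(locus_ids, barcodes))
  coverage <- matrix(rnbinom(nl * nc, mu = config$coverage_mean,
                             size = config$coverage_dispersion),
                     nrow = nl, ncol = nc)
  coverage[matrix(runif(nl * nc) < config$dropout_rate, nl, nc)] <- 0L
  n_var <- matrix(rbinom(nl * nc, coverage, latent), nl, nc)

  obs <- which(coverage > 0, arr.ind = TRUE)
  allele_counts <- tibble(
    chrom = loci$chrom[obs[, 1]], pos = loci$pos[obs[, 1]],
    ref = loci$ref[obs[, 1]], alt = loci$alt[obs[, 1]],
    barcode = barcodes[obs[, 2]],
    n_ref = as.integer(coverage[obs] - n_var[obs]),
    n_var = as.integer(n_var[obs]))

  baseline <- rnorm(config$n_genes, config$expression_meanlog,
                    config$expression_sdlog)
  log_expr <- matrix(baseline, nrow = config$n_genes, ncol = nc) +
    matrix(rnorm(config$n_genes * nc, 0, config$noise_sd),
           config$n_genes, nc)
  if (nrow(pe) > 0) {
    for (r in seq_len(nrow(pe))) {
      log_expr[pe$gene[r], ] <- baseline[pe$gene[r]] +
        pe$beta[r] * latent[pe$locus[r], ] +
        rnorm(nc, 0, pe$noise_sd[r])
    }
  }
  expression <- round(exp(log_expr))
  dimnames(expression) <- list(gene_ids, barcodes)

  cell_annotations <- tibble(barcode = barcodes,
                             sample_id = config$sample_id,
                             cell_type = type_of)
  truth <- list(
    archetypes = tibble(locus_id = locus_ids, archetype = arch,
                        mean_vaf = mean_vaf,
                        harboring_gene = gene_ids[harbor]),
    planted = if (nrow(pe) > 0) {
      tibble(locus_id = locus_ids[pe$locus], gene_id = gene_ids[pe$gene],
             beta = pe$beta, noise_sd = pe$noise_sd)
    } else {
      tibble(locus_id = character(0), gene_id = character(0),
             beta = numeric(0), noise_sd = numeric(0))
    },
    latent_vaf = latent)
  list(allele_counts = allele_counts, expression = expression,
       gene_models = gene_models, cell_annotations = cell_annotations,
       truth = truth)
}

#' Archetype-level recall of the variability filter
#'
#' Cross-tabulates the generator's known locus archetypes against the
#' survivor set of [filter_nonvariable_loci()], to quantify how well the
#' filter retains genuinely variable loci and discards stable or
#' monoallelic ones.
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param surviving_loci Character vector of locus ids that passed.
#' @return A tibble with columns `archetype`, `retained`, `removed`,
#'   `retention_rate`.
#' @export
archetype_recall <- function(truth, surviving_loci) {
  truth$archetypes |>
    dplyr::mutate(kept = .data$locus_id %in% surviving_loci) |>
    dplyr::group_by(.data$archetype) |>
    dplyr::summarise(retained = sum(.data$kept), removed = sum(!.data$kept),
                     retention_rate = mean(.data$kept), .groups = "drop")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param expression_layout Layout for the expression matrix.
#' @return `dir`, invisibly. Files: `allele_counts.tsv`, `expression/` (or
#'   `expression.tsv`), `genes.bed`, `cell_annotations.tsv`, and
#'   `truth_planted.tsv`.
#' @export
write_dataset <- function(dataset, dir,
                          expression_layout = c("mtx-triplet", "dense-tsv")) {
  expression_layout <- match.arg(expression_layout)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_allele_counts(dataset$allele_counts, file.path(dir, "allele_counts.tsv"))
  if (expression_layout == "mtx-triplet") {
    write_expression_matrix(dataset$expression, file.path(dir, "expression"),
                            layout = "mtx-triplet")
  } else {
    write_expression_matrix(dataset$expression, file.path(dir, "expression.tsv"),
                            layout = "dense-tsv")
  }
  gm <- dataset$gene_models
  readr::write_tsv(tibble(chrom = gm$chrom, start = gm$start - 1L,
                          end = gm$end, name = gm$gene_id, score = 0L,
                          strand = gm$strand),
                   file.path(dir, "genes.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(dataset$cell_annotations,
                   file.path(dir, "cell_annotations.tsv"), progress = FALSE)
  readr::write_tsv(dataset$truth$planted, file.path(dir, "truth_planted.tsv"),
                   progress = FALSE)
  invisible(dir)
}
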