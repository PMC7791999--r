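#' Column-name dialect for allele-count tables
#'
#' Per-cell allele counters differ only in their header names. The default
#' follows the SCReadCounts-style SNV-barcode output: `CHROM`, `POS`, `REF`,
#' `ALT`, `ReadGroup` (the cell barcode), `SNVCountRef`, `SNVCount`. Override
#' any element to read other headers.
#'
#' @param chrom,pos,ref,alt,barcode,n_ref,n_var Header names holding each field.
#' @return A named character vector mapping internal field names to file
#'   column names.
#' @export
allele_count_dialect <- function(chrom = "CHROM", pos = "POS", ref = "REF",
                                 alt = "ALT", barcode = "ReadGroup",
                                 n_ref = "SNVCountRef", n_var = "SNVCount") {
  c(chrom = chrom, pos = pos, ref = ref, alt = alt, barcode = barcode,
    n_ref = n_ref, n_var = n_var)
}

#' Read per-cell allele counts at SNV loci
#'
#' Reads a tab-separated table with one row per (locus, cell) observation of
#' reference- and variant-supporting deduplicated read counts. Rows absent
#' from the file are treated downstream as zero coverage, so files that omit
#' zero-coverage pairs and files that enumerate them are both accepted.
#'
#' @param path Path to a TSV file (plain or gzip) with a header.
#' @param dialect Column-name mapping from [allele_count_dialect()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `barcode`,
#'   `n_ref`, `n_var`; one row per (locus, barcode) pair.
#' @seealso [write_allele_counts()]
#' @export
read_allele_counts <- function(path, dialect = allele_count_dialect()) {
  if (!file.exists(path)) stop_format("File not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    stop_format("Allele-count file ", path, " lacks required column(s): ",
                paste(missing, collapse = ", "))
  }
  tbl <- tibble(
    chrom = raw[[dialect[["chrom"]]]],
    pos = suppressWarnings(as.integer(raw[[dialect[["pos"]]]])),
    ref = raw[[dialect[["ref"]]]],
    alt = raw[[dialect[["alt"]]]],
    barcode = raw[[dialect[["barcode"]]]],
    n_ref = suppressWarnings(as.numeric(raw[[dialect[["n_ref"]]]])),
    n_var = suppressWarnings(as.numeric(raw[[dialect[["n_var"]]]]))
  )
  for (col in c("n_ref", "n_var")) {
    x <- tbl[[col]]
    bad <- which(is.na(x) | x < 0 | x != round(x))
    if (length(bad) > 0) {
      stop_invalid("Column ", dialect[[col]],
                   " must hold non-negative integers; offending line(s): ",
                   paste(head(bad + 1L, 5), collapse = ", "))
    }
  }
  if (anyNA(tbl$pos)) {
    stop_invalid("Non-integer position(s) in ", path)
  }
  tbl$n_ref <- as.integer(tbl$n_ref)
  tbl$n_var <- as.integer(tbl$n_var)
  validate_loci(tbl, context = path)
  key <- paste(locus_id(tbl$chrom, tbl$pos, tbl$ref, tbl$alt), tbl$barcode)
  if (anyDuplicated(key)) {
    stop_invalid("Duplicate (locus, barcode) records in ", path, ": ",
                 paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  inform(paste0("Read ", nrow(tbl), " allele-count records from ", path))
  tbl
}

#' @rdname read_allele_counts
#' @param counts A tibble as returned by `read_allele_counts()`.
#' @export
write_allele_counts <- function(counts, path, dialect = allele_count_dialect()) {
  out <- counts[c("chrom", "pos", "ref", "alt", "barcode", "n_ref", "n_var")]
  names(out) <- unname(dialect[names(out)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a genes-by-cells expression count matrix
#'
#' Supports the MatrixMarket triplet layout (a directory holding
#' `matrix.mtx`, `features.tsv` (or `genes.tsv`), `barcodes.tsv`) and a dense
#' TSV with genes in rows and a leading gene-id column. Orientation of the
#' returned matrix is always genes x cells.
#'
#' @param path Directory (mtx-triplet) or file (dense-tsv).
#' @param layout `"mtx-triplet"` or `"dense-tsv"`.
#' @param integer_counts Require integer entries (count mode). Default TRUE.
#' @return A base numeric matrix, genes in rows (rownames = gene ids),
#'   cells in columns (colnames = barcodes).
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, layout = c("mtx-triplet", "dense-tsv"),
                                   integer_counts = TRUE) {
  layout <- match.arg(layout)
  if (layout == "mtx-triplet") {
    if (!dir.exists(path)) stop_format("Directory not found: ", path)
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) {
      if (!file.exists(f)) stop_format("Missing sidecar or matrix file: ", f)
    }
    bad_mm <- function(c) stop_format("Malformed MatrixMarket file ", mtx,
                                      ": ", conditionMessage(c))
    m <- tryCatch(Matrix::readMM(mtx), error = bad_mm, warning = bad_mm)
    genes <- readr::read_tsv(feat, col_names = FALSE, progress = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))[[1]]
    cells <- readr::read_tsv(bc, col_names = FALSE, progress = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop_format("Dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
                  " but sidecars list ", length(genes), " genes and ",
                  length(cells), " barcodes")
    }
    mat <- as.matrix(m)
    dimnames(mat) <- list(genes, cells)
  } else {
    if (!file.exists(path)) stop_format("File not found: ", path)
    tbl <- readr::read_tsv(path, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_guess()))
    mat <- as.matrix(tbl[-1])
    if (!is.numeric(mat)) stop_invalid("Non-numeric entries in ", path)
    rownames(mat) <- as.character(tbl[[1]])
  }
  if (any(mat < 0)) stop_invalid("Negative entries in expression matrix ", path)
  if (integer_counts && any(mat != round(mat))) {
    stop_invalid("Non-integer entries in count-mode expression matrix ", path)
  }
  inform(paste0("Read ", nrow(mat), " x ", ncol(mat),
                " expression matrix from ", path))
  mat
}

#' @rdname read_expression_matrix
#' @param mat Genes x cells matrix with dimnames.
#' @export
write_expression_matrix <- function(mat, path, layout = c("mtx-triplet", "dense-tsv")) {
  layout <- match.arg(layout)
  if (layout == "mtx-triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), file.path(path, "matrix.mtx"))
    readr::write_tsv(tibble(x = rownames(mat)), file.path(path, "features.tsv"),
                     col_names = FALSE, progress = FALSE)
    readr::write_tsv(tibble(x = colnames(mat)), file.path(path, "barcodes.tsv"),
                     col_names = FALSE, progress = FALSE)
  } else {
    tbl <- dplyr::bind_cols(tibble(gene_id = rownames(mat)), as_tibble(mat))
    readr::write_tsv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

#' Read gene models for cis/trans annotation
#'
#' Parses GTF (1-based inclusive; records with feature type `gene`) or BED6
#' (0-based half-open, converted to 1-based inclusive) into one interval per
#' gene spanning the whole transcribed gene. Strand is stored but ignored by
#' the positional cis test.
#'
#' @param path Path to a GTF or BED file.
#' @param format `"gtf"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gene_models <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("File not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop_format("Cannot parse ", format,
                                                 " file ", path, ": ",
                                                 conditionMessage(e)))
  df <- as.data.frame(gr)
  if (format == "gtf") {
    if ("type" %in% names(df)) {
      df <- df[df$type == "gene", , drop = FALSE]
    }
    if (nrow(df) == 0) stop_format("No gene records in ", path)
    if (!"gene_id" %in% names(df) || anyNA(df$gene_id)) {
      stop_format("GTF gene record(s) in ", path, " lack a gene_id attribute")
    }
    gene_name <- if ("gene_name" %in% names(df)) {
      ifelse(is.na(df$gene_name), df$gene_id, df$gene_name)
    } else df$gene_id
    out <- tibble(gene_id = df$gene_id, gene_name = gene_name,
                  chrom = as.character(df$seqnames),
                  start = as.integer(df$start), end = as.integer(df$end),
                  strand = as.character(df$strand))
  } else {
    if (!"name" %in% names(df) || anyNA(df$name)) {
      stop_format("BED file ", path, " needs a name column (column 4)")
    }
    out <- tibble(gene_id = df$name, gene_name = df$name,
                  chrom = as.character(df$seqnames),
                  start = as.integer(df$start), end = as.integer(df$end),
                  strand = as.character(df$strand))
  }
  if (any(out$start > out$end)) {
    stop_invalid("Gene interval(s) with start > end in ", path)
  }
  out <- dplyr::distinct(out)
  if (anyDuplicated(out$gene_id)) {
    stop_invalid("Duplicate gene_id with conflicting coordinates in ", path, ": ",
                 paste(head(unique(out$gene_id[duplicated(out$gene_id)]), 3),
                       collapse = ", "))
  }
  out
}

#' Read a cell annotation table
#'
#' A TSV mapping cell barcodes to donor/sample labels and cell types. One
#' annotation per barcode; barcodes present in the data but absent here are
#' dropped from analysis with a warning rather than an error, because
#' scRNA-seq sidecar files routinely disagree on barcode suffixes.
#'
#' @param path TSV with columns `barcode`, `sample_id`, `cell_type`.
#' @return A tibble with those three columns.
#' @export
read_cell_annotations <- function(path) {
  if (!file.exists(path)) stop_format("File not found: ", path)
  tbl <- readr::read_tsv(path, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("barcode", "sample_id", "cell_type")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    stop_format("Cell annotation file ", path, " lacks column(s): ",
                paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tbl$barcode)) {
    stop_invalid("Duplicate barcode annotation(s) in ", path)
  }
  tbl[need]
}

#' Read a gene-gene interaction pair list
#'
#' Two-column TSV of gene symbols (optional third numeric confidence score,
#' STRING-style). Pairs are unordered; each is canonicalized by sorting its
#' two members. Self-pairs are rejected.
#'
#' @param path TSV with two leading gene columns, optional `score`.
#' @param min_score If the file carries a score column, keep only pairs with
#'   score >= `min_score`. Default `NULL` keeps every listed pair.
#' @return A tibble with columns `gene_a`, `gene_b` in canonical order.
#' @export
read_interactions <- function(path, min_score = NULL) {
  if (!file.exists(path)) stop_format("File not found: ", path)
  tbl <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols())
  if (ncol(tbl) < 2) stop_format("Interaction file ", path, " needs >= 2 columns")
  pairs <- tibble(gene_a = as.character(tbl[[1]]), gene_b = as.character(tbl[[2]]))
  if (!is.null(min_score)) {
    if (ncol(tbl) < 3 || !is.numeric(tbl[[3]])) {
      stop_format("min_score given but ", path, " has no numeric score column")
    }
    pairs <- pairs[tbl[[3]] >= min_score, , drop = FALSE]
  }
  canonical_pairs(pairs)
}

#' Write (and re-read) an scReQTL result table
#'
#' Tab-separated output with columns `snv`, `gene`, `beta`, `t`, `p`, `q`,
#' `class`, `n_cells`, ordered by q ascending then snv then gene, so output
#' is deterministic.
#'
#' @param results A result tibble from [run_reqtl()] (after
#'   [annotate_cis_trans()] if cis/trans classes are wanted).
#' @param path Output path.
#' @return `write_reqtl_table()`: the path, invisibly. `read_reqtl_table()`:
#'   the parsed tibble.
#' @export
write_reqtl_table <- function(results, path) {
  stats_cols <- c("beta", "t_stat", "p_value", "q_value")
  ok <- results[!is.na(results$p_value), , drop = FALSE]
  if (nrow(ok) > 0 && !all(vapply(ok[stats_cols], function(x) all(is.finite(x)),
                                  logical(1)))) {
    stop_invalid("Non-finite statistics in result table")
  }
  out <- tibble(
    snv = if ("snv" %in% names(results)) results$snv else
      locus_id(results$chrom, results$pos, results$ref, results$alt),
    gene = results$gene_id,
    beta = results$beta, t = results$t_stat, p = results$p_value,
    q = results$q_value,
    class = if ("cls" %in% names(results)) results$cls else NA_character_,
    n_cells = results$n_cells
  )
  out <- dplyr::arrange(out, .data$q, .data$snv, .data$gene)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_reqtl_table
#' @export
read_reqtl_table <- function(path) {
  if (!file.exists(path)) stop_format("File not found: ", path)
  readr::read_tsv(path, progress = FALSE,
                  col_types = readr::cols(
                    snv = readr::col_character(),
                    gene = readr::col_character(),
                    beta = readr::col_double(), t = readr::col_double(),
                    p = readr::col_double(), q = readr::col_double(),
                    class = readr::col_character(),
                    n_cells = readr::col_integer()))
}
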