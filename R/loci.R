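#' SNV locus identifiers
#'
#' A locus is identified by the 4-tuple (chrom, pos, ref, alt) with a 1-based
#' VCF-style coordinate. `locus_id()` renders the conventional compact form
#' `"chrom:pos_ref>alt"` (e.g. `"10:4977767_G>A"`); `parse_locus_id()` inverts
#' it.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based genomic position(s).
#' @param ref,alt Single-nucleotide reference and alternate alleles.
#' @return `locus_id()`: a character vector. `parse_locus_id()`: a tibble with
#'   columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' locus_id("10", 4977767, "G", "A")
#' parse_locus_id("10:4977767_G>A")
#' @export
locus_id <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, "_", ref, ">", alt)
}

#' @rdname locus_id
#' @param id Character vector of identifiers in `"chrom:pos_ref>alt"` form.
#' @export
parse_locus_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)_([ACGT])>([ACGT])$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    abort(paste0("Cannot parse locus id(s): ",
                 paste(head(id[bad], 5), collapse = ", ")),
          class = "screqtl_validation_error")
  }
  tibble(
    chrom = vapply(m, `[`, character(1), 2L),
    pos = as.integer(vapply(m, `[`, character(1), 3L)),
    ref = vapply(m, `[`, character(1), 4L),
    alt = vapply(m, `[`, character(1), 5L)
  )
}

# Validates the locus columns of a table: ACGT alleles, ref != alt, pos >= 1.
validate_loci <- function(tbl, context = "table") {
  nts <- c("A", "C", "G", "T")
  if (any(!tbl$ref %in% nts) || any(!tbl$alt %in% nts)) {
    abort(paste0("Non-ACGT allele in ", context),
          class = "screqtl_validation_error")
  }
  if (any(tbl$ref == tbl$alt)) {
    abort(paste0("ref == alt at ",
                 paste(head(locus_id(tbl$chrom, tbl$pos, tbl$ref, tbl$alt)[
                   tbl$ref == tbl$alt], 3), collapse = ", ")),
          class = "screqtl_validation_error")
  }
  if (any(tbl$pos < 1L)) {
    abort(paste0("Position < 1 in ", context),
          class = "screqtl_validation_error")
  }
  invisible(tbl)
}

stop_format <- function(...) abort(paste0(...), class = "screqtl_format_error")
stop_invalid <- function(...) abort(paste0(...), class = "screqtl_validation_error")
stop_param <- function(...) abort(paste0(...), class = "screqtl_parameter_error")
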