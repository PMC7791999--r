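#' Tidy a VAF matrix into long format
#'
#' @param x A `vaf_matrix`.
#' @param informative_only Keep only informative entries. Default FALSE.
#' @param ... Ignored.
#' @return A tibble with columns `locus_id`, `barcode`, `coverage`,
#'   `informative`, `vaf` (`NA` where masked).
#' @method tidy vaf_matrix
#' @export
tidy.vaf_matrix <- function(x, informative_only = FALSE, ...) {
  out <- tibble(
    locus_id = rep(rownames(x$vaf), times = ncol(x$vaf)),
    barcode = rep(x$cells, each = nrow(x$vaf)),
    coverage = as.integer(x$coverage),
    informative = as.logical(x$mask),
    vaf = as.numeric(x$vaf))
  if (informative_only) out <- out[out$informative, , drop = FALSE]
  out
}

#' @describeIn tidy.vaf_matrix One-row summary: dimensions, informative
#'   fraction, minR.
#' @method glance vaf_matrix
#' @export
glance.vaf_matrix <- function(x, ...) {
  tibble(n_loci = nrow(x$vaf), n_cells = ncol(x$vaf), minR = x$minR,
         n_informative = sum(x$mask),
         informative_fraction = mean(x$mask))
}

#' Tidy scReQTL results
#'
#' `tidy()` returns the per-pair records as a plain tibble; `glance()`
#' returns a one-row summary with test and discovery counts.
#'
#' @param x A `reqtl_result`.
#' @param fdr Significance threshold used by `glance()`. Default 0.05.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy reqtl_result
#' @export
tidy.reqtl_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.reqtl_result
#' @method glance reqtl_result
#' @export
glance.reqtl_result <- function(x, fdr = 0.05, ...) {
  ok <- x$status == "ok"
  sig <- ok & !is.na(x$q_value) & x$q_value <= fdr
  tibble(
    n_pairs = nrow(x), n_tested = sum(ok), n_skipped = sum(!ok),
    n_significant = sum(sig),
    n_cis = if ("cls" %in% names(x)) sum(sig & x$cls == "cis", na.rm = TRUE)
            else NA_integer_,
    n_trans = if ("cls" %in% names(x)) sum(sig & x$cls == "trans", na.rm = TRUE)
              else NA_integer_,
    min_q = if (any(ok)) min(x$q_value[ok]) else NA_real_)
}

#' Tidy a permutation enrichment result
#'
#' `tidy()` returns the permutation overlap distribution; `glance()` the
#' observed overlap and p-value (a p of 0 is reported as `< 1/n_perm` in
#' `p_label`).
#'
#' @param x An `enrichment_result`.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(permutation = seq_len(x$n_permutations),
         overlap = x$permutation_overlaps)
}

#' @rdname tidy.enrichment_result
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed_overlap = x$observed_overlap, n_pairs = x$n_pairs,
         n_permutations = x$n_permutations, p_value = x$p_value,
         p_label = if (x$p_value == 0) paste0("< ", 1 / x$n_permutations)
                   else format(x$p_value),
         seed = x$seed)
}
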