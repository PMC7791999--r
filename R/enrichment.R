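#' Canonicalize unordered gene pairs
#'
#' Sorts the two members of each pair so that unordered-pair equality
#' reduces to row equality, drops duplicate pairs, and rejects self-pairs.
#'
#' @param pairs Tibble/data frame with columns `gene_a`, `gene_b` (or the
#'   first two columns).
#' @return A tibble with columns `gene_a <= gene_b`, unique rows.
#' @export
canonical_pairs <- function(pairs) {
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  if (any(a == b)) {
    stop_invalid("Self-pair(s) found: ", paste(head(a[a == b], 3), collapse = ", "))
  }
  dplyr::distinct(tibble(gene_a = pmin(a, b), gene_b = pmax(a, b)))
}

#' Count overlap between two unordered pair sets
#'
#' @param pairs,interactions Pair tables (canonicalized internally).
#' @return Integer: number of pairs present in both sets.
#' @export
pair_overlap <- function(pairs, interactions) {
  p <- canonical_pairs(pairs)
  i <- canonical_pairs(interactions)
  sum(paste(p$gene_a, p$gene_b, sep = "\r") %in%
        paste(i$gene_a, i$gene_b, sep = "\r"))
}

# Decode 1-based unordered-pair indices k in 1..m(m-1)/2 to (i, j), i < j,
# enumerated row-major: (1,2),(1,3),...,(1,m),(2,3),...
decode_pair_index <- function(k, m) {
  # i satisfies cum(i-1) < k <= cum(i), cum(i) = i*m - i*(i+1)/2
  i <- ceiling(m - 0.5 - sqrt((m - 0.5)^2 - 2 * k))
  cum_prev <- (i - 1) * m - i * (i - 1) / 2
  # guard against floating-point edge error
  too_low <- cum_prev >= k
  i[too_low] <- i[too_low] - 1L
  cum_prev <- (i - 1) * m - i * (i - 1) / 2
  too_high <- k > i * m - i * (i + 1) / 2
  i[too_high] <- i[too_high] + 1L
  cum_prev <- (i - 1) * m - i * (i - 1) / 2
  j <- i + (k - cum_prev)
  cbind(as.integer(i), as.integer(j))
}

#' Permutation test for enrichment of gene pairs in an interaction set
#'
#' Assesses whether observed (e.g. trans-scReQTL) gene pairs overlap a known
#' gene-gene interaction set more than chance. Each permutation draws the
#' same number of distinct unordered pairs uniformly from the supplied gene
#' universe (no self-pairs, no duplicates within a permutation) and counts
#' its overlap with the interaction set; the p-value is the fraction of
#' permutations whose overlap is at least as large as the observed one.
#' A p of 0 is reported as below 1/n_perm resolution by [glance()].
#'
#' @param pairs Observed pair table.
#' @param universe Character vector of all genes eligible to form pairs
#'   (the analysis input genes). Must allow `nrow(pairs)` distinct pairs.
#' @param interactions Known-interaction pair table.
#' @param n_perm Number of permutations. Default 10000.
#' @param seed Integer seed for reproducibility.
#' @return An `enrichment_result`: list with `observed_overlap`, `n_pairs`,
#'   `n_permutations`, `permutation_overlaps`, `p_value`, `seed`.
#' @export
permutation_enrichment <- function(pairs, universe, interactions,
                                   n_perm = 10000, seed = 1) {
  p <- canonical_pairs(pairs)
  ints <- canonical_pairs(interactions)
  universe <- unique(as.character(universe))
  m <- length(universe)
  n_pairs <- nrow(p)
  n_possible <- m * (m - 1) / 2
  if (n_pairs < 1) stop_param("Need at least one observed pair")
  if (n_possible < n_pairs) {
    stop_param("Universe of ", m, " genes cannot form ", n_pairs,
               " distinct pairs")
  }
  observed <- pair_overlap(p, ints)
  # interaction pairs as numeric codes over universe indices (i-1)*m + j
  ia <- match(ints$gene_a, universe)
  ib <- match(ints$gene_b, universe)
  in_univ <- !is.na(ia) & !is.na(ib)
  lo <- pmin(ia[in_univ], ib[in_univ])
  hi <- pmax(ia[in_univ], ib[in_univ])
  int_codes <- (lo - 1) * m + hi
  set.seed(seed)
  perm_overlaps <- vapply(seq_len(n_perm), function(r) {
    k <- sample(n_possible, n_pairs)
    ij <- decode_pair_index(k, m)
    codes <- (ij[, 1] - 1) * m + ij[, 2]
    sum(codes %in% int_codes)
  }, integer(1))
  p_value <- mean(perm_overlaps >= observed)
  structure(list(observed_overlap = observed, n_pairs = n_pairs,
                 n_permutations = n_perm,
                 permutation_overlaps = perm_overlaps,
                 p_value = p_value, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  p_str <- if (x$p_value == 0) paste0("< ", format(1 / x$n_permutations)) else
    format(x$p_value)
  cat("Permutation enrichment:", x$observed_overlap, "of", x$n_pairs,
      "pairs in interaction set\n")
  cat("p =", p_str, "(", x$n_permutations, "permutations, seed", x$seed, ")\n")
  invisible(x)
}

#' Chi-square comparison of two overlap proportions
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table of hits and misses in two groups, e.g. to compare the fraction
#' of scReQTL SNVs found in two external catalogues.
#'
#' @param hits_a,total_a Hits and total in group A.
#' @param hits_b,total_b Hits and total in group B.
#' @param correct Apply Yates continuity correction. Default FALSE.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
overlap_chi_square <- function(hits_a, total_a, hits_b, total_b,
                               correct = FALSE) {
  if (total_a <= 0 || total_b <= 0) stop_param("Totals must be positive")
  if (hits_a > total_a || hits_b > total_b || hits_a < 0 || hits_b < 0) {
    stop_param("Hits must lie in [0, total]")
  }
  tab <- matrix(c(hits_a, total_a - hits_a, hits_b, total_b - hits_b),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop_invalid("Zero expected cell count; use an exact test instead")
  }
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}
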