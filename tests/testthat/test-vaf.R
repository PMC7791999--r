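test_that("pooling sums allele counts per locus", {
  tbl <- tibble::tibble(
    chrom = "1", pos = 100L, ref = "A", alt = "G",
    barcode = c("c1", "c2", "c3"),
    n_ref = c(2L, 3L, 5L), n_var = c(1L, 0L, 4L))
  pooled <- pool_allele_counts(tbl)
  expect_equal(pooled$n_ref, 10L)
  expect_equal(pooled$n_var, 5L)

  set.seed(51)
  big <- random_allele_table(n_loci = 12, n_cells = 20, p_obs = 0.85)
  pooled2 <- pool_allele_counts(big)
  # brute-force group-by oracle
  key <- paste(big$chrom, big$pos)
  for (k in unique(key)) {
    row <- pooled2[paste(pooled2$chrom, pooled2$pos) == k, ]
    expect_equal(row$n_ref, sum(big$n_ref[key == k]))
    expect_equal(row$n_var, sum(big$n_var[key == k]))
  }
  expect_equal(nrow(pooled2), length(unique(key)))  # absent loci absent
})

test_that("biallelic selection keeps loci with >= 50 reads per allele", {
  pooled <- tibble::tibble(
    chrom = "1", pos = 1:6 * 10L, ref = "A", alt = "G",
    n_ref = c(50L, 49L, 400L, 50L, 1000L, 60L),
    n_var = c(50L, 50L, 0L, 49L, 51L, 70L))
  kept <- select_biallelic_loci(pooled)
  expect_equal(kept$pos, c(10L, 50L, 60L))  # boundary (50,50) inclusive
  expect_false(30L %in% kept$pos)           # monoallelic pool removed
})

test_that("VAF matrix masks by minR and treats absent records as zero coverage", {
  counts <- tibble::tibble(
    chrom = "1", pos = c(100L, 100L, 200L), ref = "A", alt = "G",
    barcode = c("c1", "c2", "c1"),
    n_ref = c(5L, 6L, 20L), n_var = c(5L, 3L, 20L))
  vm <- build_vaf_matrix(counts, cells = c("c1", "c2", "c3"), minR = 10)
  expect_true(vm$mask["1:100_A>G", "c1"])            # coverage 10 boundary kept
  expect_equal(vm$vaf["1:100_A>G", "c1"], 0.5)
  expect_false(vm$mask["1:100_A>G", "c2"])           # coverage 9 masked
  expect_true(is.na(vm$vaf["1:100_A>G", "c2"]))
  expect_equal(vm$coverage["1:200_A>G", "c3"], 0L)   # absent record
  expect_error(build_vaf_matrix(counts, "c1", minR = 0),
               class = "screqtl_parameter_error")
})

test_that("VAF and its complement conserve mass at informative entries", {
  set.seed(52)
  tbl <- random_allele_table(n_loci = 8, n_cells = 15)
  vm <- build_vaf_matrix(tbl, cells = sprintf("BC%03d", 1:15), minR = 10)
  idx <- which(vm$mask)
  ref_frac <- (vm$coverage[idx] * (1 - vm$vaf[idx])) / vm$coverage[idx]
  expect_equal(vm$vaf[idx] + ref_frac, rep(1, length(idx)), tolerance = 1e-12)
})

test_that("informative-entry count is non-increasing in minR", {
  set.seed(53)
  tbl <- random_allele_table(n_loci = 15, n_cells = 25, mean_cov = 12)
  cells <- sprintf("BC%03d", 1:25)
  n_inf <- vapply(5:15, function(r) {
    sum(build_vaf_matrix(tbl, cells, minR = r)$mask)
  }, numeric(1))
  expect_true(all(diff(n_inf) <= 0))
})

test_that("non-variable loci are removed on strict band dominance", {
  rows <- list(
    stable16 = c(rep(0.5, 16), 0.1, 0.9, 0.3, 0.7),   # 16/20 = 0.80 > 0.75
    stable15 = c(rep(0.5, 15), rep(0.1, 5)),          # 15/20 = 0.75, not > 0.75
    const03 = rep(0.30, 20),                          # neither band dominated
    mono = c(rep(0.05, 18), 0.5, 0.5),                # 18/20 monoallelic
    skew_hi = c(rep(0.9, 16), rep(0.5, 4)),           # 16/20 in [0.75, 1]
    edge_band = c(rep(0.4, 16), rep(0.1, 4)))         # 0.4 counts as stable (closed)
  vm <- vaf_matrix_from_values(rows, coverage = 100)
  kept <- filter_nonvariable_loci(vm)
  ids <- rownames(vm$vaf)
  names(ids) <- names(rows)
  expect_setequal(as.character(kept), unname(ids[c("stable15", "const03")]))
  removed <- attr(kept, "removed")
  expect_equal(removed$rule[removed$locus_id == ids[["mono"]]],
               "monoallelic_or_skewed")
  expect_equal(removed$rule[removed$locus_id == ids[["edge_band"]]],
               "stable_biallelic")
})

test_that("constructed band occupancies match hand enumeration", {
  set.seed(54)
  # 10 loci with known stable-band occupancy k/20; removed iff k/20 > 0.75
  rows <- lapply(seq(6, 20, length.out = 10), function(k) {
    k <- round(k)
    c(rep(0.5, k), rep(0.1, 20 - k))
  })
  vm <- vaf_matrix_from_values(rows, coverage = 100)
  kept <- filter_nonvariable_loci(vm)
  k_vals <- round(seq(6, 20, length.out = 10))
  # loci dominated by neither band survive: stable frac <= 0.75 AND mono <= 0.75
  expected <- rownames(vm$vaf)[k_vals / 20 <= 0.75 & (20 - k_vals) / 20 <= 0.75]
  expect_setequal(as.character(kept), expected)
})

test_that("zero-informative loci are removed with a logged reason", {
  counts <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "G",
                           barcode = "c1", n_ref = 2L, n_var = 1L)
  vm <- build_vaf_matrix(counts, cells = c("c1", "c2"), minR = 10)
  kept <- filter_nonvariable_loci(vm)
  expect_length(kept, 0)
  expect_equal(attr(kept, "removed")$rule, "no_informative_cells")
})

test_that("strict mode keeps only variable-band-dominated loci", {
  rows <- list(
    var_band = c(rep(0.3, 8), rep(0.65, 8), rep(0.5, 4)),  # 16/20 in variable bands
    mixed = c(rep(0.5, 10), rep(0.1, 10)))                 # passes neither band rule
  vm <- vaf_matrix_from_values(rows, coverage = 100)
  strict <- filter_nonvariable_loci(vm, mode = "strict")
  expect_equal(as.character(strict), rownames(vm$vaf)[1])
  # the default exclusion rule keeps both (neither band exceeds 75%)
  expect_length(filter_nonvariable_loci(vm), 2)
})

test_that("minimum-cells filter is inclusive at the boundary", {
  set.seed(55)
  tbl <- random_allele_table(n_loci = 10, n_cells = 30, p_obs = 0.7)
  cells <- sprintf("BC%03d", 1:30)
  vm <- build_vaf_matrix(tbl, cells, minR = 10)
  kept20 <- filter_min_cells(vm, min_cells = 20)
  expect_setequal(kept20, rownames(vm$vaf)[rowSums(vm$mask) >= 20])

  counts <- dplyr::bind_rows(
    tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "G",
                   barcode = sprintf("BC%03d", 1:20), n_ref = 10L, n_var = 10L),
    tibble::tibble(chrom = "1", pos = 2L, ref = "A", alt = "G",
                   barcode = sprintf("BC%03d", 1:19), n_ref = 10L, n_var = 10L))
  vm2 <- build_vaf_matrix(counts, sprintf("BC%03d", 1:20), minR = 10)
  expect_equal(filter_min_cells(vm2, min_cells = 20), "1:1_A>G")
})

test_that("chance-variability probability is exact binomial upper tail", {
  expect_equal(chance_variability_probability(20, 0.75, 0.5),
               21700 / 2^20, tolerance = 1e-15)
  expect_equal(chance_variability_probability(10, 0.75, 0.5),
               56 / 1024, tolerance = 1e-15)
  expect_equal(chance_variability_probability(1, 0.75, 0.5), 0.5)
  expect_error(chance_variability_probability(20.5),
               class = "screqtl_parameter_error")
})

test_that("chance-variability probability decreases with more cells", {
  p <- vapply(seq(20, 100, by = 4), chance_variability_probability, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("composed filters equal a one-shot brute-force evaluation", {
  set.seed(56)
  tbl <- random_allele_table(n_loci = 20, n_cells = 40, p_obs = 0.8,
                             mean_cov = 15)
  cells <- sprintf("BC%03d", 1:40)
  pooled <- pool_allele_counts(tbl)
  bi <- select_biallelic_loci(pooled, min_reads_per_allele = 50)
  vm <- build_vaf_matrix(tbl, cells, bi, minR = 10)
  surv <- filter_min_cells(vm, filter_nonvariable_loci(vm), min_cells = 20)

  # brute force: evaluate every rule directly from the raw table
  brute <- character(0)
  for (p in unique(tbl$pos)) {
    sub <- tbl[tbl$pos == p, ]
    if (sum(sub$n_ref) < 50 || sum(sub$n_var) < 50) next
    cov <- sub$n_ref + sub$n_var
    vaf <- sub$n_var[cov >= 10] / cov[cov >= 10]
    if (length(vaf) == 0) next
    if (mean(vaf >= 0.4 & vaf <= 0.6) > 0.75) next
    if (mean(vaf <= 0.25 | vaf >= 0.75) > 0.75) next
    if (length(vaf) < 20) next
    brute <- c(brute, locus_id(sub$chrom[1], p, "A", "G"))
  }
  expect_setequal(as.character(surv), brute)
})
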