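test_that("a perfect linear relationship is recovered exactly", {
  vaf <- seq(0.1, 0.9, length.out = 20)
  fit <- fit_snv_gene(vaf, 2 * vaf, min_cells = 20)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-200)
  expect_equal(fit$n_cells, 20)
  expect_equal(fit$status, "ok")
})

test_that("OLS fit matches the brute-force normal-equations oracle", {
  set.seed(61)
  for (rep in 1:100) {
    n <- sample(25:40, 1)
    k <- sample(0:4, 1)
    vaf <- runif(n)
    vaf[sample(n, sample(0:3, 1))] <- NA
    cv <- if (k > 0) matrix(rnorm(n * k), n) else NULL
    y <- rnorm(n)
    fit <- fit_snv_gene(vaf, y, cv, min_cells = 10)
    use <- which(!is.na(vaf))
    x <- cbind(1, vaf[use], if (k > 0) cv[use, , drop = FALSE])
    xtx_inv <- solve(crossprod(x))
    b <- xtx_inv %*% crossprod(x, y[use])
    res <- y[use] - x %*% b
    df <- length(use) - ncol(x)
    se <- sqrt(sum(res^2) / df * xtx_inv[2, 2])
    expect_equal(fit$beta, b[2], tolerance = 1e-8)
    expect_equal(fit$t_stat, b[2] / se, tolerance = 1e-8)
    expect_equal(fit$p_value, 2 * pt(-abs(b[2] / se), df), tolerance = 1e-8)
  }
})

test_that("fit without covariates reproduces the Pearson correlation t-test", {
  set.seed(62)
  n <- 50
  vaf <- runif(n)
  y <- 0.4 * vaf + rnorm(n)
  fit <- fit_snv_gene(vaf, y, min_cells = 20)
  r <- cor(vaf, y)
  expect_equal(fit$t_stat, r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
})

test_that("degenerate inputs are skipped with reasons", {
  expect_equal(fit_snv_gene(rep(0.5, 30), rnorm(30))$status,
               "degenerate regressor")
  expect_equal(fit_snv_gene(runif(10), rnorm(10), min_cells = 20)$status,
               "insufficient cells")
  # covariates leave no residual degrees of freedom
  n <- 21
  fit <- fit_snv_gene(runif(n), rnorm(n), matrix(rnorm(n * 19), n),
                      min_cells = 20)
  expect_equal(fit$status, "insufficient cells for covariates")
})

test_that("null p-values are uniform", {
  set.seed(63)
  p <- vapply(1:1000, function(i) {
    fit_snv_gene(runif(30), rnorm(30), min_cells = 20)$p_value
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("an all-zero covariate column does not move the slope", {
  set.seed(64)
  n <- 40
  vaf <- runif(n)
  y <- vaf + rnorm(n)
  cv <- matrix(rnorm(n * 2), n)
  f1 <- fit_snv_gene(vaf, y, cv)
  f2 <- fit_snv_gene(vaf, y, cbind(cv, 0))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("BH q-values match the hand-coded step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "screqtl_validation_error")

  step_up <- function(p) {  # independent implementation of BH
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  set.seed(65)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, step_up(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-order
  }
})

make_group <- function(seed = 66, n_cells = 40, n_loci = 3, n_genes = 4,
                       const_locus = FALSE) {
  set.seed(seed)
  cells <- sprintf("BC%03d", seq_len(n_cells))
  counts <- dplyr::bind_rows(lapply(seq_len(n_loci), function(i) {
    v <- if (const_locus && i == 1) rep(0.5, n_cells) else
      runif(n_cells, 0.1, 0.9)
    tibble::tibble(chrom = "1", pos = i * 100L, ref = "A", alt = "G",
                   barcode = cells, n_ref = as.integer(20 - round(20 * v)),
                   n_var = as.integer(round(20 * v)))
  }))
  expr <- matrix(rpois(n_genes * n_cells, 30), n_genes,
                 dimnames = list(sprintf("G%02d", seq_len(n_genes)), cells))
  vm <- build_vaf_matrix(counts, cells, minR = 10)
  norm <- normalize_expression(expr)
  list(vm = vm, norm = norm, cells = cells)
}

test_that("run_reqtl enumerates every pair and assigns group-wise q-values", {
  g <- make_group(n_loci = 2, n_genes = 3)
  res <- run_reqtl(g$vm, g$norm, group = c(sample_id = "S1", cell_type = "t"))
  expect_s3_class(res, "reqtl_result")
  expect_equal(nrow(res), 6)
  expect_equal(sum(res$status == "ok"), 6)
  expect_equal(res$q_value[res$status == "ok"],
               unname(bh_fdr(res$p_value[res$status == "ok"])))
  expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))
  expect_equal(res$sample_id, rep("S1", 6))
})

test_that("constant-VAF loci yield skip records, not dropped rows", {
  g <- make_group(n_loci = 3, n_genes = 3, const_locus = TRUE)
  res <- run_reqtl(g$vm, g$norm)
  expect_equal(nrow(res), 9)
  skipped <- res[res$status == "degenerate regressor", ]
  expect_equal(nrow(skipped), 3)
  expect_true(all(is.na(skipped$p_value)))
  expect_equal(sum(res$status == "ok"), 6)
})

test_that("results are invariant to cell ordering", {
  g <- make_group(seed = 67)
  res1 <- run_reqtl(g$vm, g$norm)
  perm <- sample(length(g$cells))
  vm2 <- g$vm[, perm]
  res2 <- run_reqtl(vm2, g$norm)
  expect_equal(tidy(res1)[c("snv", "gene_id", "beta", "p_value")],
               tidy(res2)[c("snv", "gene_id", "beta", "p_value")],
               tolerance = 1e-12)
})

test_that("cis/trans annotation follows closed-interval gene residence", {
  genes <- tibble::tibble(
    gene_id = c("AKR1C1", "AKR1C2"), gene_name = gene_id,
    chrom = "10", start = c(4969097L, 5000000L),
    end = c(4987351L, 5030000L), strand = "+")
  recs <- tibble::tibble(
    snv = "10:4977767_G>A", chrom = "10", pos = 4977767L, ref = "G", alt = "A",
    gene_id = c("AKR1C1", "AKR1C2"),
    beta = 1, t_stat = 1, p_value = 0.1, q_value = 0.1,
    n_cells = 30L, status = "ok")
  ann <- annotate_cis_trans(recs, genes)
  expect_equal(ann$cls, c("cis", "trans"))

  # exact start coordinate is cis (closed interval)
  edge <- recs[1, ]
  edge$pos <- 4969097L
  expect_equal(annotate_cis_trans(edge, genes)$cls, "cis")

  # missing model flags NA without dropping the record
  orphan <- recs[1, ]
  orphan$gene_id <- "NOPE"
  expect_warning(out <- annotate_cis_trans(orphan, genes), "unannotated")
  expect_equal(nrow(out), 1)
  expect_true(is.na(out$cls))
})

test_that("cis/trans classes match brute-force interval checks", {
  set.seed(68)
  genes <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:20), gene_name = gene_id,
    chrom = sample(c("1", "2"), 20, TRUE),
    start = as.integer(sample(1:5000, 20)))
  genes$end <- genes$start + as.integer(sample(100:2000, 20))
  genes$strand <- "+"
  recs <- tibble::tibble(
    chrom = sample(c("1", "2"), 50, TRUE),
    pos = as.integer(sample(1:7000, 50)),
    ref = "A", alt = "G",
    gene_id = sample(genes$gene_id, 50, TRUE),
    beta = 0, t_stat = 0, p_value = 0.5, q_value = 0.5,
    n_cells = 30L, status = "ok")
  recs$snv <- locus_id(recs$chrom, recs$pos, recs$ref, recs$alt)
  ann <- annotate_cis_trans(recs, genes)
  for (i in 1:50) {
    g <- genes[genes$gene_id == recs$gene_id[i], ]
    expected <- if (g$chrom == recs$chrom[i] && g$start <= recs$pos[i] &&
                    recs$pos[i] <= g$end) "cis" else "trans"
    expect_equal(ann$cls[i], expected)
  }
})
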