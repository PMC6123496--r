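test_that("cell QC metrics match direct sums and counts", {
  em <- toy_expr(rbind(c(0, 3, 0, 1), c(0, 0, 0, 0)), unit = "raw_tpm")
  m <- compute_cell_qc_metrics(em)
  expect_equal(m$library_size, c(4, 0))
  expect_equal(m$n_genes_expressed, c(2, 0))   # log2(1+1) = 1 >= 0.1
  expect_equal(m$total_mrna, m$library_size)   # degenerate without controls
  expect_true(attr(m, "log")$total_mrna_degenerate)

  # 10-cell toy against a hand-rolled oracle
  set.seed(1)
  v <- matrix(round(rexp(10 * 8, 0.2), 2), nrow = 10)
  em2 <- toy_expr(v)
  m2 <- compute_cell_qc_metrics(em2)
  for (i in 1:10) {
    expect_equal(m2$library_size[i], sum(v[i, ]))
    expect_equal(m2$n_genes_expressed[i], sum(log2(v[i, ] + 1) >= 0.1))
  }
  empty <- expression_matrix(matrix(numeric(0), 0, 0), "raw_tpm",
                             cell_ids = character(0), gene_ids = character(0))
  expect_error(compute_cell_qc_metrics(empty), "empty")
})

test_that("MAD cell filter matches enumeration and applies the union rule", {
  libs <- c(100, 980, 1000, 1005, 1010, 1020, 1050, 990, 995, 1002)
  metrics <- data.frame(cell_id = paste0("c", 1:10), library_size = libs,
                        n_genes_expressed = rep(50, 10),
                        total_mrna = rep(1000, 10))
  res <- filter_cells_by_mad(metrics, k = 4)
  # enumeration oracle on log2(x+1)
  lx <- log2(libs + 1)
  cut <- median(lx) - 4 * median(abs(lx - median(lx)))
  expect_identical(res$removed, paste0("c", which(lx < cut)))
  expect_identical(res$removed, "c1")
  expect_setequal(res$kept, paste0("c", 2:10))

  # union rule: failing only the third metric removes the cell
  metrics$total_mrna[5] <- 1
  res2 <- filter_cells_by_mad(metrics, k = 4)
  expect_true("c5" %in% res2$removed)
  expect_equal(unname(res2$removed_by_metric["total_mrna"]), 1)

  # degenerate MAD: identical metrics keep everything
  same <- data.frame(cell_id = paste0("c", 1:10), library_size = 500,
                     n_genes_expressed = 50, total_mrna = 500)
  expect_length(filter_cells_by_mad(same, k = 4)$removed, 0)

  expect_error(filter_cells_by_mad(metrics[1:2, ], 4), "3 cells")
  expect_error(filter_cells_by_mad(metrics, k = 0), "k must be")
})

test_that("MAD filter removal is monotone in the failing metric", {
  set.seed(7)
  for (rep in 1:5) {
    libs <- c(round(runif(1, 1, 40)), round(rnorm(19, 1000, 30)))
    metrics <- data.frame(cell_id = paste0("c", 1:20), library_size = libs,
                          n_genes_expressed = 50, total_mrna = 1000)
    res <- filter_cells_by_mad(metrics, k = 4)
    for (cell in res$removed) {
      worse <- metrics
      i <- match(cell, worse$cell_id)
      worse$library_size[i] <- worse$library_size[i] / 2
      expect_true(cell %in% filter_cells_by_mad(worse, k = 4)$removed)
    }
  }
})

test_that("gene prevalence filter removes only the all-patient intersection", {
  # 2 patients x 25/20 cells; gene A silent in 96% of P1 but 50% of P2
  set.seed(2)
  n1 <- 25; n2 <- 20
  v <- matrix(5, n1 + n2, 3,
              dimnames = list(paste0("c", 1:(n1 + n2)), c("gA", "gB", "gC")))
  v[1:24, "gA"] <- 0                       # 96% silent in patient 1
  v[n1 + 1:10, "gA"] <- 0                  # 50% silent in patient 2
  v[, "gB"] <- 0                           # silent everywhere
  patients <- rep(c("P1", "P2"), c(n1, n2))
  res <- filter_genes_by_prevalence(expression_matrix(v, "raw_tpm"), patients)
  expect_true("gA" %in% res$kept)          # intersection rule
  expect_identical(res$removed, "gB")

  # brute-force oracle on a random toy
  v2 <- matrix(rbinom(45 * 30, 1, 0.04) * 5, 45, 30,
               dimnames = list(paste0("c", 1:45), paste0("g", 1:30)))
  res2 <- filter_genes_by_prevalence(expression_matrix(v2, "raw_tpm"),
                                     patients <- rep(c("A", "B"), c(25, 20)),
                                     threshold = 0.1, prevalence = 0.95)
  silent <- sapply(seq_len(30), function(j) {
    all(sapply(c("A", "B"), function(p) {
      mean(log2(v2[patients == p, j] + 1) < 0.1) >= 0.95
    }))
  })
  expect_setequal(res2$removed, colnames(v2)[silent])

  expect_error(filter_genes_by_prevalence(expression_matrix(v, "raw_tpm"),
                                          patients, patients = c("A", "Z")),
               "0 cells")
})

test_that("relative-count transform anchors the nonzero mode at 1", {
  em <- toy_expr(rbind(c(25, 25, 50, 0, 30)), unit = "raw_tpm")
  counts <- estimate_relative_counts(em)
  # mode 25 -> scale 1/25; TPM 50 -> 2, TPM 30 -> round(1.2) = 1
  expect_equal(unname(counts$values[1, ]), c(1, 1, 2, 0, 1))
})

test_that("relative-count transform is monotone and supports passthrough", {
  set.seed(3)
  v <- matrix(rexp(5 * 40, 0.1), 5, 40)
  em <- toy_expr(v)
  counts <- estimate_relative_counts(em)
  for (i in 1:5) {
    o <- order(v[i, ])
    expect_true(all(diff(counts$values[i, o]) >= 0))
  }
  pt <- estimate_relative_counts(em, mode = "passthrough")
  expect_equal(pt$values, em$values)
  expect_identical(pt$unit, "counts")

  # all-zero cell stays zero and is flagged
  v0 <- rbind(v[1:2, ], 0)
  c0 <- estimate_relative_counts(toy_expr(v0))
  expect_equal(unname(c0$values[3, ]), rep(0, 40))
  expect_identical(attr(c0, "log")$zero_cells, "c3")
})

test_that("size factors scale correctly and flag all-zero cells", {
  base <- matrix(rpois(120, 20) + 1, 1, 120)
  v <- rbind(base, 2 * base, 3 * base, 4 * base)
  em <- toy_expr(v, unit = "counts")
  f <- compute_size_factors(em)
  expect_equal(unname(f / f[1]), c(1, 2, 3, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mean(f), 1, ignore_attr = TRUE)

  # identical cells give unit factors
  same <- toy_expr(v[c(1, 1, 1), ] + 0, unit = "counts",
                   cells = c("a", "b", "c"))
  expect_equal(unname(compute_size_factors(same)), rep(1, 3),
               ignore_attr = TRUE)

  # all-zero cell: factor 0, dropped by normalization
  vz <- rbind(v, 0)
  fz <- compute_size_factors(toy_expr(vz, unit = "counts"))
  expect_equal(unname(fz[5]), 0, ignore_attr = TRUE)
  norm <- normalize_by_size_factors(toy_expr(vz, unit = "counts"), fz)
  expect_equal(nrow(norm$values), 4)
  expect_identical(attr(norm, "log")$removed_zero_factor, "c5")

  # deconvolution variant agrees on clean scalings
  fd <- compute_size_factors(em, method = "deconvolution")
  expect_equal(unname(fd / fd[1]), c(1, 2, 3, 4), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("RUV correction removes an implanted batch and spares signal", {
  norm0 <- toy_expr(matrix(rnorm(80 * 60), 80, 60), unit = "normalized_log")
  expect_identical(remove_unwanted_variation(norm0, k = 0), norm0)
  expect_error(remove_unwanted_variation(norm0, k = 80), "smaller than")
  expect_error(remove_unwanted_variation(norm0, control_genes = "nope", k = 1),
               "empty control")

  set.seed(4)
  n <- 80; p <- 60
  batch <- rnorm(n)
  signal <- rnorm(n)
  v <- matrix(rnorm(n * p, sd = 0.3), n, p)
  controls <- paste0("g", 1:20)
  target <- paste0("g", 21:40)
  colnames(v) <- paste0("g", 1:p); rownames(v) <- paste0("c", 1:n)
  v[, 1:20] <- v[, 1:20] + batch            # batch hits all controls
  v[, 21:40] <- v[, 21:40] + signal         # biology on non-controls
  em <- expression_matrix(v, "normalized_log")
  fixed <- remove_unwanted_variation(em, control_genes = controls, k = 1)
  for (g in controls)
    expect_lt(abs(cor(fixed$values[, g], batch)), 0.05)
  for (g in target) {
    pre <- abs(cor(v[, g], signal))
    expect_gte(abs(cor(fixed$values[, g], signal)), 0.9 * pre)
  }
})

test_that("normalization removes library-size confounding", {
  # counts with per-cell capture efficiency: the first PC of the raw log
  # counts tracks library size until size-factor scaling removes it
  set.seed(5)
  n <- 100; p <- 300
  mu <- exp(rnorm(p, 2, 1))
  eff <- 2^rnorm(n, 0, 1.2)
  counts <- matrix(rpois(n * p, outer(eff, mu)), n, p)
  em <- toy_expr(counts, unit = "counts")
  total <- rowSums(counts)
  pc1_raw <- prcomp(log2(counts + 1), rank. = 1)$x[, 1]
  expect_gt(abs(cor(total, pc1_raw)), 0.8)
  sf <- compute_size_factors(em)
  norm <- normalize_by_size_factors(em, sf)
  # size factors remove the scale; the RUV step (all genes are valid
  # controls here since the simulated data carries no biology) removes
  # the residual depth-dependent zero structure
  fixed <- remove_unwanted_variation(norm, control_genes = gene_ids(norm),
                                     k = 1)
  pc1 <- prcomp(fixed$values, rank. = 1)$x[, 1]
  expect_lt(abs(cor(total, pc1)), 0.3)
})

test_that("full QC chain keeps >98% of clean synthetic cells", {
  cfg <- small_sim_config(seed = 71, cnv_specs = list())
  ds <- generate_tumor_dataset(cfg)
  metrics <- compute_cell_qc_metrics(ds$expr)
  res <- filter_cells_by_mad(metrics, k = 4)
  expect_lt(length(res$removed) / nrow(metrics), 0.02)
})
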