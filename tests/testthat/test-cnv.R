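make_genes <- function(n, chrom = rep("chr1", n)) {
  gene_records(paste0("g", seq_len(n)), chrom, seq_len(n) * 1000)
}

test_that("reference normalization subtracts the reference mean per gene", {
  # toy 5-gene, 2-cell tumor vs 3-cell reference, hand computed
  tum <- toy_expr(matrix(c(10, 0, 5, 2, 8,
                           1, 4, 0, 6, 3), 2, 5, byrow = TRUE))
  ref <- toy_expr(matrix(c(2, 2, 2, 2, 2,
                           4, 4, 4, 4, 4,
                           6, 6, 6, 6, 6), 3, 5, byrow = TRUE),
                  cells = c("r1", "r2", "r3"))
  cen <- reference_normalize(tum, ref)
  scaled_t <- log2(tum$values + 1) / 10
  scaled_r <- log2(ref$values + 1) / 10
  expect_equal(cen$centered, sweep(scaled_t, 2, colMeans(scaled_r)))
  expect_equal(cen$scaled_mean, colMeans(scaled_t))
  expect_equal(cen$n_shared, 5)

  # a tumor cell identical to every reference cell maps to a zero profile
  same_ref <- toy_expr(matrix(3, 3, 5), cells = c("r1", "r2", "r3"))
  same_tum <- toy_expr(matrix(3, 1, 5))
  expect_equal(unname(reference_normalize(same_tum, same_ref)$centered[1, ]),
               rep(0, 5))

  # disjoint gene panels are a hard error
  other <- toy_expr(matrix(1, 2, 3), genes = c("x1", "x2", "x3"))
  expect_error(reference_normalize(tum, other), "no genes shared")
})

test_that("CNV inference equals the brute-force moving average on a toy", {
  n <- 12
  set.seed(8)
  vals <- matrix(rnorm(2 * n, 0, 2), nrow = 2,
                 dimnames = list(c("c1", "c2"), paste0("g", 1:n)))
  cen <- structure(list(centered = vals,
                        scaled_mean = setNames(rep(1, n), paste0("g", 1:n)),
                        n_shared = n), class = "cnv_centered")
  cnv <- infer_cnv_profiles(cen, make_genes(n), window = 3, clip = 1.5,
                            min_mean = 0.1)
  clipped <- pmin(pmax(vals, -1.5), 1.5)
  expected <- t(rbind(oracle_moving_average(clipped[1, ], 3),
                      oracle_moving_average(clipped[2, ], 3)))
  expected <- expected - rowMeans(expected)
  expect_equal(unname(cnv$values), unname(expected))
  # final centering invariant: per-gene mean across cells is 0
  expect_equal(unname(rowMeans(cnv$values)), rep(0, n), tolerance = 1e-8)
  # clip bound survives averaging and centering
  expect_true(all(abs(cnv$values) <= 2 * 1.5 + 1e-12))
})

test_that("window 1 is the identity on clipped values before centering", {
  n <- 10
  set.seed(9)
  vals <- matrix(rnorm(3 * n, 0, 2), nrow = 3,
                 dimnames = list(paste0("c", 1:3), paste0("g", 1:n)))
  cen <- structure(list(centered = vals,
                        scaled_mean = setNames(rep(1, n), paste0("g", 1:n))),
                   class = "cnv_centered")
  cnv <- infer_cnv_profiles(cen, make_genes(n), window = 1, clip = 3)
  clipped <- t(pmin(pmax(vals, -3), 3))
  expect_equal(unname(cnv$values), unname(clipped - rowMeans(clipped)))
})

test_that("CNV windows do not cross chromosome boundaries", {
  n <- 12
  vals <- matrix(0, 1, n, dimnames = list("c1", paste0("g", 1:n)))
  vals[1, 6] <- 6   # spike at the last gene of chr1
  genes <- make_genes(n, chrom = rep(c("chr1", "chr2"), each = 6))
  cen <- structure(list(centered = vals,
                        scaled_mean = setNames(rep(1, n), paste0("g", 1:n))),
                   class = "cnv_centered")
  cnv <- infer_cnv_profiles(cen, genes, window = 3, clip = 10)
  # centering over a single cell subtracts each gene's own value -> compare
  # pre-centering smoothing via a 2-cell design instead
  vals2 <- rbind(vals, -vals)
  dimnames(vals2) <- list(c("c1", "c2"), paste0("g", 1:n))
  cen2 <- structure(list(centered = vals2,
                         scaled_mean = setNames(rep(1, n), paste0("g", 1:n))),
                    class = "cnv_centered")
  cnv2 <- infer_cnv_profiles(cen2, genes, window = 3, clip = 10)
  # spike spreads to g5 and g6 (truncated window) but NOT to g7 on chr2
  expect_gt(cnv2$values["g6", "c1"], 0)
  expect_gt(cnv2$values["g5", "c1"], 0)
  expect_equal(cnv2$values["g7", "c1"], 0)

  # even windows are incremented with a message
  expect_message(infer_cnv_profiles(cen2, genes, window = 4, clip = 10),
                 "101|incremented")
})

test_that("CNV inference respects the expression filter and small chromosomes", {
  n <- 10
  vals <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("c1", "c2"), paste0("g", 1:n)))
  sm <- setNames(c(rep(1, 8), 0.01, 0.01), paste0("g", 1:n))
  cen <- structure(list(centered = vals, scaled_mean = sm),
                   class = "cnv_centered")
  cnv <- infer_cnv_profiles(cen, make_genes(n), window = 3, min_mean = 0.1)
  expect_setequal(rownames(cnv$values), paste0("g", 1:8))

  genes <- make_genes(n, chrom = c(rep("chr1", 8), "chr2", "chr2"))
  cen$scaled_mean[] <- 1
  expect_message(infer_cnv_profiles(cen, genes, window = 3),
                 "chr2")
})

test_that("CNV inference is equivariant under cell relabelling", {
  cfg <- small_sim_config(seed = 101, n_patients = 1, cells_per_patient = 30,
                          cell_type_fractions = c(epithelial = 1))
  ds <- generate_tumor_dataset(cfg)
  ref <- generate_normal_reference(30, cfg)
  cnv <- infer_cnv_profiles(reference_normalize(ds$expr, ref), ds$genes,
                            window = 11)
  perm <- sample(nrow(ds$expr$values))
  expr_p <- em_subset(ds$expr, cells = perm)
  cnv_p <- infer_cnv_profiles(reference_normalize(expr_p, ref), ds$genes,
                              window = 11)
  expect_equal(cnv_p$values, cnv$values[, colnames(cnv_p$values)])
})

test_that("implanted dosage gain separates carriers inside the block", {
  cfg <- small_sim_config(
    seed = 111, n_genes = 2000, n_chromosomes = 10, n_patients = 1,
    cells_per_patient = 100, cell_type_fractions = c(epithelial = 1),
    cycling_fraction = 0,
    cnv_specs = list(list(patient = 1, carrier_fraction = 0.5,
                          block = c(201, 350), dosage = 1.5)))
  ds <- generate_tumor_dataset(cfg)
  ref <- generate_normal_reference(100, cfg)
  cnv <- infer_cnv_profiles(reference_normalize(ds$expr, ref), ds$genes)
  block <- intersect(ds$truth$cnv_blocks[[1]], rownames(cnv$values))
  carrier <- ds$truth$cells$cnv_carrier
  block_score <- colMeans(cnv$values[block, ])
  expect_lt(wilcox.test(block_score[carrier], block_score[!carrier],
                        alternative = "greater")$p.value, 1e-6)
})

test_that("correlation map matches the rank oracle and handles degeneracy", {
  v <- cbind(c1 = c(1, 2, 3, 4), c2 = c(2, 4, 6, 8), c3 = c(4, 3, 2, 1),
             c4 = c(1, 3, 2, 4))
  res <- correlation_map(v, group_labels = c("a", "a", "b", "b"))
  # enumeration oracle: Pearson on ranks
  ranks <- apply(v, 2, rank)
  expect_equal(res$correlation, cor(ranks), tolerance = 1e-12)
  expect_equal(unname(diag(res$correlation)), rep(1, 4))
  expect_equal(res$correlation, t(res$correlation))
  expect_equal(res$correlation["c1", "c2"], 1)   # rank-identical cells
  expect_equal(unname(res$group_means["a"]), 1)

  # constant profiles are excluded with a message
  v2 <- cbind(v, c5 = rep(2, 4))
  expect_message(res2 <- correlation_map(v2, c("a", "a", "b", "b", "b")),
                 "c5")
  expect_identical(res2$excluded, "c5")
  expect_false("c5" %in% colnames(res2$correlation))
})

test_that("subclone calling requires a reference and labels only carriers", {
  cfg <- small_sim_config(seed = 121, n_patients = 1, cells_per_patient = 60,
                          cell_type_fractions = c(epithelial = 1),
                          cnv_specs = list(list(patient = 1,
                                                carrier_fraction = 0.5,
                                                block = c(101, 250),
                                                dosage = 1.6)))
  ds <- generate_tumor_dataset(cfg)
  ref <- generate_normal_reference(120, cfg)
  res <- infer_cnv_with_reference(ds$expr, em_subset(ref, cells = 1:60),
                                  em_subset(ref, cells = 61:120),
                                  ds$genes, window = 51)
  calls <- call_cnv_subclones(res$tumor, res$reference)
  expect_true(all(is.na(calls$subclone[!calls$carrier])))
  expect_true(all(!is.na(calls$subclone[calls$carrier])))
  expect_true(all(calls$burden >= 0))
})
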