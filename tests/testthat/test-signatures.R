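test_that("directional scores are mean(up) - mean(down)", {
  v <- rbind(c(1, 3, 5, 2, 4), c(2, 2, 2, 2, 2))
  em <- toy_expr(v, unit = "normalized_log")
  sig <- gene_signature("S", c("g1", "g2", "g3"), c("g4", "g5"))
  s <- score_directional_signature(em, sig)
  expect_equal(unname(s), rowMeans(v[, 1:3]) - rowMeans(v[, 4:5]))

  # empty down list reduces to the plain gene-set mean
  up_only <- gene_signature("U", c("g1", "g2"))
  expect_equal(score_directional_signature(em, up_only),
               score_gene_set(em, c("g1", "g2")))

  # cancellation: up and down lists reading the same values give 0
  v2 <- cbind(v[, 1:2], v[, 1:2])
  colnames(v2) <- c("a1", "a2", "b1", "b2")
  em2 <- expression_matrix(v2, "normalized_log")
  cancel <- gene_signature("C", c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(score_directional_signature(em2, cancel)), c(0, 0))
  # the same algebra on an ad-hoc object with up == down
  raw <- structure(list(name = "raw", up_genes = c("g1", "g2"),
                        down_genes = c("g1", "g2"), directional = TRUE),
                   class = "GeneSignature")
  expect_equal(unname(score_directional_signature(em, raw)), c(0, 0))

  # shift behaviour: down-empty scores shift by c, balanced ones do not
  shifted <- toy_expr(v + 7, unit = "normalized_log")
  expect_equal(score_directional_signature(shifted, up_only),
               score_directional_signature(em, up_only) + 7)
  expect_equal(score_directional_signature(shifted, sig),
               score_directional_signature(em, sig))

  expect_error(score_directional_signature(em, gene_signature("X", "zzz")),
               "X")
  expect_error(gene_signature("bad", c("g1"), c("g1")), "both up and down")
})

test_that("cells are assigned to their top signature with named tie-breaks", {
  scores <- rbind(c(0.2, 0.9, -0.1), c(0.5, 0.5, 0.1), c(-1, -2, -0.5))
  colnames(scores) <- c("B_sig", "A_sig", "C_sig")
  rownames(scores) <- paste0("c", 1:3)
  expect_message(lab <- assign_to_signature(scores), "tied")
  expect_equal(unname(lab), c("A_sig", "A_sig", "C_sig"),
               ignore_attr = TRUE)
  expect_equal(attr(lab, "n_ties"), 1L)
  expect_error(assign_to_signature(scores[, 1, drop = FALSE]), "2 signatures")
})

test_that("signature assignment recovers template-built cells", {
  set.seed(14)
  sigs <- list(gene_signature("alpha", paste0("a", 1:15)),
               gene_signature("beta", paste0("b", 1:15)),
               gene_signature("gamma", paste0("c", 1:15)))
  genes <- unlist(lapply(sigs, `[[`, "up_genes"))
  truth <- sample(c("alpha", "beta", "gamma"), 150, replace = TRUE)
  v <- matrix(rnorm(150 * length(genes), 0, 0.5), 150, length(genes),
              dimnames = list(paste0("c", 1:150), genes))
  for (i in seq_len(150))
    v[i, sigs[[match(truth[i], c("alpha", "beta", "gamma"))]]$up_genes] <-
      v[i, sigs[[match(truth[i], c("alpha", "beta", "gamma"))]]$up_genes] + 2
  em <- expression_matrix(v, "normalized_log")
  lab <- assign_to_signature(score_signatures(em, sigs))
  expect_gte(mean(lab == truth), 0.95)
})

test_that("rank-sum statistics equal the exhaustive enumeration oracle", {
  set.seed(15)
  v <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:5)))
  v[1:12, 2] <- v[1:12, 2] + 2
  em <- expression_matrix(v, "normalized_log")
  labels <- rep(c("t", "o"), c(12, 18))
  res <- derive_cluster_signature(em, labels, "t", n_top = 5, fdr = 1)
  for (g in res$gene_id) {
    x <- v[labels == "t", g]; y <- v[labels == "o", g]
    # U statistic by direct pair enumeration
    u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(res$statistic[res$gene_id == g], u)
  }
  expect_true("g2" %in% res$gene_id[1])
  expect_error(derive_cluster_signature(em, rep("t", 30), "t"), "every cell")
  expect_error(derive_cluster_signature(em, c("t", rep("o", 29)), "t"),
               ">= 10 cells")
})

test_that("implanted up-regulated genes are recovered with positive lfc only", {
  set.seed(16)
  n_genes <- 300
  v <- matrix(rnorm(120 * n_genes), 120, n_genes,
              dimnames = list(paste0("c", 1:120), paste0("g", 1:n_genes)))
  up <- paste0("g", 1:30); down <- paste0("g", 31:60)
  v[1:40, up] <- v[1:40, up] + 2      # 4-fold up in target
  v[1:40, down] <- v[1:40, down] - 2  # down genes must NOT be returned
  em <- expression_matrix(v, "normalized_log")
  labels <- rep(c("t", "rest"), c(40, 80))
  res <- derive_cluster_signature(em, labels, "t", n_top = 30)
  expect_gte(length(intersect(res$gene_id, up)), 28)
  expect_length(intersect(res$gene_id, down), 0)
})

test_that("hypergeometric tail equals the exact combinatorial sum", {
  U <- paste0("u", 1:100)
  target <- U[1:20]
  query <- U[c(1:5, 50:54)]            # overlap 5, |Q| = 10
  res <- overrepresentation_test(query, target, U)
  expect_equal(res$overlap, 5)
  # direct enumeration of the upper tail
  p_oracle <- sum(sapply(5:10, function(k)
    choose(20, k) * choose(80, 10 - k) / choose(100, 10)))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$fold_enrichment, 5 / (10 * 20 / 100))

  # disjoint: overlap 0, p = 1
  res0 <- overrepresentation_test(U[90:95], U[1:10], U)
  expect_equal(res0$overlap, 0)
  expect_equal(res0$p, 1)

  # query inside target: maximal enrichment
  res1 <- overrepresentation_test(U[1:5], target, U)
  expect_equal(res1$fold_enrichment, 100 / 20)
  expect_error(overrepresentation_test("zz", target, U), "outside")
  expect_error(overrepresentation_test(U[1], target, character(0)), "universe")
})

test_that("genes_in_segments matches an interval-scan oracle", {
  genes <- gene_records(paste0("g", 1:10),
                        rep(c("chr1", "chr2"), each = 5),
                        c(100, 200, 300, 400, 500, 100, 200, 300, 400, 500))
  segs <- segment_table(c("chr1", "chr1", "chr2"),
                        c(150, 450, 250), c(350, 600, 999),
                        c("gain", "loss", "gain"), c(3.1, 1.2, 2.8))
  got <- genes_in_segments(segs, genes, "gain")
  oracle <- character(0)
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(segs))) {
      if (segs$call[j] == "gain" && genes$chromosome[i] == segs$chromosome[j] &&
          genes$start[i] >= segs$start[j] && genes$start[i] <= segs$end[j])
        oracle <- c(oracle, genes$gene_id[i])
    }
  }
  expect_setequal(got, unique(oracle))
  expect_setequal(genes_in_segments(segs, genes, "loss"), c("g5"))
  # genes on chromosomes without segments are excluded; unknown segment
  # chromosomes are skipped with a message
  segs2 <- segment_table("chrZ", 1, 1000, "gain", 3)
  expect_message(none <- genes_in_segments(segs2, genes, "gain"), "chrZ")
  expect_length(none, 0)
  expect_error(segment_table("chr1", c(1, 50), c(100, 150),
                             c("gain", "gain")), "overlapping")
})
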