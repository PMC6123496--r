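#' Score cells against a directional gene signature
#'
#' Score = mean expression of the (present) up genes minus mean
#' expression of the (present) down genes. With an empty down list this
#' reduces to the plain gene-set mean. Absent genes are dropped; having
#' no up gene on the panel is an error.
#'
#' @param expr `ExpressionMatrix` (log-scale).
#' @param signature a [gene_signature()].
#' @return named per-cell numeric vector.
#' @export
score_directional_signature <- function(expr, signature) {
  stopifnot(inherits(signature, "GeneSignature"))
  up <- score_gene_set(expr, signature$up_genes, paste0(signature$name, " (up)"))
  if (length(signature$down_genes) == 0) return(up)
  down_present <- intersect(signature$down_genes, colnames(expr$values))
  if (length(down_present) == 0) return(up)
  up - score_gene_set(expr, down_present, paste0(signature$name, " (down)"))
}

#' Score cells against several signatures at once
#'
#' @param expr `ExpressionMatrix` (log-scale).
#' @param signatures list of `GeneSignature` objects.
#' @return cells x signatures score matrix.
#' @export
score_signatures <- function(expr, signatures) {
  m <- vapply(signatures, function(s) score_directional_signature(expr, s),
              numeric(nrow(expr$values)))
  colnames(m) <- vapply(signatures, `[[`, character(1), "name")
  m
}

#' Assign each cell to its highest-scoring signature
#'
#' Per-cell argmax over signature scores; exact ties are broken by
#' signature name order (alphabetical) and reported via the `n_ties`
#' attribute.
#'
#' @param scores cells x signatures numeric matrix (>= 2 columns).
#' @return named character vector of signature names per cell.
#' @export
assign_to_signature <- function(scores) {
  if (ncol(scores) < 2) stop("need at least 2 signatures")
  n_ties <- 0L
  labels <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    top <- max(scores[i, ])
    hits <- colnames(scores)[scores[i, ] == top]
    if (length(hits) > 1) n_ties <- n_ties + 1L
    labels[i] <- sort(hits)[1]
  }
  names(labels) <- rownames(scores)
  if (n_ties > 0) message(n_ties, " cell(s) had tied top signatures; ",
                          "first by name order kept")
  attr(labels, "n_ties") <- n_ties
  labels
}

#' Derive a cluster-selective gene signature by differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares the target
#' cluster's cells against all other cells, p-values are
#' Benjamini-Hochberg adjusted, genes with adjusted p < `fdr` AND
#' positive log fold-change (mean difference on the log scale) are kept,
#' ranked by adjusted p then by |log fold-change|, and the top `n_top`
#' are returned.
#'
#' @param expr `ExpressionMatrix` (log-scale).
#' @param cluster_labels per-cell labels.
#' @param target_cluster label of the cluster of interest (>= 10 cells;
#'   must not be all cells).
#' @param n_top maximum signature size (default 100).
#' @param fdr BH threshold (default 0.05).
#' @return data.frame (`gene_id`, `statistic`, `p`, `padj`, `lfc`) of at
#'   most `n_top` rows, best first.
#' @export
derive_cluster_signature <- function(expr, cluster_labels, target_cluster,
                                     n_top = 100, fdr = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  in_target <- cluster_labels == target_cluster
  if (all(in_target)) stop("target cluster contains every cell")
  if (sum(in_target) < 10) stop("target cluster needs >= 10 cells")
  v <- expr$values
  n1 <- sum(in_target)
  res <- data.frame(gene_id = colnames(v), statistic = NA_real_, p = NA_real_,
                    lfc = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) {
    wt <- suppressWarnings(stats::wilcox.test(v[in_target, j], v[!in_target, j],
                                              exact = FALSE, correct = TRUE))
    res$statistic[j] <- unname(wt$statistic)
    res$p[j] <- wt$p.value
    res$lfc[j] <- mean(v[in_target, j]) - mean(v[!in_target, j])
  }
  res$p[is.na(res$p)] <- 1   # constant genes
  res$padj <- stats::p.adjust(res$p, method = "BH")
  hit <- res[res$padj < fdr & res$lfc > 0, , drop = FALSE]
  hit <- hit[order(hit$padj, -abs(hit$lfc)), , drop = FALSE]
  utils::head(hit, n_top)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a query gene list and a target set drawn from a finite
#' universe, plus the fold enrichment over expectation.
#'
#' @param query_genes,target_set,universe character vectors; query and
#'   target must be subsets of the universe.
#' @return list with `overlap`, `fold_enrichment`, `p`.
#' @export
overrepresentation_test <- function(query_genes, target_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query_genes <- unique(query_genes)
  target_set <- unique(target_set)
  if (length(setdiff(query_genes, universe)) > 0)
    stop("query genes outside the universe")
  if (length(setdiff(target_set, universe)) > 0)
    stop("target set outside the universe")
  k <- length(intersect(query_genes, target_set))
  q <- length(query_genes); t <- length(target_set); u <- length(universe)
  expected <- q * t / u
  p <- stats::phyper(k - 1, t, u - t, q, lower.tail = FALSE)
  list(overlap = k,
       fold_enrichment = if (expected > 0) k / expected else NA_real_,
       p = p)
}
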