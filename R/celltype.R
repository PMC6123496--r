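#' Mean-expression score of a gene set
#'
#' Per-cell mean of the expression of the set's genes. Duplicated genes
#' are de-duplicated and genes absent from the panel are dropped with a
#' message; scoring a set with no gene on the panel is an error.
#'
#' @param expr `ExpressionMatrix` (any log-scale unit).
#' @param gene_set character vector of gene ids.
#' @param set_name used in error messages.
#' @return named per-cell numeric vector.
#' @export
score_gene_set <- function(expr, gene_set, set_name = "gene set") {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, colnames(expr$values))
  if (length(present) == 0)
    stop("no gene of '", set_name, "' is present in the expression matrix")
  if (length(present) < length(gene_set))
    message(length(gene_set) - length(present), " gene(s) of '", set_name,
            "' absent from the panel; dropped")
  rowMeans(expr$values[, present, drop = FALSE])
}

#' Clustering of cells in marker-score space for typing refinement
#'
#' Produces the cluster labels consumed by step 2 of
#' [assign_cell_types()]. Cells are clustered by k-means on the
#' standardized marker-score matrix with deliberate overclustering
#' (`k_per_type` clusters per marker set): within marker-score space,
#' technical noise is averaged across each set's genes and patient batch
#' effects are strongly diluted, so small clusters are nearly pure in
#' cell type and the majority-override rule can clean up ambiguous
#' cells without following batch structure.
#'
#' @param expr `ExpressionMatrix` (log-scale).
#' @param marker_sets named list of marker gene vectors.
#' @param k_per_type clusters per cell type (default 2).
#' @param seed seed for the k-means starts.
#' @return integer cluster label per cell.
#' @export
refinement_clusters <- function(expr, marker_sets, k_per_type = 2, seed = 1) {
  scores <- vapply(names(marker_sets), function(ty)
    score_gene_set(expr, marker_sets[[ty]], ty),
    numeric(nrow(expr$values)))
  k <- min(k_per_type * ncol(scores), nrow(scores) - 1)
  set.seed(as.integer(seed))
  stats::kmeans(scale(scores), centers = k, nstart = 10,
                iter.max = 50)$cluster
}

#' Two-step marker-based cell-type assignment
#'
#' Step 1 scores every cell against each type's marker set and takes the
#' argmax, leaving a cell unassigned when the top score is not positive
#' or does not exceed `margin` times the runner-up. Step 2 uses an
#' independent clustering of all cells to clean up: within any cluster
#' where at least `majority` of the provisionally assigned cells agree on
#' a type, unassigned and minority cells are relabelled to that majority
#' type. Cells in clusters with no clear majority keep their step-1 call.
#'
#' @param expr `ExpressionMatrix` (log-scale).
#' @param marker_sets named list (>= 2 types) of marker gene vectors.
#' @param cluster_labels per-cell labels from any clustering of all
#'   cells; NULL skips step 2.
#' @param margin top-score multiplier over the runner-up (default 1.1).
#' @param majority cluster-majority fraction for the override (0.7).
#' @return list with `cell_type` (named per-cell vector, `"unassigned"`
#'   where ambiguous), `scores` (cells x types matrix) and `step1`
#'   (pre-override labels).
#' @export
assign_cell_types <- function(expr, marker_sets, cluster_labels = NULL,
                              margin = 1.1, majority = 0.7) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (length(marker_sets) < 2) stop("need marker sets for at least 2 types")
  if (any(lengths(marker_sets) == 0)) stop("empty marker set")
  scores <- vapply(names(marker_sets), function(ty)
    score_gene_set(expr, marker_sets[[ty]], ty),
    numeric(nrow(expr$values)))
  n <- nrow(scores)
  labels <- rep("unassigned", n)
  for (i in seq_len(n)) {
    o <- order(scores[i, ], decreasing = TRUE)
    top <- scores[i, o[1]]; second <- scores[i, o[2]]
    if (top > 0 && top >= margin * second) labels[i] <- colnames(scores)[o[1]]
  }
  step1 <- labels
  if (!is.null(cluster_labels)) {
    if (length(cluster_labels) != n)
      stop("cluster_labels must label every cell")
    for (cl in unique(cluster_labels)) {
      ix <- which(cluster_labels == cl)
      assigned <- labels[ix][labels[ix] != "unassigned"]
      if (length(assigned) == 0) next
      tab <- table(assigned)
      if (max(tab) / length(assigned) >= majority)
        labels[ix] <- names(tab)[which.max(tab)]
    }
  }
  names(labels) <- rownames(expr$values)
  names(step1) <- rownames(expr$values)
  list(cell_type = labels, scores = scores, step1 = step1)
}

#' Classify cycling cells from G1-S and G2-M phase scores
#'
#' Phase scores are gene-set means; a data-derived threshold of
#' `median + k * MAD` (raw MAD) is computed per phase across all cells,
#' and a cell is called `high` (cycling) when EITHER phase score strictly
#' exceeds its threshold. With degenerate spread (MAD 0 and all scores
#' equal) every cell is low.
#'
#' @param expr `ExpressionMatrix` (log-scale).
#' @param g1s_set,g2m_set phase gene sets.
#' @param k MADs above the median (default 2).
#' @return list with `cycling` (named `"high"`/`"low"` per cell),
#'   `scores` (cells x 2 matrix) and `thresholds`.
#' @export
classify_cycling <- function(expr, g1s_set, g2m_set, k = 2) {
  g1s <- score_gene_set(expr, g1s_set, "G1-S")
  g2m <- score_gene_set(expr, g2m_set, "G2-M")
  thr <- c(g1s = stats::median(g1s) + k * mad_raw(g1s),
           g2m = stats::median(g2m) + k * mad_raw(g2m))
  high <- g1s > thr["g1s"] | g2m > thr["g2m"]
  cycling <- ifelse(high, "high", "low")
  names(cycling) <- rownames(expr$values)
  list(cycling = cycling, scores = cbind(g1s = g1s, g2m = g2m),
       thresholds = thr)
}
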