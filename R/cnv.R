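#' Normalize tumor expression against a normal reference
#'
#' Both matrices are brought to the log2(TPM+1)/10 scale, restricted to
#' their shared genes, and each gene's mean over the reference cells is
#' subtracted from every tumor cell. The size of the gene intersection is
#' recorded in the result.
#'
#' @param expr tumor `ExpressionMatrix`, unit `raw_tpm`.
#' @param normal_ref reference `ExpressionMatrix`, unit `raw_tpm`.
#' @return list of class `cnv_centered` with `centered` (cells x shared
#'   genes, reference-subtracted), `scaled_mean` (per-gene mean of the
#'   scaled TUMOR expression before subtraction, used by the downstream
#'   expression filter) and `n_shared`.
#' @export
reference_normalize <- function(expr, normal_ref) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(normal_ref, "ExpressionMatrix"))
  if (expr$unit != "raw_tpm" || normal_ref$unit != "raw_tpm")
    stop("reference_normalize expects raw_tpm inputs")
  shared <- intersect(colnames(expr$values), colnames(normal_ref$values))
  if (length(shared) == 0) stop("no genes shared between tumor and reference")
  tum <- log2(expr$values[, shared, drop = FALSE] + 1) / 10
  ref <- log2(normal_ref$values[, shared, drop = FALSE] + 1) / 10
  ref_mean <- colMeans(ref)
  centered <- sweep(tum, 2, ref_mean)
  structure(list(centered = centered, scaled_mean = colMeans(tum),
                 n_shared = length(shared)),
            class = "cnv_centered")
}

#' Infer copy-number profiles by genomically ordered sliding averages
#'
#' In order: (1) genes whose mean scaled expression across cells (before
#' reference subtraction) is below `min_mean` are dropped; (2) remaining
#' genes are arranged by genomic order; (3) reference-subtracted values
#' are clipped to `[-clip, clip]`; (4) each gene's copy-number value per
#' cell is the average of the clipped values in a window of `window`
#' genes centered on it, truncated (shrunk) at chromosome boundaries so
#' chromosomes stay independent; (5) each gene's values are centered
#' across cells. Chromosomes retaining fewer than 3 genes are excluded.
#'
#' @param centered a `cnv_centered` object from [reference_normalize()].
#' @param genes gene record table (see [gene_records()]).
#' @param window sliding-window size in genes (even values are
#'   incremented to the next odd number, with a message). Default 100.
#' @param clip symmetric clipping bound (default 3).
#' @param min_mean expression filter threshold on the scaled mean
#'   (default 0.1).
#' @param keep_genes optional explicit gene set overriding the
#'   `min_mean` filter (used to profile reference cells on exactly the
#'   genes retained for the tumor cells).
#' @return a `CNVMatrix`: list with `values` (ordered genes x cells),
#'   `genes` (records of the retained genes, in order), and the `window`
#'   and `clip` used.
#' @export
infer_cnv_profiles <- function(centered, genes, window = 100, clip = 3,
                               min_mean = 0.1, keep_genes = NULL) {
  stopifnot(inherits(centered, "cnv_centered"))
  if (window %% 2 == 0) {
    window <- window + 1
    message("even window incremented to ", window)
  }
  keep <- if (is.null(keep_genes)) {
    names(centered$scaled_mean)[centered$scaled_mean >= min_mean]
  } else {
    intersect(keep_genes, colnames(centered$centered))
  }
  keep <- intersect(keep, genes$gene_id)
  g <- genes[match(keep, genes$gene_id), , drop = FALSE]
  g <- g[order(g$order_index), , drop = FALSE]
  chr_sizes <- table(g$chromosome)
  small <- names(chr_sizes)[chr_sizes < 3]
  if (length(small) > 0) {
    message("excluding chromosomes with < 3 genes: ",
            paste(small, collapse = ", "))
    g <- g[!g$chromosome %in% small, , drop = FALSE]
  }
  if (nrow(g) == 0) stop("no genes left after expression filtering")
  x <- t(centered$centered[, g$gene_id, drop = FALSE])   # genes x cells
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  half <- (window - 1) / 2
  sm <- x
  for (chr in unique(g$chromosome)) {
    ix <- which(g$chromosome == chr)
    n <- length(ix)
    block <- x[ix, , drop = FALSE]
    # cumulative sums give every truncated centered window in O(n)
    cs <- rbind(0, apply(block, 2, cumsum))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    sm[ix, ] <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  sm <- sm - rowMeans(sm)
  structure(list(values = sm, genes = g, window = window, clip = clip),
            class = "CNVMatrix")
}

#' @export
print.CNVMatrix <- function(x, ...) {
  cat("CNVMatrix:", nrow(x$values), "ordered genes x", ncol(x$values),
      "cells (window", x$window, ", clip", x$clip, ")\n")
  invisible(x)
}

#' Joint tumor-plus-reference CNV inference
#'
#' Profiles tumor cells and held-out normal cells in ONE inference run:
#' both are normalized against the same baseline reference, concatenated,
#' smoothed together and — crucially — centered per gene across ALL cells
#' jointly, the layout in which inferred-CNV heatmaps place normal cells
#' beside tumor cells. Centering on tumor cells alone would split a
#' shared gain symmetrically between carriers and non-carriers (a 50%
#' subclone leaves both halves at +/- half the signal), destroying the
#' burden contrast; the joint normal pool anchors the zero level.
#'
#' @param tumor_expr tumor `ExpressionMatrix` (raw_tpm).
#' @param baseline_ref normal cells whose per-gene mean is subtracted.
#' @param held_out_ref normal cells profiled alongside the tumor cells
#'   and used downstream to calibrate carrier burdens; must be disjoint
#'   from `baseline_ref`.
#' @param genes gene record table.
#' @inheritParams infer_cnv_profiles
#' @return list with `tumor` and `reference` `CNVMatrix` objects sharing
#'   one gene set and one joint centering.
#' @export
infer_cnv_with_reference <- function(tumor_expr, baseline_ref, held_out_ref,
                                     genes, window = 100, clip = 3,
                                     min_mean = 0.1) {
  stopifnot(inherits(tumor_expr, "ExpressionMatrix"),
            inherits(held_out_ref, "ExpressionMatrix"))
  shared_cells <- intersect(cell_ids(tumor_expr), cell_ids(held_out_ref))
  if (length(shared_cells) > 0)
    stop("tumor and held-out reference share cell ids: ", shared_cells[1])
  shared <- intersect(gene_ids(tumor_expr), gene_ids(held_out_ref))
  joint <- expression_matrix(
    rbind(tumor_expr$values[, shared, drop = FALSE],
          held_out_ref$values[, shared, drop = FALSE]), "raw_tpm")
  cen <- reference_normalize(joint, baseline_ref)
  cnv <- infer_cnv_profiles(cen, genes, window = window, clip = clip,
                            min_mean = min_mean)
  split_cnv <- function(cells) {
    structure(list(values = cnv$values[, cells, drop = FALSE],
                   genes = cnv$genes, window = cnv$window, clip = cnv$clip),
              class = "CNVMatrix")
  }
  list(tumor = split_cnv(cell_ids(tumor_expr)),
       reference = split_cnv(cell_ids(held_out_ref)))
}

#' Call CNV-bearing cells and group them into subclones
#'
#' Carriers are cells whose CNV signal exceeds the `q`-th quantile of the
#' same statistic computed on held-out normal cells (run through the same
#' inference, ideally jointly via [infer_cnv_with_reference()]). Two
#' statistics are available. The default, `projection`, is a matched
#' filter: each cell's per-cell-centered profile is projected onto the
#' leave-one-out mean tumor profile (the shared CNV direction), which
#' integrates a coherent event over all of its genes; projections of the
#' reference cells onto the full tumor mean calibrate the null.
#' `mean_square` is the per-cell mean squared profile entry; it is
#' retained for transparency but has little power for focal events,
#' whose squared contribution is diluted by genome-wide smoothed noise.
#' Carriers are grouped by average-linkage hierarchical clustering on
#' Pearson distance between CNV profiles; the tree is cut at the k in
#' 2..`max_clusters` maximizing mean silhouette, collapsing to a single
#' subclone when the best silhouette is below `min_silhouette`.
#'
#' @param cnv `CNVMatrix` for the tumor cells.
#' @param reference_cnv `CNVMatrix` for held-out normal cells.
#' @param q reference quantile used as carrier threshold (default 0.95).
#' @param method carrier statistic, `"projection"` (default) or
#'   `"mean_square"`.
#' @param max_clusters maximum number of subclones tried (default 6).
#' @param min_silhouette minimum mean silhouette to accept a split (0.1).
#' @return data.frame with per-cell `cell_id`, `burden` (mean squared
#'   profile entry, descriptive), `signal` (the carrier statistic),
#'   `carrier`, and `subclone` (integer, NA for non-carriers).
#' @export
call_cnv_subclones <- function(cnv, reference_cnv, q = 0.95,
                               method = c("projection", "mean_square"),
                               max_clusters = 6, min_silhouette = 0.1) {
  stopifnot(inherits(cnv, "CNVMatrix"), inherits(reference_cnv, "CNVMatrix"))
  method <- match.arg(method)
  if (ncol(reference_cnv$values) == 0) stop("no reference cells")
  burden <- colMeans(cnv$values^2)
  if (method == "mean_square") {
    signal <- burden
    ref_signal <- colMeans(reference_cnv$values^2)
  } else {
    # per-cell centering removes library-composition offsets that survive
    # the per-gene centering of the CNV matrix
    pt <- sweep(cnv$values, 2, colMeans(cnv$values))
    pr <- sweep(reference_cnv$values, 2, colMeans(reference_cnv$values))
    n_t <- ncol(pt)
    m_all <- rowMeans(pt)
    # sparsify the filter to genes where the mean profile is an outlier
    # (candidate event regions); this discards thin-spread technical
    # structure (e.g. batch offsets) that tumor cells share
    sparse_filter <- function(m) {
      keep <- abs(m - stats::median(m)) > 3 * mad_raw(m)
      if (!any(keep)) keep <- rep(TRUE, length(m))
      ifelse(keep, m, 0)
    }
    # leave-one-out tumor mean (and leave-one-out sparsification) keeps
    # the null distribution of tumor cells identical to that of the
    # reference cells
    signal <- vapply(seq_len(n_t), function(j) {
      m_j <- if (n_t > 1) (n_t * m_all - pt[, j]) / (n_t - 1) else m_all
      mean(pt[, j] * sparse_filter(m_j))
    }, numeric(1))
    names(signal) <- colnames(pt)
    ref_signal <- colMeans(pr * sparse_filter(m_all))
  }
  thr <- stats::quantile(ref_signal, q, names = FALSE)
  carrier <- signal > thr
  subclone <- rep(NA_integer_, length(burden))
  if (sum(carrier) >= 4) {
    prof <- cnv$values[, carrier, drop = FALSE]
    d <- 1 - stats::cor(prof)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    best_k <- 1L; best_sil <- -Inf
    for (k in 2:min(max_clusters, sum(carrier) - 1)) {
      lab <- stats::cutree(hc, k = k)
      sil <- mean_silhouette(lab, d)
      if (!is.na(sil) && sil > best_sil) {
        best_sil <- sil; best_k <- k
      }
    }
    if (best_sil >= min_silhouette) {
      subclone[carrier] <- stats::cutree(hc, k = best_k)
    } else {
      subclone[carrier] <- 1L
    }
  } else if (any(carrier)) {
    subclone[carrier] <- 1L
  }
  data.frame(cell_id = colnames(cnv$values), burden = burden,
             signal = unname(signal), carrier = unname(carrier),
             subclone = subclone, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise Spearman correlation map with group summaries
#'
#' Spearman rank correlation over genes for every pair of cells, plus the
#' mean within-group off-diagonal correlation for each supplied group.
#' Cells with a constant profile have undefined rank correlations; they
#' are excluded with a message.
#'
#' @param mat numeric matrix (features x cells), an `ExpressionMatrix`
#'   (transposed internally) or a `CNVMatrix`.
#' @param group_labels per-cell group labels (named or aligned).
#' @return list with `correlation` (cells x cells), `group_means` (named
#'   vector), and `excluded` (constant-profile cell ids).
#' @export
correlation_map <- function(mat, group_labels) {
  if (inherits(mat, "ExpressionMatrix")) mat <- t(mat$values)
  if (inherits(mat, "CNVMatrix")) mat <- mat$values
  if (length(group_labels) != ncol(mat))
    stop("group_labels must label every cell")
  constant <- apply(mat, 2, function(col) max(col) == min(col))
  excluded <- colnames(mat)[constant]
  if (any(constant)) {
    message("excluding constant-profile cells: ",
            paste(excluded, collapse = ", "))
    mat <- mat[, !constant, drop = FALSE]
    group_labels <- group_labels[!constant]
  }
  cm <- stats::cor(mat, method = "spearman")
  groups <- unique(group_labels)
  gm <- vapply(groups, function(g) {
    ix <- which(group_labels == g)
    if (length(ix) < 2) return(NA_real_)
    sub <- cm[ix, ix]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(gm) <- groups
  list(correlation = cm, group_means = gm, excluded = excluded)
}
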