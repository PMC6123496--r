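#' Per-cell quality-control metrics
#'
#' Computes the three metrics used to flag low-quality cells: (i) library
#' size (per-cell value sum), (ii) number of expressed genes
#' (log2(value+1) >= `expr_threshold`), and (iii) total endogenous mRNA.
#' When no endogenous-gene annotation is supplied, metric (iii)
#' degenerates to the library size; this duplication is reported in the
#' returned log.
#'
#' @param expr `ExpressionMatrix` with unit `raw_tpm` or `counts`.
#' @param endogenous_genes optional character vector restricting metric
#'   (iii); default all genes.
#' @param expr_threshold log2(value+1) threshold above which a gene counts
#'   as expressed (default 0.1).
#' @return data.frame with columns `cell_id`, `library_size`,
#'   `n_genes_expressed`, `total_mrna`; attribute `log` records
#'   degeneracy.
#' @export
compute_cell_qc_metrics <- function(expr, endogenous_genes = NULL,
                                    expr_threshold = 0.1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!expr$unit %in% c("raw_tpm", "counts"))
    stop("QC metrics are defined on raw_tpm or counts, got ", expr$unit)
  v <- expr$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty expression matrix")
  library_size <- rowSums(v)
  n_genes_expressed <- rowSums(log2(v + 1) >= expr_threshold)
  degenerate <- is.null(endogenous_genes)
  endo <- if (degenerate) colnames(v) else intersect(endogenous_genes, colnames(v))
  total_mrna <- rowSums(v[, endo, drop = FALSE])
  out <- data.frame(cell_id = rownames(v), library_size = library_size,
                    n_genes_expressed = n_genes_expressed,
                    total_mrna = total_mrna, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "log") <- list(total_mrna_degenerate = degenerate)
  out
}

#' Remove low-quality cells by a robust MAD rule
#'
#' A cell is removed when, for ANY of the three metrics, its
#' log2(metric+1) falls strictly below `median - k * MAD` of that
#' metric's log values across cells (union of failures). The MAD is the
#' raw median absolute deviation without the 1.4826 consistency constant
#' (see [mad_raw()]); set `mad_constant` to change this.
#'
#' @param metrics output of [compute_cell_qc_metrics()].
#' @param k number of MADs below the median (default 4).
#' @param mad_constant multiplier on the raw MAD (default 1).
#' @return list with `kept` (cell ids), `removed` (cell ids),
#'   `removed_by_metric` (named counts), and `thresholds` (per-metric
#'   log-scale cutoffs).
#' @export
filter_cells_by_mad <- function(metrics, k = 4, mad_constant = 1) {
  if (k <= 0) stop("k must be > 0")
  if (nrow(metrics) < 3) stop("need at least 3 cells for a stable median/MAD")
  metric_cols <- c("library_size", "n_genes_expressed", "total_mrna")
  fail <- matrix(FALSE, nrow(metrics), length(metric_cols),
                 dimnames = list(metrics$cell_id, metric_cols))
  thresholds <- numeric(length(metric_cols))
  names(thresholds) <- metric_cols
  for (m in metric_cols) {
    lx <- log2(metrics[[m]] + 1)
    thresholds[m] <- stats::median(lx) - k * mad_raw(lx, mad_constant)
    fail[, m] <- lx < thresholds[m]
  }
  removed <- metrics$cell_id[rowSums(fail) > 0]
  list(kept = setdiff(metrics$cell_id, removed), removed = removed,
       removed_by_metric = colSums(fail), thresholds = thresholds)
}

#' Remove genes silent in nearly all cells of every patient
#'
#' For each patient, a gene is "silent" when log2(TPM+1) < `threshold` in
#' at least `prevalence` of that patient's cells. The removed set is the
#' INTERSECTION of the per-patient silent sets — a gene expressed in even
#' one patient's tumor is retained.
#'
#' @param expr `ExpressionMatrix` (unit `raw_tpm`).
#' @param patient_labels per-cell patient ids aligned with `cell_ids(expr)`.
#' @param threshold log2(TPM+1) expression cutoff (default 0.1).
#' @param prevalence silent-fraction cutoff per patient (default 0.95).
#' @param patients patient ids expected in the cohort; a listed patient
#'   with no cells is an error. Defaults to the labels present.
#' @return list with `kept` and `removed` gene id vectors.
#' @export
filter_genes_by_prevalence <- function(expr, patient_labels, threshold = 0.1,
                                       prevalence = 0.95,
                                       patients = unique(patient_labels)) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (length(patient_labels) != nrow(expr$values))
    stop("patient_labels must cover all cells")
  if (any(is.na(patient_labels))) stop("patient_labels must cover all cells")
  lv <- log2(expr$values + 1) < threshold
  silent_all <- rep(TRUE, ncol(lv))
  for (p in patients) {
    ix <- patient_labels == p
    if (!any(ix)) stop("patient ", p, " has 0 cells")
    frac_silent <- colMeans(lv[ix, , drop = FALSE])
    silent_all <- silent_all & (frac_silent >= prevalence)
  }
  list(kept = colnames(lv)[!silent_all], removed = colnames(lv)[silent_all])
}
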