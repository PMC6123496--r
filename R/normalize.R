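#' Transform TPM values into relative counts (mode-anchored)
#'
#' Simplified census-style transform: within each cell the most common
#' nonzero TPM value is assumed to correspond to one transcript, so
#' counts = round(TPM * scale) with scale = 1/mode. When no nonzero value
#' repeats, the anchor falls back to the median nonzero TPM. The scale is
#' bounded below by `min_scale`; the map is monotone within each cell.
#' A `passthrough` mode returns the TPM values unchanged (relabelled as
#' counts) for pipelines that skip this step.
#'
#' @param expr `ExpressionMatrix` with unit `raw_tpm`.
#' @param mode `"mode_anchored"` (default) or `"passthrough"`.
#' @param min_scale lower bound on the per-cell scale (default 1e-6).
#' @return `ExpressionMatrix` with unit `counts`; attribute `log` lists
#'   cells with no nonzero values (their rows stay zero).
#' @export
estimate_relative_counts <- function(expr, mode = c("mode_anchored", "passthrough"),
                                     min_scale = 1e-6) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$unit != "raw_tpm") stop("expected unit raw_tpm, got ", expr$unit)
  mode <- match.arg(mode)
  v <- expr$values
  if (mode == "passthrough") {
    out <- expression_matrix(v, "counts")
    attr(out, "log") <- list(mode = "passthrough", zero_cells = character(0))
    return(out)
  }
  counts <- v
  zero_cells <- character(0)
  for (i in seq_len(nrow(v))) {
    nz <- v[i, v[i, ] > 0]
    if (length(nz) == 0) {
      zero_cells <- c(zero_cells, rownames(v)[i])
      next
    }
    tab <- table(nz)
    anchor <- if (max(tab) > 1) {
      as.numeric(names(tab)[which.max(tab)])   # ties: smallest value wins
    } else {
      stats::median(nz)
    }
    scale <- max(1 / anchor, min_scale)
    counts[i, ] <- round(v[i, ] * scale)
  }
  out <- expression_matrix(counts, "counts")
  attr(out, "log") <- list(mode = "mode_anchored", zero_cells = zero_cells)
  out
}

# Least-squares pooled deconvolution of size factors (ring pools).
# Needs enough cells for distinct pools to span the ring; below the
# smallest pool size the system is rank-deficient, so fall back to
# library-size factors.
deconvolution_factors <- function(v, pool_sizes = c(21, 41, 61)) {
  n <- nrow(v)
  if (n < min(pool_sizes)) {
    message("deconvolution needs >= ", min(pool_sizes),
            " cells; using library-size factors")
    return(rowSums(v))
  }
  pool_sizes <- pool_sizes[pool_sizes <= n]
  ref <- colMeans(v)
  use <- ref > 0
  ord <- order(rowSums(v))                 # ring ordered by library size
  rows <- list(); rhs <- numeric(0)
  for (ps in pool_sizes) {
    for (s in seq_len(n)) {
      members <- ord[((s - 1 + seq_len(ps) - 1) %% n) + 1]
      pooled <- colSums(v[members, , drop = FALSE])
      theta <- stats::median(pooled[use] / ref[use])
      row <- numeric(n); row[members] <- 1
      rows[[length(rows) + 1]] <- row
      rhs <- c(rhs, theta)
    }
  }
  A <- do.call(rbind, rows)
  fit <- stats::lm.fit(A, rhs)
  pmax(fit$coefficients, 0)
}

#' Per-cell size factors
#'
#' Default method is the median-ratio estimator: each cell's factor is
#' the median, over genes nonzero in every cell, of its counts divided by
#' the gene's geometric mean. With fewer than `min_shared_genes` such
#' genes the estimator falls back to library-size factors. A pooled
#' least-squares deconvolution variant (ring pools of sizes 21/41/61) is
#' available as `method = "deconvolution"`. All-zero cells get factor 0
#' (and are expected to be removed downstream); factors are rescaled to
#' mean 1 over the cells with positive factors.
#'
#' @param counts `ExpressionMatrix` with unit `counts`.
#' @param method `"median_ratio"` (default), `"library_size"` or
#'   `"deconvolution"`.
#' @param min_shared_genes fall-back threshold for the median-ratio
#'   method (default 100).
#' @return named numeric vector of size factors (mean 1 over nonzero
#'   factors); attribute `log` records the method actually used.
#' @export
compute_size_factors <- function(counts,
                                 method = c("median_ratio", "library_size",
                                            "deconvolution"),
                                 min_shared_genes = 100) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts") stop("expected unit counts, got ", counts$unit)
  method <- match.arg(method)
  v <- counts$values
  if (nrow(v) == 0) stop("empty count matrix")
  lib <- rowSums(v)
  used <- method
  if (method == "median_ratio") {
    shared <- colSums(v > 0) == nrow(v)
    if (sum(shared) >= min_shared_genes) {
      sub <- v[, shared, drop = FALSE]
      geo <- exp(colMeans(log(sub)))
      f <- apply(sweep(sub, 2, geo, "/"), 1, stats::median)
    } else {
      used <- "library_size_fallback"
      f <- lib
    }
  } else if (method == "library_size") {
    f <- lib
  } else {
    f <- deconvolution_factors(v)
  }
  f[lib == 0] <- 0
  pos <- f > 0
  if (any(pos)) f[pos] <- f[pos] / mean(f[pos])
  names(f) <- rownames(v)
  attr(f, "log") <- list(method = used, n_zero_factor = sum(!pos))
  f
}

#' Normalize counts by size factors and log-transform
#'
#' Cells with size factor 0 are dropped (mirroring the rule that
#' zero-factor cells leave the analysis); remaining counts are divided by
#' their factor and transformed as log2(x + 1).
#'
#' @param counts `ExpressionMatrix` with unit `counts`.
#' @param size_factors output of [compute_size_factors()].
#' @return `ExpressionMatrix` with unit `normalized_log`; attribute `log`
#'   lists removed zero-factor cells.
#' @export
normalize_by_size_factors <- function(counts, size_factors) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "counts") stop("expected unit counts, got ", counts$unit)
  sf <- size_factors[rownames(counts$values)]
  keep <- !is.na(sf) & sf > 0
  v <- counts$values[keep, , drop = FALSE] / sf[keep]
  out <- expression_matrix(log2(v + 1), "normalized_log")
  attr(out, "log") <- list(removed_zero_factor = rownames(counts$values)[!keep])
  out
}

#' Remove unwanted variation using control genes
#'
#' Factor-based correction in the RUV spirit: the first `k` left singular
#' vectors of the column-centered control-gene submatrix (cells x
#' controls) estimate unwanted factors, and every gene is residualized on
#' them (with intercept). `k = 0` is the identity.
#'
#' @param normexpr `ExpressionMatrix` with unit `normalized_log`.
#' @param control_genes gene ids assumed to carry only unwanted
#'   variation; default (NULL) uses the `n_default_controls`
#'   least-variable genes.
#' @param k number of unwanted factors (default 1).
#' @param n_default_controls size of the default control set (500).
#' @return corrected `ExpressionMatrix`, unit `normalized_log`.
#' @export
remove_unwanted_variation <- function(normexpr, control_genes = NULL, k = 1,
                                      n_default_controls = 500) {
  stopifnot(inherits(normexpr, "ExpressionMatrix"))
  if (normexpr$unit != "normalized_log")
    stop("expected unit normalized_log, got ", normexpr$unit)
  if (k < 0) stop("k must be >= 0")
  if (k == 0) return(normexpr)
  v <- normexpr$values
  if (k >= nrow(v)) stop("k must be smaller than the number of cells")
  if (is.null(control_genes)) {
    vars <- apply(v, 2, stats::var)
    control_genes <- names(sort(vars))[seq_len(min(n_default_controls, ncol(v)))]
  }
  control_genes <- intersect(control_genes, colnames(v))
  if (length(control_genes) == 0) stop("empty control gene set with k > 0")
  ctrl <- scale(v[, control_genes, drop = FALSE], center = TRUE, scale = FALSE)
  W <- svd(ctrl, nu = k, nv = 0)$u
  X <- cbind(1, W)
  # residualize every gene on the unwanted factors
  beta <- solve(crossprod(X), crossprod(X, v))
  resid <- v - X %*% beta
  expression_matrix(resid, "normalized_log")
}
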