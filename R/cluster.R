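#' Regress patient effects out of expression
#'
#' Per gene, expression is fit on patient indicator variables (with
#' intercept) by least squares; with one-hot patients this amounts to
#' removing each patient's per-gene mean. Patients contributing a single
#' cell get residual 0 for that cell (perfect fit) and trigger a warning.
#'
#' @param expr `ExpressionMatrix` (unit `normalized_log`).
#' @param patient_labels per-cell patient ids.
#' @return residual matrix (cells x genes).
#' @export
regress_out_patient <- function(expr, patient_labels) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (length(patient_labels) != nrow(expr$values) || any(is.na(patient_labels)))
    stop("every cell needs a patient label")
  singletons <- names(which(table(patient_labels) == 1))
  if (length(singletons) > 0)
    warning("patient(s) with a single cell get residual 0: ",
            paste(singletons, collapse = ", "))
  v <- expr$values
  resid <- v
  for (p in unique(patient_labels)) {
    ix <- patient_labels == p
    resid[ix, ] <- sweep(v[ix, , drop = FALSE], 2,
                         colMeans(v[ix, , drop = FALSE]))
  }
  resid
}

#' Low-dimensional embedding of cells
#'
#' Projects cells onto their top `n_pcs` principal components and then to
#' a `dims`-dimensional embedding. The nonlinear step is pluggable: the
#' default (`method = "pca"`) simply keeps the leading components with a
#' deterministic sign convention, which is sufficient for the density
#' clustering downstream; `method = "tsne"` runs Barnes-Hut t-SNE when
#' the Rtsne package is available. Deterministic given `seed`.
#'
#' @param residuals numeric matrix (cells x genes), e.g. from
#'   [regress_out_patient()].
#' @param dims embedding dimensionality (default 2).
#' @param seed integer seed.
#' @param n_pcs number of principal components retained first (50).
#' @param method `"pca"` or `"tsne"`.
#' @return cells x `dims` coordinate matrix.
#' @export
embed_cells <- function(residuals, dims = 2, seed = 1, n_pcs = 50,
                        method = c("pca", "tsne")) {
  method <- match.arg(method)
  n <- nrow(residuals)
  if (n < 10) stop("need at least 10 cells to embed")
  if (dims >= n) stop("dims must be smaller than the number of cells")
  set.seed(as.integer(seed))
  k <- min(n_pcs, n - 1, ncol(residuals))
  pcs <- stats::prcomp(residuals, center = TRUE, scale. = FALSE,
                       rank. = k)$x
  # sign convention: largest-magnitude score positive, per component
  for (j in seq_len(ncol(pcs))) {
    i <- which.max(abs(pcs[, j]))
    if (pcs[i, j] < 0) pcs[, j] <- -pcs[, j]
  }
  if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("method 'tsne' requires the Rtsne package")
    out <- Rtsne::Rtsne(pcs, dims = dims, pca = FALSE,
                        perplexity = min(30, floor((n - 1) / 3)),
                        theta = 0.5, check_duplicates = FALSE)$Y
  } else {
    out <- pcs[, seq_len(dims), drop = FALSE]
  }
  rownames(out) <- rownames(residuals)
  colnames(out) <- paste0("dim", seq_len(dims))
  out
}

#' Density-peak clustering with automatic cluster count
#'
#' Implements the decision-graph density-peak algorithm: the local
#' density rho_i is computed with a Gaussian kernel of bandwidth d_c
#' (the `dc_quantile` quantile of all pairwise distances); delta_i is
#' the distance to the nearest point of higher density (the global
#' density peak gets the maximum distance); cluster centers are the
#' points whose product gamma = rho * delta is an upper outlier on the
#' log scale (log gamma > median + `gamma_mads` * raw MAD of log gamma;
#' gamma is heavy-tailed, so the outlier rule is applied to its
#' logarithm); every remaining point
#' inherits the label of its nearest point of higher density. The
#' `count` kernel (number of points within d_c) is available but at the
#' cell counts typical here it produces heavily tied integer densities,
#' which destabilize delta; the continuous kernel is the standard remedy
#' and the default. Density ties are broken by smaller total distance,
#' then input index, making the procedure deterministic.
#'
#' @param coordinates points x dims numeric matrix.
#' @param dc_quantile quantile of pairwise distances defining d_c
#'   (default 0.02).
#' @param gamma_mads MAD multiplier for center selection (default 3).
#' @param kernel `"gaussian"` (default) or `"count"`.
#' @return list with `labels` (integer per point; cluster 1 is the
#'   strongest center), `centers` (indices), `rho`, `delta`, `dc`.
#' @export
density_peak_cluster <- function(coordinates, dc_quantile = 0.02,
                                 gamma_mads = 3,
                                 kernel = c("gaussian", "count")) {
  kernel <- match.arg(kernel)
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (n < 10) stop("need at least 10 points")
  D <- as.matrix(stats::dist(coordinates))
  pd <- D[upper.tri(D)]
  if (max(pd) == 0) {
    return(list(labels = rep(1L, n), centers = 1L, rho = rep(n - 1, n),
                delta = rep(0, n), dc = 0))
  }
  dc <- stats::quantile(pd, dc_quantile, names = FALSE)
  if (dc == 0) dc <- min(pd[pd > 0])
  rho <- if (kernel == "gaussian") {
    unname(rowSums(exp(-(D / dc)^2)) - 1)
  } else {
    unname(rowSums(D <= dc) - 1)
  }
  # strict density order; ties by total distance (denser = closer to the
  # rest), then index
  ord <- order(-rho, rowSums(D), seq_len(n))
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(D)
  nn_higher[ord[1]] <- NA_integer_
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1)]
    j <- higher[which.min(D[i, higher])]
    delta[i] <- D[i, j]
    nn_higher[i] <- j
  }
  gamma <- rho * delta
  lg <- log(pmax(gamma, .Machine$double.xmin))
  cutoff <- stats::median(lg) + gamma_mads * mad_raw(lg)
  cand <- which(lg > cutoff & gamma > 0)
  if (length(cand) == 0) {
    centers <- ord[1]
  } else {
    # candidates are gamma outliers; true centers additionally stand off
    # from the continuum by a large gap in log gamma, so cut the sorted
    # candidate values at their largest consecutive gap (the value just
    # below the last candidate closes the sequence)
    cand <- cand[order(-lg[cand], cand)]
    below <- if (length(cand) < n) max(lg[-cand]) else min(lg[cand]) - 1
    vals <- c(lg[cand], below)
    k <- which.max(vals[-length(vals)] - vals[-1])
    centers <- cand[seq_len(k)]
  }
  centers <- centers[order(-gamma[centers], centers)]
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  if (labels[ord[1]] == 0) {
    # global density peak was not selected as a center: attach it to the
    # nearest center so the inheritance chain stays grounded
    labels[ord[1]] <- labels[centers[which.min(D[ord[1], centers])]]
  }
  for (r in seq_len(n)) {
    i <- ord[r]
    if (labels[i] == 0) labels[i] <- labels[nn_higher[i]]
  }
  list(labels = labels, centers = centers, rho = rho, delta = delta, dc = dc)
}
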