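# Shared fixtures: everything is built in code at test time.

# A small but structurally complete simulation config (fast to generate).
small_sim_config <- function(seed = 11, ...) {
  defaults <- list(
    n_genes = 600, n_patients = 3, cells_per_patient = c(40, 50, 60),
    cell_type_fractions = c(epithelial = 0.6, t_cell = 0.2, b_cell = 0.2),
    n_marker_genes = 20, marker_effect = 3,
    cycling_fraction = 0.15, cycling_effect = 2, n_cycling_genes = 15,
    cnv_specs = list(list(patient = 1, carrier_fraction = 0.5,
                          block = c(51, 200), dosage = 1.5)),
    patient_batch_sd = 0.3, n_chromosomes = 4,
    seed = seed)
  over <- list(...)
  defaults[names(over)] <- over   # wholesale replacement, never recursive
  do.call(simulation_config, defaults)
}

# Tiny deterministic expression matrix (cells x genes).
toy_expr <- function(values, unit = "raw_tpm",
                     cells = paste0("c", seq_len(nrow(values))),
                     genes = paste0("g", seq_len(ncol(values)))) {
  dimnames(values) <- list(cells, genes)
  expression_matrix(values, unit)
}

# Brute-force truncated centered moving average over one chromosome,
# independent of the package implementation (plain loops).
oracle_moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

# Independent density-peak computation: literal rho/delta/gamma per the
# published recipe, O(n^2) loops, same kernel and tie conventions as
# documented.
oracle_density_peak <- function(coords, dc_quantile = 0.02, gamma_mads = 3,
                                kernel = "gaussian") {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  dc <- unname(quantile(D[upper.tri(D)], dc_quantile))
  rho <- sapply(seq_len(n), function(i) {
    if (kernel == "gaussian") sum(exp(-(D[i, -i] / dc)^2))
    else sum(D[i, -i] <= dc)
  })
  ord <- order(-rho, rowSums(D), seq_len(n))
  delta <- numeric(n); nn <- rep(NA_integer_, n)
  delta[ord[1]] <- max(D)
  for (r in 2:n) {
    i <- ord[r]
    best <- Inf
    for (q in seq_len(r - 1)) {
      j <- ord[q]
      if (D[i, j] < best) { best <- D[i, j]; nn[i] <- j }
    }
    delta[i] <- best
  }
  gamma <- rho * delta
  lg <- log(pmax(gamma, .Machine$double.xmin))
  cutoff <- median(lg) + gamma_mads * median(abs(lg - median(lg)))
  cand <- which(lg > cutoff & gamma > 0)
  if (length(cand) == 0) {
    centers <- ord[1]
  } else {
    cand <- cand[order(-lg[cand], cand)]
    below <- if (length(cand) < n) max(lg[-cand]) else min(lg[cand]) - 1
    vals <- c(lg[cand], below)
    k <- which.max(vals[-length(vals)] - vals[-1])
    centers <- cand[seq_len(k)]
  }
  centers <- centers[order(-gamma[centers], centers)]
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  if (labels[ord[1]] == 0)
    labels[ord[1]] <- labels[centers[which.min(D[ord[1], centers])]]
  for (r in seq_len(n)) {
    i <- ord[r]
    if (labels[i] == 0) labels[i] <- labels[nn[i]]
  }
  list(labels = labels, rho = rho, delta = delta, centers = centers)
}

# Hand-rolled K-group log-rank pieces for two groups (O-E and V summed
# over event times).
oracle_logrank_2group <- function(g, times, events) {
  g <- as.integer(factor(g))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    risk <- times >= t
    n <- sum(risk); d <- sum(times == t & events == 1)
    n1 <- sum(risk & g == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  (O - E)^2 / V
}
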