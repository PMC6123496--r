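#' Simulation configuration for synthetic TNBC single-cell datasets
#'
#' Defaults describe the emulated study design: six patients contributing
#' roughly 80-290 cells each, an epithelial-dominant cell-type mix with
#' immune/stromal/endothelial minorities, marker genes elevated ~3 log2
#' units in their own type, a minority of cycling cells, two clonal CNV
#' gain blocks (150 genes, dosage 1.5, half the epithelial cells of one
#' patient each), per-patient batch effects and uniform dropout. Base
#' expression is log-normal; all effects are multiplicative.
#'
#' @param n_genes number of genes on the panel.
#' @param n_patients number of patients.
#' @param cells_per_patient integer vector (recycled to `n_patients`).
#' @param cell_type_fractions named fractions over the supported cell
#'   types; must lie in \[0,1\] and sum to 1 (values summing below 1 are
#'   renormalized with a message).
#' @param n_marker_genes marker genes per cell type.
#' @param marker_effect log2-fold elevation of a type's markers in cells
#'   of that type.
#' @param cycling_fraction fraction of epithelial cells that cycle.
#' @param cycling_fraction_other cycling fraction among non-epithelial
#'   cells; the default (1/40 of the epithelial fraction) makes nearly
#'   all cycling cells epithelial, the regime observed in these tumors.
#' @param cycling_effect log2-fold elevation of G1-S/G2-M genes in
#'   cycling cells.
#' @param n_cycling_genes genes per cell-cycle phase set.
#' @param cycling_offstate log2 downshift of the cell-cycle gene sets in
#'   non-epithelial, non-cycling cells (default 2): proliferation
#'   programs are essentially silent in the quiescent immune and stromal
#'   compartments of these tumors, which is what keeps detected cycling
#'   cells almost entirely epithelial.
#' @param cnv_specs list of CNV subclone specs, each a list with fields
#'   `patient` (index), `carrier_fraction` (of that patient's epithelial
#'   cells), `block` (length-2 contiguous order-index range) and `dosage`
#'   (multiplier > 0 applied to raw expression on the block).
#' @param patient_batch_sd SD of per-patient, per-gene offsets on the
#'   natural-log scale.
#' @param base_logmean,base_logsd mean and SD of per-cell log-normal
#'   noise around each gene's log-mean.
#' @param gene_logmean_sd SD of the per-gene log-means around
#'   `base_logmean` (expression heterogeneity across genes).
#' @param dropout_rate ceiling dropout probability (reached by the
#'   lowest-expression genes).
#' @param dropout_model `"logistic_tpm"` (default): per-gene dropout
#'   probability `dropout_rate / (1 + (TPM_g / knee)^hill)` where `TPM_g`
#'   is the gene's expected TPM — the strong expression dependence of
#'   dropout in full-length scRNA-seq protocols, under which
#'   well-expressed genes are essentially always detected. `"uniform"`:
#'   expression-independent Bernoulli at `dropout_rate`, the analytically
#'   transparent model used for null calibrations.
#' @param dropout_knee_tpm expected TPM at which dropout is half its
#'   ceiling (default 5).
#' @param dropout_hill steepness of the dropout curve (default 2).
#' @param n_chromosomes chromosomes over which genes are laid out
#'   contiguously.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_patients = 6,
                              cells_per_patient = c(80, 120, 160, 200, 240, 286),
                              cell_type_fractions = c(epithelial = 0.70,
                                                      t_cell = 0.12,
                                                      b_cell = 0.05,
                                                      macrophage = 0.06,
                                                      stroma = 0.04,
                                                      endothelial = 0.03),
                              n_marker_genes = 25,
                              marker_effect = 3,
                              cycling_fraction = 0.15,
                              cycling_fraction_other = cycling_fraction / 40,
                              cycling_effect = 2,
                              n_cycling_genes = 20,
                              cycling_offstate = 2,
                              cnv_specs = list(
                                list(patient = 1, carrier_fraction = 0.5,
                                     block = c(101, 250), dosage = 1.5),
                                list(patient = 2, carrier_fraction = 0.5,
                                     block = c(1101, 1250), dosage = 1.5)),
                              patient_batch_sd = 0.5,
                              base_logmean = 1, base_logsd = 1,
                              gene_logmean_sd = 1.5,
                              dropout_rate = 0.8,
                              dropout_model = c("logistic_tpm", "uniform"),
                              dropout_knee_tpm = 5,
                              dropout_hill = 2,
                              n_chromosomes = 10,
                              seed = 1) {
  fr <- cell_type_fractions
  types <- c("epithelial", "t_cell", "b_cell", "macrophage", "stroma",
             "endothelial")
  if (is.null(names(fr)) || !all(names(fr) %in% types))
    stop("cell_type_fractions must be named with supported cell types")
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-8)
    stop("infeasible cell_type_fractions: must lie in [0,1] and sum to <= 1")
  if (sum(fr) < 1 - 1e-8) {
    message("cell_type_fractions sum to ", round(sum(fr), 3),
            "; renormalizing to 1")
    fr <- fr / sum(fr)
  }
  for (sp in cnv_specs) {
    if (sp$dosage <= 0) stop("CNV dosage multiplier must be > 0")
    if (sp$block[1] < 1 || sp$block[2] > n_genes || sp$block[1] > sp$block[2])
      stop("CNV block range out of bounds")
    if (sp$carrier_fraction < 0 || sp$carrier_fraction > 1)
      stop("carrier_fraction must lie in [0,1]")
    if (sp$patient < 1 || sp$patient > n_patients)
      stop("CNV spec names patient ", sp$patient, " of ", n_patients)
  }
  cfg <- list(n_genes = n_genes, n_patients = n_patients,
              cells_per_patient = rep_len(cells_per_patient, n_patients),
              cell_type_fractions = fr, n_marker_genes = n_marker_genes,
              marker_effect = marker_effect,
              cycling_fraction = cycling_fraction,
              cycling_fraction_other = cycling_fraction_other,
              cycling_effect = cycling_effect,
              n_cycling_genes = n_cycling_genes,
              cycling_offstate = cycling_offstate,
              cnv_specs = cnv_specs, patient_batch_sd = patient_batch_sd,
              base_logmean = base_logmean, base_logsd = base_logsd,
              gene_logmean_sd = gene_logmean_sd,
              dropout_rate = dropout_rate,
              dropout_model = match.arg(dropout_model),
              dropout_knee_tpm = dropout_knee_tpm,
              dropout_hill = dropout_hill,
              n_chromosomes = n_chromosomes, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# Deterministic fixed-seed layout of the gene panel: ids, chromosome
# assignment, marker and cycling set allocation, per-gene log-means.
# Shared by the tumor generator and the normal reference so both live on
# the same panel.
simulate_gene_panel <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  per_chr <- ceiling(n / config$n_chromosomes)
  chrom <- paste0("chr", rep(seq_len(config$n_chromosomes), each = per_chr))[seq_len(n)]
  start_full <- numeric(n)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    start_full[ix] <- sort(sample.int(2e8, length(ix)))
  }
  genes <- gene_records(ids, chrom, start_full)
  types <- names(config$cell_type_fractions)
  need <- length(types) * config$n_marker_genes + 2 * config$n_cycling_genes
  if (need > n) stop("n_genes too small for the marker and cycling sets")
  special <- sample(ids, need)
  marker_sets <- list()
  k <- 0
  for (ty in types) {
    marker_sets[[ty]] <- special[(k + 1):(k + config$n_marker_genes)]
    k <- k + config$n_marker_genes
  }
  g1s <- special[(k + 1):(k + config$n_cycling_genes)]
  g2m <- special[(k + config$n_cycling_genes + 1):(k + 2 * config$n_cycling_genes)]
  logmean <- stats::rnorm(n, config$base_logmean, config$gene_logmean_sd)
  names(logmean) <- ids
  list(genes = genes, marker_sets = marker_sets, g1s = g1s, g2m = g2m,
       logmean = logmean)
}

# Per-gene dropout probabilities for a panel (see simulation_config).
dropout_probability <- function(logmean, config) {
  if (config$dropout_model == "uniform")
    return(rep(config$dropout_rate, length(logmean)))
  t <- exp(logmean + config$base_logsd^2 / 2)
  tpm <- t / sum(t) * 1e6
  config$dropout_rate / (1 + (tpm / config$dropout_knee_tpm)^config$dropout_hill)
}

# Largest-remainder integer apportionment of n cells to fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic multi-patient tumor dataset with ground truth
#'
#' Draws raw expression as `exp(Normal(log-mean + effects, log-sd))` per
#' gene and cell, multiplies gene dosage on CNV blocks for carrier cells,
#' elevates marker genes in cells of the matching type and cell-cycle
#' genes in cycling cells, adds a per-patient batch offset on the log
#' scale, zeroes entries by Bernoulli dropout, and finally rescales each
#' cell to TPM (rows sum to 1e6). Because dosage acts before the TPM
#' rescale, a gain block slightly depresses all other genes — the
#' compositional artifact real expression-based CNV inference must
#' tolerate.
#'
#' @param config a [simulation_config()].
#' @return list with `expr` (`ExpressionMatrix`, unit `raw_tpm`), `cells`
#'   (per-cell metadata table), `genes` (gene records), and `truth`
#'   (true cell types, cycling flags, CNV carrier/block labels, gene set
#'   memberships, and the generating parameters).
#' @export
generate_tumor_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  panel <- simulate_gene_panel(config)
  set.seed(config$seed + 1L)
  n_genes <- config$n_genes
  gene_id_by_order <- panel$genes$gene_id   # ordered by order_index

  patients <- sprintf("P%02d", seq_len(config$n_patients))
  cell_patient <- rep(patients, config$cells_per_patient)
  n_cells <- length(cell_patient)
  cell_ids <- sprintf("%s_c%03d", cell_patient,
                      unlist(lapply(config$cells_per_patient, seq_len)))
  types <- names(config$cell_type_fractions)
  cell_type <- character(n_cells)
  for (p in patients) {
    ix <- which(cell_patient == p)
    counts <- apportion(length(ix), config$cell_type_fractions)
    cell_type[ix] <- sample(rep(types, counts))
  }
  is_epi <- cell_type == "epithelial"
  cycling <- ifelse(is_epi,
                    stats::runif(n_cells) < config$cycling_fraction,
                    stats::runif(n_cells) < config$cycling_fraction_other)

  carrier_block <- rep(NA_integer_, n_cells)
  for (b in seq_along(config$cnv_specs)) {
    sp <- config$cnv_specs[[b]]
    cand <- which(cell_patient == patients[sp$patient] & is_epi &
                    is.na(carrier_block))
    n_car <- round(sp$carrier_fraction * sum(cell_patient == patients[sp$patient] & is_epi))
    n_car <- min(n_car, length(cand))
    if (n_car > 0) carrier_block[sample(cand, n_car)] <- b
  }

  batch <- matrix(stats::rnorm(config$n_patients * n_genes, 0,
                               config$patient_batch_sd),
                  nrow = config$n_patients,
                  dimnames = list(patients, names(panel$logmean)))

  # per-cell log-mean = gene baseline + marker/cycling elevations + batch
  mu <- matrix(rep(panel$logmean, each = n_cells), nrow = n_cells,
               dimnames = list(cell_ids, names(panel$logmean)))
  l2 <- log(2)
  for (ty in types) {
    mk <- panel$marker_sets[[ty]]
    mu[cell_type == ty, mk] <- mu[cell_type == ty, mk] + l2 * config$marker_effect
  }
  cyc_genes <- c(panel$g1s, panel$g2m)
  mu[cycling, cyc_genes] <- mu[cycling, cyc_genes] + l2 * config$cycling_effect
  off <- !is_epi & !cycling
  mu[off, cyc_genes] <- mu[off, cyc_genes] - l2 * config$cycling_offstate
  mu <- mu + batch[cell_patient, , drop = FALSE]

  values <- exp(mu + matrix(stats::rnorm(n_cells * n_genes, 0, config$base_logsd),
                            nrow = n_cells))
  for (b in seq_along(config$cnv_specs)) {
    sp <- config$cnv_specs[[b]]
    blk <- gene_id_by_order[sp$block[1]:sp$block[2]]
    car <- which(carrier_block == b)
    if (length(car) > 0)
      values[car, blk] <- values[car, blk] * sp$dosage
  }
  if (config$dropout_rate > 0) {
    p_drop <- dropout_probability(panel$logmean, config)
    drop <- matrix(stats::runif(n_cells * n_genes), nrow = n_cells) <
      matrix(rep(p_drop, each = n_cells), nrow = n_cells)
    values[drop] <- 0
  }
  rs <- rowSums(values)
  if (any(rs == 0)) stop("simulated cell with all-zero expression; lower dropout_rate")
  values <- values / rs * 1e6

  expr <- expression_matrix(values, "raw_tpm")
  cells <- data.frame(cell_id = cell_ids, patient_id = cell_patient,
                      sort_protocol = "cd45_depleted",
                      library_size = NA_real_, n_genes_expressed = NA_integer_,
                      total_mrna = NA_real_, size_factor = NA_real_,
                      cell_type = "unassigned", cycling = "unknown",
                      epithelial_cluster = NA_integer_,
                      stringsAsFactors = FALSE)
  truth <- list(
    cells = data.frame(cell_id = cell_ids, patient_id = cell_patient,
                       cell_type = cell_type, cycling = cycling,
                       cnv_carrier = !is.na(carrier_block),
                       cnv_block = carrier_block, stringsAsFactors = FALSE),
    marker_sets = panel$marker_sets, g1s_genes = panel$g1s,
    g2m_genes = panel$g2m,
    cnv_blocks = lapply(config$cnv_specs, function(sp)
      gene_id_by_order[sp$block[1]:sp$block[2]]),
    gene_logmean = panel$logmean, config = config)
  list(expr = expr, cells = cells, genes = panel$genes, truth = truth)
}

#' Generate a normal epithelial reference matrix
#'
#' Cells drawn from the baseline epithelial profile of the same gene
#' panel: epithelial markers elevated, no CNV, no cycling elevation and
#' no patient batch effect (the reference emulates normal cells from an
#' external study), but subject to the same technical dropout as the
#' tumor cells so that burden comparisons against it are calibrated.
#' Default size is 240 cells.
#'
#' @param n_cells number of reference cells (>= 2).
#' @param config the [simulation_config()] whose gene panel is shared.
#' @return an `ExpressionMatrix` (unit `raw_tpm`) of `n_cells` rows.
#' @export
generate_normal_reference <- function(n_cells = 240, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (n_cells < 2) stop("n_cells must be >= 2")
  panel <- simulate_gene_panel(config)
  set.seed(config$seed + 2L)
  n_genes <- config$n_genes
  mu <- matrix(rep(panel$logmean, each = n_cells), nrow = n_cells)
  mk <- match(panel$marker_sets$epithelial, names(panel$logmean))
  mu[, mk] <- mu[, mk] + log(2) * config$marker_effect
  values <- exp(mu + matrix(stats::rnorm(n_cells * n_genes, 0, config$base_logsd),
                            nrow = n_cells))
  if (config$dropout_rate > 0) {
    p_drop <- dropout_probability(panel$logmean, config)
    drop <- matrix(stats::runif(n_cells * n_genes), nrow = n_cells) <
      matrix(rep(p_drop, each = n_cells), nrow = n_cells)
    values[drop] <- 0
  }
  rs <- rowSums(values)
  if (any(rs == 0)) stop("simulated cell with all-zero expression; lower dropout_rate")
  values <- values / rs * 1e6
  dimnames(values) <- list(sprintf("normal_c%03d", seq_len(n_cells)),
                           names(panel$logmean))
  expression_matrix(values, "raw_tpm")
}

#' Generate a synthetic bulk survival cohort driven by a gene signature
#'
#' Each sample gets a latent standard-normal signature activity `s` that
#' is propagated into expression (up genes shifted by `+s`, down genes by
#' `-s` on the log scale) and into outcome: event times are exponential
#' with hazard proportional to `exp(beta * s)`, with independent
#' exponential censoring tuned to the requested marginal censoring rate.
#'
#' @param n_samples cohort size (>= 8 so that quartiles are defined).
#' @param signature a [gene_signature()].
#' @param beta true log-hazard coefficient per unit of `s`.
#' @param censor_rate target fraction censored, in \[0, 1).
#' @param seed integer seed.
#' @param n_noise_genes non-signature background genes on the panel.
#' @param baseline_hazard event hazard at `s = 0` (per month; default
#'   gives a 60-month median).
#' @param effect_size log-scale expression shift per unit of `s`.
#' @return list with `cohort` (data.frame: `sample_id`, `time`, `event`,
#'   then one column per gene) and `truth` (`s`, `beta`).
#' @export
generate_survival_cohort <- function(n_samples, signature, beta,
                                     censor_rate = 0.3, seed = 1,
                                     n_noise_genes = 100,
                                     baseline_hazard = log(2) / 60,
                                     effect_size = 1) {
  if (n_samples < 8) stop("n_samples must be >= 8 (quartiles undefined below)")
  if (!is.finite(beta)) stop("beta must be finite")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  stopifnot(inherits(signature, "GeneSignature"))
  set.seed(as.integer(seed))
  sig_genes <- c(signature$up_genes, signature$down_genes)
  genes <- c(sig_genes, sprintf("noise%04d", seq_len(n_noise_genes)))
  s <- stats::rnorm(n_samples)
  expr <- matrix(stats::rnorm(n_samples * length(genes), 0, 1),
                 nrow = n_samples,
                 dimnames = list(sprintf("s%04d", seq_len(n_samples)), genes))
  expr[, signature$up_genes] <- expr[, signature$up_genes] + effect_size * s
  if (length(signature$down_genes) > 0)
    expr[, signature$down_genes] <- expr[, signature$down_genes] - effect_size * s
  t_event <- stats::rexp(n_samples, rate = baseline_hazard * exp(beta * s))
  if (censor_rate > 0) {
    t_cens <- stats::rexp(n_samples,
                          rate = baseline_hazard * censor_rate / (1 - censor_rate))
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n_samples)
    time <- t_event
  }
  cohort <- data.frame(sample_id = rownames(expr), time = time, event = event,
                       expr, check.names = FALSE, stringsAsFactors = FALSE)
  list(cohort = cohort, truth = list(s = s, beta = beta))
}
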