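#' Default pipeline parameters
#'
#' All analysis defaults in one place: 4-MAD cell filter, 2-MAD cycling
#' threshold, 95% prevalence gene filter at log2(TPM+1) < 0.1, CNV window
#' 100 with clipping at 3 and mean-expression filter 0.1, one RUV factor,
#' 1.1 typing margin and 70% cluster-majority override, top-100 cluster
#' signature at FDR 0.05.
#'
#' @return named list of parameters.
#' @export
default_params <- function() {
  list(mad_k = 4, cycling_k = 2, prevalence = 0.95, expr_threshold = 0.1,
       window = 100, clip = 3, min_mean = 0.1, ruv_k = 1,
       margin = 1.1, majority = 0.7, n_top = 100, fdr = 0.05,
       carrier_quantile = 0.95, embed_dims = 2, n_pcs = 50,
       size_factor_method = "median_ratio", census_mode = "mode_anchored")
}

#' Read a pipeline configuration file
#'
#' YAML (if the yaml package is available) or JSON. The configuration is
#' a named list with optional fields `seed`, `stages`, `params`
#' (overriding [default_params()]), `inputs` (file paths) and `simulate`
#' (overrides for [simulation_config()]).
#'
#' @param path config file ending in `.yaml`/`.yml` or `.json`.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

pipeline_stage_order <- c("simulate", "qc", "normalize", "celltype", "cnv",
                          "cluster", "signature", "survive")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Retrieve an upstream artifact from in-memory state or from a file the
# stage wrote in a previous run; otherwise fail naming the missing stage.
pipeline_need <- function(state, key, stage, producer, loader = NULL,
                          file = NULL, out = NULL) {
  if (!is.null(state[[key]])) return(state[[key]])
  if (!is.null(loader) && !is.null(file)) {
    path <- file.path(out, file)
    if (file.exists(path)) return(loader(path))
  }
  stop("stage '", stage, "' requires output of stage '", producer,
       "' (missing: ", key, ")")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate, qc, normalize, celltype, cnv, cluster, signature,
#' survive`), each stage writing TSV tables into `out_dir` that the next
#' stages consume, and finally a JSON run summary recording every
#' parameter and the record counts after every filter. Deterministic
#' given `config$seed` (per-stage seeds are fixed offsets of it).
#'
#' @param config a config list (see [read_config()]) or a path to a
#'   config file.
#' @param out_dir output directory (created if needed).
#' @return the run summary, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  params <- utils::modifyList(default_params(), config$params %||% list())
  stages <- config$stages %||% pipeline_stage_order
  if ("all" %in% stages) stages <- pipeline_stage_order
  unknown <- setdiff(stages, pipeline_stage_order)
  if (length(unknown) > 0) stop("unknown stage: ", unknown[1])
  stages <- pipeline_stage_order[pipeline_stage_order %in% stages]
  inputs <- config$inputs %||% list()

  state <- new.env(parent = emptyenv())
  summary <- list(seed = seed, params = params, stages = stages,
                  counts = list())
  note <- function(stage, what, n) {
    summary$counts[[stage]][[what]] <<- n
  }

  load_inputs <- function(stage) {
    if (is.null(state$expr) && !is.null(inputs$expression))
      state$expr <- read_expression(inputs$expression,
                                    format = inputs$expression_format %||% "tsv_dense",
                                    unit = "raw_tpm",
                                    orientation = inputs$orientation %||% "cells_x_genes")
    if (is.null(state$cells) && !is.null(inputs$cells))
      state$cells <- utils::read.delim(inputs$cells, stringsAsFactors = FALSE)
    if (is.null(state$genes) && !is.null(inputs$genes))
      state$genes <- read_gene_positions(inputs$genes)
    if (is.null(state$markers) && !is.null(inputs$markers_gmt))
      state$markers <- read_gmt(inputs$markers_gmt)
    if (is.null(state$normal_ref) && !is.null(inputs$normal_reference))
      state$normal_ref <- read_expression(inputs$normal_reference,
                                          unit = "raw_tpm")
    if (is.null(state$segments) && !is.null(inputs$segments))
      state$segments <- read_segments(inputs$segments)
    if (is.null(state$cohort) && !is.null(inputs$cohort))
      state$cohort <- utils::read.delim(inputs$cohort, check.names = FALSE,
                                        stringsAsFactors = FALSE)
    if (is.null(state$survival_signature) && !is.null(inputs$signature_gmt))
      state$survival_signature <- read_gmt(inputs$signature_gmt)[[1]]
  }

  for (stage in stages) {
    load_inputs(stage)
    switch(stage,
      simulate = {
        sim_over <- config$simulate %||% list()
        sim_over$seed <- sim_over$seed %||% (seed + 10L)
        cfg <- do.call(simulation_config, sim_over)
        ds <- generate_tumor_dataset(cfg)
        state$expr <- ds$expr
        state$cells <- ds$cells
        state$cells$patient_id <- ds$truth$cells$patient_id
        state$genes <- ds$genes
        state$truth <- ds$truth
        state$markers <- c(
          lapply(names(ds$truth$marker_sets), function(ty)
            gene_signature(ty, ds$truth$marker_sets[[ty]])),
          list(gene_signature("G1S", ds$truth$g1s_genes),
               gene_signature("G2M", ds$truth$g2m_genes)))
        names(state$markers) <- c(names(ds$truth$marker_sets), "G1S", "G2M")
        state$normal_ref <- generate_normal_reference(240, cfg)
        sig_genes <- sprintf("sg%03d", 1:70)
        state$survival_signature <- gene_signature("SYN_PROGNOSTIC", sig_genes)
        sc <- generate_survival_cohort(300, state$survival_signature, beta = 1,
                                       censor_rate = 0.3, seed = seed + 20L)
        state$cohort <- sc$cohort
        write_expression(state$expr, file.path(out_dir, "expression.tsv"))
        write_tsv(state$cells, file.path(out_dir, "cells.tsv"))
        write_tsv(state$genes, file.path(out_dir, "genes.tsv"))
        write_expression(state$normal_ref,
                         file.path(out_dir, "normal_reference.tsv"))
        write_gmt(state$markers, file.path(out_dir, "markers.gmt"))
        write_tsv(ds$truth$cells, file.path(out_dir, "truth_cells.tsv"))
        write_gmt(list(state$survival_signature),
                  file.path(out_dir, "survival_signature.gmt"))
        write_tsv(state$cohort, file.path(out_dir, "survival_cohort.tsv"))
        note("simulate", "cells", nrow(state$cells))
        note("simulate", "genes", nrow(state$genes))
      },
      qc = {
        expr <- pipeline_need(state, "expr", "qc", "simulate",
                              loader = function(p) read_expression(p, unit = "raw_tpm"),
                              file = "expression.tsv", out = out_dir)
        cells <- pipeline_need(state, "cells", "qc", "simulate",
                               loader = function(p) utils::read.delim(p, stringsAsFactors = FALSE),
                               file = "cells.tsv", out = out_dir)
        metrics <- compute_cell_qc_metrics(expr,
                                           expr_threshold = params$expr_threshold)
        filt <- filter_cells_by_mad(metrics, k = params$mad_k)
        expr <- em_subset(expr, cells = filt$kept)
        cells <- cells[cells$cell_id %in% filt$kept, , drop = FALSE]
        gf <- filter_genes_by_prevalence(expr, cells$patient_id,
                                         threshold = params$expr_threshold,
                                         prevalence = params$prevalence)
        expr <- em_subset(expr, genes = gf$kept)
        state$expr <- expr
        state$cells <- merge(cells[, setdiff(colnames(cells),
                                             colnames(metrics)[-1])],
                             metrics, by = "cell_id", sort = FALSE)
        write_tsv(metrics, file.path(out_dir, "qc_metrics.tsv"))
        writeLines(filt$kept, file.path(out_dir, "kept_cells.txt"))
        writeLines(gf$kept, file.path(out_dir, "kept_genes.txt"))
        write_expression(expr, file.path(out_dir, "expression_qc.tsv"))
        note("qc", "cells_removed", length(filt$removed))
        note("qc", "cells_kept", nrow(expr$values))
        note("qc", "genes_removed", length(gf$removed))
        note("qc", "genes_kept", ncol(expr$values))
      },
      normalize = {
        expr <- pipeline_need(state, "expr", "normalize", "qc",
                              loader = function(p) read_expression(p, unit = "raw_tpm"),
                              file = "expression_qc.tsv", out = out_dir)
        counts <- estimate_relative_counts(expr, mode = params$census_mode)
        sf <- compute_size_factors(counts, method = params$size_factor_method)
        norm <- normalize_by_size_factors(counts, sf)
        n_zero <- length(attr(norm, "log")$removed_zero_factor)
        norm <- remove_unwanted_variation(norm, k = params$ruv_k)
        state$norm <- norm
        write_tsv(data.frame(cell_id = names(sf), size_factor = as.numeric(sf)),
                  file.path(out_dir, "size_factors.tsv"))
        write_expression(norm, file.path(out_dir, "normalized.tsv"))
        note("normalize", "cells_zero_factor", n_zero)
        note("normalize", "cells_kept", nrow(norm$values))
      },
      celltype = {
        norm <- pipeline_need(state, "norm", "celltype", "normalize",
                              loader = function(p) read_expression(p, unit = "normalized_log"),
                              file = "normalized.tsv", out = out_dir)
        markers <- pipeline_need(state, "markers", "celltype", "simulate",
                                 loader = read_gmt,
                                 file = "markers.gmt", out = out_dir)
        cyc_names <- intersect(c("G1S", "G2M"), names(markers))
        type_sets <- lapply(markers[setdiff(names(markers), cyc_names)],
                            `[[`, "up_genes")
        cl <- refinement_clusters(norm, type_sets, seed = seed + 30L)
        ct <- assign_cell_types(norm, type_sets, cl,
                                margin = params$margin,
                                majority = params$majority)
        out_tab <- data.frame(cell_id = rownames(norm$values),
                              cell_type = ct$cell_type,
                              stringsAsFactors = FALSE)
        if (length(cyc_names) == 2) {
          cyc <- classify_cycling(norm, markers$G1S$up_genes,
                                  markers$G2M$up_genes, k = params$cycling_k)
          out_tab$cycling <- cyc$cycling
        } else {
          out_tab$cycling <- "unknown"
        }
        state$cell_types <- out_tab
        write_tsv(out_tab, file.path(out_dir, "cell_types.tsv"))
        note("celltype", "assigned", sum(out_tab$cell_type != "unassigned"))
        note("celltype", "epithelial", sum(out_tab$cell_type == "epithelial"))
        note("celltype", "cycling_high", sum(out_tab$cycling == "high"))
      },
      cnv = {
        expr <- pipeline_need(state, "expr", "cnv", "simulate",
                              loader = function(p) read_expression(p, unit = "raw_tpm"),
                              file = "expression.tsv", out = out_dir)
        genes <- pipeline_need(state, "genes", "cnv", "simulate",
                               loader = read_gene_positions,
                               file = "genes.tsv", out = out_dir)
        normal_ref <- pipeline_need(state, "normal_ref", "cnv", "simulate",
                                    loader = function(p) read_expression(p, unit = "raw_tpm"),
                                    file = "normal_reference.tsv", out = out_dir)
        # the inference targets malignant (epithelial) cells; restrict to
        # them when the typing stage has run
        if (!is.null(state$cell_types)) {
          epi <- state$cell_types$cell_id[state$cell_types$cell_type ==
                                            "epithelial"]
          epi <- intersect(rownames(expr$values), epi)
          if (length(epi) >= 2) expr <- em_subset(expr, cells = epi)
        }
        n_ref <- nrow(normal_ref$values)
        half <- seq_len(floor(n_ref / 2))
        res <- infer_cnv_with_reference(
          expr, em_subset(normal_ref, cells = half),
          em_subset(normal_ref, cells = setdiff(seq_len(n_ref), half)),
          genes, window = params$window, clip = params$clip,
          min_mean = params$min_mean)
        cnv <- res$tumor
        # subclones are patient-level structures: profiles are displayed
        # and called per patient against the common normal reference
        patients <- state$cells$patient_id[match(colnames(cnv$values),
                                                 state$cells$cell_id)]
        calls <- do.call(rbind, lapply(unique(patients), function(p) {
          sub <- structure(list(values = cnv$values[, patients == p,
                                                    drop = FALSE],
                                genes = cnv$genes, window = cnv$window,
                                clip = cnv$clip), class = "CNVMatrix")
          cbind(patient_id = p,
                call_cnv_subclones(sub, res$reference,
                                   q = params$carrier_quantile))
        }))
        state$cnv <- cnv
        state$subclones <- calls
        cnv_tab <- data.frame(gene_id = rownames(cnv$values), cnv$values,
                              check.names = FALSE)
        write_tsv(cnv_tab, file.path(out_dir, "cnv_matrix.tsv"))
        write_tsv(calls, file.path(out_dir, "subclones.tsv"))
        cells <- state$cells
        if (!is.null(cells)) {
          cmap <- correlation_map(cnv,
                                  cells$patient_id[match(colnames(cnv$values),
                                                         cells$cell_id)])
          write_tsv(data.frame(group = names(cmap$group_means),
                               mean_within_correlation = as.numeric(cmap$group_means)),
                    file.path(out_dir, "correlation_group_means.tsv"))
        }
        note("cnv", "genes_profiled", nrow(cnv$values))
        note("cnv", "carriers", sum(calls$carrier))
      },
      cluster = {
        norm <- pipeline_need(state, "norm", "cluster", "normalize",
                              loader = function(p) read_expression(p, unit = "normalized_log"),
                              file = "normalized.tsv", out = out_dir)
        ct <- pipeline_need(state, "cell_types", "cluster", "celltype",
                            loader = function(p) utils::read.delim(p, stringsAsFactors = FALSE),
                            file = "cell_types.tsv", out = out_dir)
        cells <- pipeline_need(state, "cells", "cluster", "qc",
                               loader = function(p) utils::read.delim(p, stringsAsFactors = FALSE),
                               file = "cells.tsv", out = out_dir)
        epi <- ct$cell_id[ct$cell_type == "epithelial"]
        if (length(epi) < 10)
          stop("stage 'cluster' found fewer than 10 epithelial cells")
        sub <- em_subset(norm, cells = intersect(rownames(norm$values), epi))
        pat <- cells$patient_id[match(rownames(sub$values), cells$cell_id)]
        resid <- regress_out_patient(sub, pat)
        emb <- embed_cells(resid, dims = params$embed_dims, seed = seed + 40L,
                           n_pcs = params$n_pcs)
        cl <- density_peak_cluster(emb)
        lab <- data.frame(cell_id = rownames(emb), cluster = cl$labels,
                          stringsAsFactors = FALSE)
        state$clusters <- lab
        write_tsv(data.frame(cell_id = rownames(emb), emb),
                  file.path(out_dir, "embedding.tsv"))
        write_tsv(lab, file.path(out_dir, "clusters.tsv"))
        note("cluster", "epithelial_cells", nrow(lab))
        note("cluster", "n_clusters", length(unique(cl$labels)))
      },
      signature = {
        norm <- pipeline_need(state, "norm", "signature", "normalize",
                              loader = function(p) read_expression(p, unit = "normalized_log"),
                              file = "normalized.tsv", out = out_dir)
        clusters <- pipeline_need(state, "clusters", "signature", "cluster",
                                  loader = function(p) utils::read.delim(p, stringsAsFactors = FALSE),
                                  file = "clusters.tsv", out = out_dir)
        sub <- em_subset(norm, cells = clusters$cell_id)
        target <- config$target_cluster %||%
          as.integer(names(which.max(table(clusters$cluster))))
        if (length(unique(clusters$cluster)) < 2) {
          message("signature stage: only one epithelial cluster; ",
                  "no cluster signature to derive")
          sig_tab <- data.frame(gene_id = character(0), statistic = numeric(0),
                                p = numeric(0), lfc = numeric(0),
                                padj = numeric(0))
        } else {
          sig_tab <- derive_cluster_signature(sub, clusters$cluster, target,
                                              n_top = params$n_top,
                                              fdr = params$fdr)
        }
        state$cluster_signature <- sig_tab
        write_tsv(sig_tab, file.path(out_dir, "cluster_signature.tsv"))
        enr <- NULL
        if (!is.null(state$segments) && !is.null(state$genes) &&
            nrow(sig_tab) > 0) {
          gain <- genes_in_segments(state$segments, state$genes, "gain")
          enr <- overrepresentation_test(sig_tab$gene_id,
                                         intersect(gain, gene_ids(sub)),
                                         gene_ids(sub))
          jsonlite::write_json(enr, file.path(out_dir, "gain_enrichment.json"),
                               auto_unbox = TRUE, digits = NA)
        }
        note("signature", "target_cluster", target)
        note("signature", "signature_genes", nrow(sig_tab))
      },
      survive = {
        cohort <- pipeline_need(state, "cohort", "survive", "simulate",
                                loader = function(p) utils::read.delim(p, check.names = FALSE,
                                                                       stringsAsFactors = FALSE),
                                file = "survival_cohort.tsv", out = out_dir)
        sig <- pipeline_need(state, "survival_signature", "survive", "simulate",
                             loader = function(p) read_gmt(p)[[1]],
                             file = "survival_signature.gmt", out = out_dir)
        res <- validate_signature_survival(cohort, sig)
        out_json <- list(signature = sig$name,
                         cox = res$cox[c("coef", "hr", "se", "z", "p")],
                         logrank = res$logrank[c("statistic", "df", "p")])
        jsonlite::write_json(out_json, file.path(out_dir, "survival_results.json"),
                             auto_unbox = TRUE, digits = NA)
        km_tab <- do.call(rbind, lapply(names(res$km), function(g)
          cbind(quartile = g, res$km[[g]])))
        write_tsv(km_tab, file.path(out_dir, "km_curves.tsv"))
        note("survive", "samples", nrow(cohort))
        note("survive", "events", sum(cohort$event))
      })
  }
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
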