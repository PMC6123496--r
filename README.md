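# scTNBC

Single-cell transcriptomic heterogeneity analysis for triple-negative
breast cancer (TNBC), re-implemented as a tested, reusable R pipeline.

Triple-negative breast cancers are heterogeneous mixtures of malignant
epithelial cells, immune cells and stroma, and their malignant
compartments split further into subclones and shared expression states.
This package implements the full desk-side analysis chain used to
dissect that heterogeneity from single-cell RNA-seq, for
bioinformaticians who want each step as an auditable, composable
function rather than a monolithic script:

* **QC** — cells removed when any of library size, detected genes or
  total mRNA falls 4 raw MADs below the median on the log scale
  (`filter_cells_by_mad`); genes removed only when silent
  (log2(TPM+1) < 0.1 in ≥ 95% of cells) in *every* patient
  (`filter_genes_by_prevalence`).
* **Normalization** — simplified Census-style relative counts,
  median-ratio or ring-pool deconvolution size factors (zero-factor
  cells dropped), and RUV-style factor correction on control genes.
* **Cell typing** — marker-set scoring with an argmax + margin rule,
  refined by a cluster-majority override; cycling cells called when a
  G1-S or G2-M score exceeds `median + 2·MAD`.
* **Inferred CNV** — expression scaled as log2(TPM+1)/10, centered on a
  normal epithelial reference, clipped at ±3, smoothed by a 100-gene
  moving average along genomic order (truncated at chromosome
  boundaries) and centered per gene: `x̃_gc = (1/|W_g|) Σ_{h∈W_g} x_hc`.
  Carrier cells are called by a leave-one-out matched-filter projection
  calibrated on held-out normal cells, and grouped into subclones by
  average-linkage clustering on Pearson distance.
* **Epithelial clustering** — per-gene patient regression, PCA
  embedding, and density-peak clustering (ρ, δ, γ = ρδ decision graph)
  with automatic cluster count.
* **Signatures** — directional scoring `mean(up) − mean(down)`,
  max-score subtype assignment, Wilcoxon + Benjamini–Hochberg derivation
  of cluster-selective signatures, and exact hypergeometric
  over-representation tests (e.g. against WES gain segments).
* **Survival** — signature scoring of bulk cohorts, quartile
  stratification, Kaplan–Meier curves, K-group log-rank, and a
  from-scratch univariate Cox model (Newton–Raphson, Breslow/Efron
  ties): h(t|s) = h₀(t)·exp(β·s).
* **Synthetic data** — a generator for multi-patient tumors (cell-type
  mixtures, marker programs, cycling cells, clonal gene-dosage blocks,
  patient batch, dropout) and signature-driven survival cohorts, with
  full ground truth for recovery testing.

## Worked example

End-to-end on a synthetic three-patient tumor (360 cells, 1500 genes,
one 150-gene 1.5× gain in half of patient 1's epithelial cells):

```r
library(scTNBC)

cfg <- list(seed = 7, stages = "all",
            simulate = list(n_genes = 1500, n_patients = 3,
                            cells_per_patient = c(80, 120, 160),
                            n_chromosomes = 6,
                            cnv_specs = list(list(patient = 1,
                                                  carrier_fraction = 0.5,
                                                  block = c(101, 250),
                                                  dosage = 1.5))))
summary <- run_pipeline(cfg, "run")
str(summary$counts)
```

```
$ simulate : cells: 360, genes: 1500
$ qc       : cells_removed: 1, cells_kept: 359, genes_removed: 0
$ normalize: cells_zero_factor: 0, cells_kept: 359
$ celltype : assigned: 359, epithelial: 252, cycling_high: 39
$ cnv      : genes_profiled: 1493, carriers: 120
$ cluster  : epithelial_cells: 252, n_clusters: 1
$ signature: target_cluster: 1, signature_genes: 0
$ survive  : samples: 300, events: 183
```

Reading the run: one cell fails the 4-MAD QC rule; typing recovers the
simulated 70% epithelial fraction exactly (252/360); the epithelial
cells form a single shared cluster (nothing beyond the CNV subclone was
implanted, so the empty cluster signature is the right answer); the
carrier list contains all 28 true carriers of the implanted gain
(cross-patient calls also absorb patient-level expression offsets — see
the methods vignette for why carrier guarantees are stated per tumor).
Stage tables (`cells.tsv`, `cnv_matrix.tsv`, `subclones.tsv`,
`clusters.tsv`, `survival_results.json`, …) and a JSON run summary are
written to the output directory; identical configs produce
byte-identical outputs.

Validating a 70-gene prognostic signature on a synthetic bulk cohort
(n = 300, true log-hazard β = 1 per unit signature activity, 30%
censoring):

```r
sig <- gene_signature("PROGNOSTIC", paste0("pg", 1:70))
sc  <- generate_survival_cohort(300, sig, beta = 1, censor_rate = 0.3, seed = 7)
res <- validate_signature_survival(sc$cohort, sig)
```

```
Cox coef: 0.974   HR: 2.65   p: 8.59e-29
log-rank chi2: 114.53   df: 3   p: 1.16e-24
```

The continuous-score Cox model (the primary test; quartiles are for
visualization) recovers the generating coefficient β = 1 to within its
standard error, and the 4-group log-rank over score quartiles confirms
the survival separation.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "scTNBC", package = "scTNBC"))') \
    all --config cfg.yaml --out run
```

## Documentation

`vignettes/sctnbc-methods.Rmd` describes the models and their
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical
conventions and degenerate-input behavior, and known limitations.
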