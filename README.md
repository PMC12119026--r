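# cortexdev

Tools for comparative single-nucleus RNA-seq analysis of developing sensory
cortex, built for the question: which gene-expression programs change
between two postnatal ages, which are cell-type-specific, and does sensory
perturbation alter cell-type identity or composition?

The package implements the full analysis protocol as reusable, tested
functions, and pairs it with a negative-binomial synthetic-data generator
that plants known ground truth (marker programs, temporal programs, a
three-type continuum with a compositional shift, doublet/low-quality/
high-mito artifacts) so that every stage can be verified against a known
answer.

## What it computes

* **QC & purification** — strict cell filters (`n_genes` < 7,000,
  500 < `n_counts` < 40,000), gene detection filters, library-size
  normalisation with log1p, HVG/PCA/kNN/Leiden clustering, removal of
  high-mitochondrial clusters, and mapping-based cluster purification.
* **SV/tDE quadrants** — for each gene, a subclass-variability score
  (max one-vs-rest |log2FC| across subclasses and ages) and a temporal
  score (max per-subclass |log2FC| between ages), both capped at 2;
  genes stratify at a fold-change threshold into Q1 (subclass-specific
  temporal), Q2 (global temporal), Q3 (static non-specific), Q4 (static
  identity). Fisher-exact category enrichment per quadrant with Bonferroni
  adjustment; exclusive set intersections of subclass-wise DE genes;
  hypergeometric overlap of temporally regulated genes between regions.
* **Label transfer** — an XGBoost multiclass classifier trained with the
  per-cluster protocol (70% sampled, capped at 1,000, small clusters
  bootstrapped to 100; eta 0.2, depth 6, subsample 0.6), with the
  rejection rule `assign argmax p_i iff max p_i > 1.2/r`, held-out
  validation, over-clustering diagnostics and frequency-concordance
  comparisons.
* **Continuum PCA** — one-vs-rest type markers (FC > 1.5, FDR < 0.05,
  expressed in > 20% of the type) pooled into a fixed feature panel, PCA
  per condition, eigenvector correspondence across conditions via
  absolute loading dot products, per-cell marker scores, and
  Kolmogorov–Smirnov comparisons of score distributions along PC1.

## Worked example

```r
library(cortexdev)

# simulate a miniature experiment with planted ground truth
design <- sim_design(cells_per_type = 20, n_genes = 1000, seed = 1)
sim <- simulate_counts(design)

# QC: per-cell stats, strict filters, normalisation
meta <- cell_qc_stats(sim$counts, sim$meta)
f <- filter_cells(sim$counts, meta)           # n_genes/n_counts bounds
counts <- filter_genes(f$counts, min_cells = 20)
x <- normalize_log(counts)                    # per-cell 10,000 + log1p

# quadrant scoring on the two control ages
ctrl <- f$meta$condition %in% c("T1", "T2")
truth <- sim$truth$cells[match(f$meta$barcode, sim$truth$cells$barcode), ]
keep <- ctrl & !is.na(truth$subclass)
sq <- score_quadrants(x[keep, ], truth$subclass[keep], f$meta$timepoint[keep])
table(sq$quadrants$quadrant)
```

On this fixture the quadrant table prints

```
 Q1  Q2  Q3  Q4
 98  58 394 353
```

i.e. 98 genes are called subclass-specific-temporal (Q1), 58 global-temporal
(Q2), 353 static identity markers (Q4) and the rest static/non-specific.
This design plants 96 Q1, 52 Q2 and 474 Q4 genes (subclass plus type
markers) with effects of 1.5–3 log2 units: the temporal quadrants are
recovered almost exactly even at this miniature scale, while a minority of
the weaker identity markers fall below the fold-change threshold at 20
cells per type (the protocol-scale recovery bounds are asserted in the test
suite).

Label transfer with the per-cluster training protocol:

```r
labs <- truth$subclass[keep]
sp <- split_train_validation(labs, frac = 0.7, cap = 1000, min_train = 100, seed = 1)
model <- train_mapper(x[keep, ], labs, rows = sp$train, seed = 1)
pred <- predict_labels(model, x[keep, ][sp$heldout, ], reject_factor = 1.2)
mean(pred$assigned == labs[sp$heldout])       # held-out accuracy: 0.977
```

An end-to-end run (simulate → QC → quadrants → transfer → continuum PCA →
overlap) with a manifest and JSON report:

```r
mf <- run_pipeline(list(output_dir = "demo_run", seed = 1))
rep <- pipeline_report("demo_run")
```

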