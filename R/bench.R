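# Reference benchmark for the label-transfer protocol: a well-separated
# multi-subclass negative-binomial reference on which the train/validate
# procedure should reach its nominal validation performance (>95% accuracy).

#' Design of the classifier validation benchmark
#'
#' A flat reference taxonomy: `n_subclasses` subclasses of one type each,
#' observed in a single condition, with `n_markers` markers per subclass at
#' a fixed log2 effect, negative-binomial dispersion `dispersion`, and no
#' artifact cells.
#'
#' @param n_subclasses Number of subclasses.
#' @param cells_per_subclass Cells per subclass.
#' @param n_genes Total genes.
#' @param n_markers Markers per subclass.
#' @param effect Marker log2 fold change.
#' @param dispersion Negative-binomial dispersion.
#' @param seed Integer seed.
#' @return A [sim_design()].
#' @export
design_classifier_bench <- function(n_subclasses = 12, cells_per_subclass = 1000,
                                    n_genes = 2000, n_markers = 50,
                                    effect = 2, dispersion = 0.5, seed = 1L) {
  subclasses <- sprintf("SC%02d", seq_len(n_subclasses))
  programs <- do.call(rbind, lapply(seq_len(n_subclasses), function(i)
    data.frame(gene = (i - 1L) * n_markers + seq_len(n_markers),
               program = "subclass_marker", subclass = subclasses[i],
               type = NA, timepoint = NA, condition = NA,
               log2fc = effect, quadrant = "Q4", stringsAsFactors = FALSE)))
  sim_design(subclasses = subclasses,
             class_of_subclass = rep("glutamatergic", n_subclasses),
             types_per_subclass = rep(1L, n_subclasses),
             conditions = "T2", timepoint_of_condition = "T2",
             cells_per_type = cells_per_subclass, n_genes = n_genes,
             programs = programs, dispersion = dispersion,
             continuum_subclass = NA,
             doublet_rate = 0, lowq_rate = 0, highmito_rate = 0, seed = seed)
}

#' Held-out validation accuracy of the label-transfer protocol
#'
#' Runs the full protocol on a benchmark reference: simulate, normalise
#' (target 10,000, log1p), select highly variable genes, split per cluster
#' (70% capped at 1,000, bootstrap small clusters to 100), train the
#' gradient-boosted classifier, and score the held-out cells under the
#' probability-rejection rule.
#'
#' @param design A [sim_design()], e.g. [design_classifier_bench()].
#' @param n_hvg Feature genes to select.
#' @param seed Integer seed for the split and training.
#' @param ... Passed to [train_mapper()].
#' @return List: `accuracy` (fraction of held-out cells assigned their true
#'   label), `n_heldout`, `unassigned` (fraction rejected), `plan`.
#' @export
classifier_validation_accuracy <- function(design, n_hvg = 2000, seed = 1L, ...) {
  sim <- simulate_counts(design)
  x <- normalize_log(sim$counts)
  hvg <- select_hvgs(x, n_hvg)
  labels <- sim$truth$cells$subclass
  sp <- split_train_validation(labels, seed = seed)
  model <- train_mapper(x, labels, features = hvg, rows = sp$train,
                        seed = seed, ...)
  pred <- predict_labels(model, x[sp$heldout, , drop = FALSE])
  list(accuracy = mean(pred$assigned == labels[sp$heldout]),
       n_heldout = length(sp$heldout),
       unassigned = mean(pred$assigned == "Unassigned"),
       plan = sp$plan)
}
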