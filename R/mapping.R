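# Classifier-based label transfer between datasets: per-cluster sampling with
# bootstrap upsampling, gradient-boosted multiclass training, and a
# probability-rejection assignment rule.

#' Per-cluster train/validation split with bootstrap upsampling
#'
#' For each cluster, samples `floor(frac * n)` unique cells capped at `cap`;
#' clusters whose training draw falls below `min_train` are bootstrapped
#' (with replacement) to `min_train` cells. All unsampled cells form the
#' held-out set.
#'
#' @param labels Cluster/type label per cell.
#' @param frac Training fraction per cluster.
#' @param cap Maximum unique training cells per cluster.
#' @param min_train Bootstrap target for small clusters.
#' @param seed Integer seed; the split is reproducible from `(labels, seed)`.
#' @return List: `train` (indices, possibly with duplicates), `heldout`
#'   (indices), `plan` (per-cluster data.frame: n, n_unique, n_train,
#'   upsampled).
#' @export
split_train_validation <- function(labels, frac = 0.7, cap = 1000,
                                   min_train = 100, seed = 1L) {
  stopifnot(frac > 0, frac < 1, cap >= min_train)
  with_seed(seed, {
    train <- integer(); heldout <- integer()
    plan <- list()
    for (cl in sort(unique(as.character(labels)))) {
      idx <- which(labels == cl)
      n <- length(idx)
      n_unique <- max(1L, min(floor(frac * n), cap))
      pick <- idx[sample.int(n, n_unique)]
      up <- n_unique < min_train
      tr <- if (up) pick[sample.int(n_unique, min_train, replace = TRUE)] else pick
      if (n == 1L) warnf("cluster '%s' has a single cell; held-out set empty", cl)
      train <- c(train, tr)
      heldout <- c(heldout, setdiff(idx, pick))
      plan[[cl]] <- data.frame(cluster = cl, n = n, n_unique = n_unique,
                               n_train = length(tr), upsampled = up,
                               stringsAsFactors = FALSE)
    }
    list(train = train, heldout = heldout,
         plan = do.call(rbind, c(plan, list(make.row.names = FALSE))))
  })
}

#' Train a gradient-boosted multiclass label-transfer model
#'
#' Trains an XGBoost ensemble (softmax-probability objective, multiclass
#' log-loss evaluation; learning rate 0.2, maximum depth 6, row subsampling
#' 0.6 by default) on the given cells and features. A 10% tune split of the
#' training rows drives early stopping. Deterministic for a fixed seed and
#' single thread.
#'
#' @param x Normalised log expression (cells x genes) of the reference.
#' @param labels Label per cell (>= 2 distinct values).
#' @param features Ordered feature genes (e.g., the intersection of
#'   reference and test HVGs, in reference order).
#' @param rows Training row indices (duplicates allowed), e.g.,
#'   `split_train_validation()$train`. Default: all cells.
#' @param eta,max_depth,subsample Boosting hyperparameters.
#' @param nrounds Maximum boosting rounds.
#' @param early_stopping_rounds Patience for early stopping on the tune
#'   split log-loss.
#' @param nthread Threads (1 keeps training deterministic).
#' @param seed Integer seed.
#' @return `mapping_model` object: the booster, `feature_genes`,
#'   `label_vocabulary`, and a training `manifest`.
#' @export
train_mapper <- function(x, labels, features = colnames(x), rows = NULL,
                         eta = 0.2, max_depth = 6, subsample = 0.6,
                         nrounds = 40, early_stopping_rounds = 10,
                         nthread = 1, seed = 1L) {
  x <- as_sparse(x)
  stopifnot(length(labels) == nrow(x))
  if (!all(features %in% colnames(x))) stopf("features missing from matrix")
  vocab <- sort(unique(as.character(labels)))
  if (length(vocab) < 2) stopf("need at least 2 labels")
  if (is.null(rows)) rows <- seq_len(nrow(x))
  y <- match(as.character(labels)[rows], vocab) - 1L
  if (length(unique(y)) < length(vocab))
    stopf("a label is absent from the training rows")
  xt <- x[rows, features, drop = FALSE]

  with_seed(seed, {
    n <- nrow(xt)
    tune <- sample.int(n, max(1L, floor(0.1 * n)))
    tr <- setdiff(seq_len(n), tune)
    dtrain <- xgboost::xgb.DMatrix(xt[tr, , drop = FALSE], label = y[tr])
    dtune <- xgboost::xgb.DMatrix(xt[tune, , drop = FALSE], label = y[tune])
    params <- list(objective = "multi:softprob", eval_metric = "mlogloss",
                   num_class = length(vocab), eta = eta,
                   max_depth = max_depth, subsample = subsample,
                   nthread = nthread, tree_method = "hist",
                   seed = as.integer(seed))
    booster <- xgboost::xgb.train(
      params = params, data = dtrain, nrounds = nrounds,
      evals = list(tune = dtune),
      early_stopping_rounds = early_stopping_rounds, verbose = 0)
    structure(list(
      booster = booster,
      feature_genes = features,
      label_vocabulary = vocab,
      manifest = list(n_train = n, n_tune = length(tune), seed = seed,
                      eta = eta, max_depth = max_depth, subsample = subsample,
                      nrounds = nrounds,
                      best_iteration = tryCatch(xgboost::xgb.attr(booster, "best_iteration"),
                                                error = function(e) NULL))
    ), class = "mapping_model")
  })
}

#' Predict labels with a probability-rejection rule
#'
#' Applies a trained [train_mapper()] model to a test matrix. A cell is
#' assigned `arg max p_i` only when `max p_i > reject_factor / r` (strict;
#' `r` = number of reference labels); otherwise it is `Unassigned`. Feature
#' genes missing from the test matrix are zero-filled with a warning.
#'
#' @param model A `mapping_model`.
#' @param x Test normalised log expression (cells x genes).
#' @param reject_factor Multiplier on the uniform probability `1/r`.
#' @return `mapping_result` object: `prob` (cells x r matrix), `assigned`,
#'   `max_prob`, `threshold`.
#' @export
predict_labels <- function(model, x, reject_factor = 1.2) {
  stopifnot(inherits(model, "mapping_model"))
  x <- as_sparse(x)
  r <- length(model$label_vocabulary)
  if (r < 2) stopf("rejection rule requires at least 2 reference labels")
  miss <- setdiff(model$feature_genes, colnames(x))
  if (length(miss)) {
    warnf("%d feature genes absent from test matrix; zero-filled", length(miss))
    pad <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                        dims = c(nrow(x), length(miss)),
                        dimnames = list(rownames(x), miss))
    x <- cbind(x, pad)
  }
  xt <- x[, model$feature_genes, drop = FALSE]
  prob <- predict(model$booster, xgboost::xgb.DMatrix(xt))
  if (!is.matrix(prob))
    prob <- matrix(prob, nrow = nrow(xt), ncol = r, byrow = TRUE)
  dimnames(prob) <- list(rownames(xt), model$label_vocabulary)
  max_prob <- apply(prob, 1L, max)
  thr <- reject_factor / r
  assigned <- ifelse(max_prob > thr,
                     model$label_vocabulary[max.col(prob, ties.method = "first")],
                     "Unassigned")
  structure(list(prob = prob, assigned = unname(assigned),
                 max_prob = unname(max_prob), threshold = thr,
                 reject_factor = reject_factor),
            class = "mapping_result")
}

#' Serialise a mapping model for audit
#'
#' Writes the boosted-ensemble dump as JSON alongside the ordered feature
#' list and label vocabulary as TSV. The dump is a human-auditable record
#' of the trees, not a reload format.
#'
#' @param model A `mapping_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_mapper <- function(model, dir) {
  stopifnot(inherits(model, "mapping_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- xgboost::xgb.dump(model$booster, dump_format = "json")
  writeLines(dump, file.path(dir, "model_dump.json"))
  tsv_write(data.frame(feature = model$feature_genes),
            file.path(dir, "features.tsv"))
  tsv_write(data.frame(label = model$label_vocabulary),
            file.path(dir, "labels.tsv"))
  jsonlite::write_json(model$manifest, file.path(dir, "train_manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' Relative-frequency concordance between two labelings
#'
#' Normalises label frequencies within each dataset and reports the paired
#' frequency table with Pearson correlations on the linear and log10 scales
#' and each label's fold deviation from the diagonal.
#'
#' @param labels_a,labels_b Label vectors (shared vocabulary; labels absent
#'   from one side get frequency 0 and are excluded from the log10
#'   correlation).
#' @return List: `table` (label, freq_a, freq_b, fold = freq_b/freq_a),
#'   `pearson` (linear), `pearson_log10`.
#' @export
frequency_concordance <- function(labels_a, labels_b) {
  vocab <- sort(union(unique(labels_a), unique(labels_b)))
  fa <- as.numeric(table(factor(labels_a, vocab))) / length(labels_a)
  fb <- as.numeric(table(factor(labels_b, vocab))) / length(labels_b)
  if (length(vocab) < 2 || sd(fa) == 0 || sd(fb) == 0)
    stopf("constant frequency vector; correlation undefined")
  pos <- fa > 0 & fb > 0
  list(table = data.frame(label = vocab, freq_a = fa, freq_b = fb,
                          fold = ifelse(fa > 0, fb / fa, Inf),
                          stringsAsFactors = FALSE),
       pearson = cor(fa, fb),
       pearson_log10 = if (sum(pos) >= 3) cor(log10(fa[pos]), log10(fb[pos]))
                       else NA_real_)
}

#' Held-out validation error across clustering resolutions
#'
#' For each candidate clustering, runs the train/validate protocol
#' ([split_train_validation()] + [train_mapper()]) and records the held-out
#' error; flags the smallest resolution whose error exceeds `error_threshold`
#' as the onset of over-clustering.
#'
#' @param x Normalised log expression (cells x genes).
#' @param labels_at_resolutions Named list of per-cell label vectors, one
#'   per resolution (names are resolution values).
#' @param frac,cap,min_train Split protocol parameters.
#' @param error_threshold Error level indicating over-clustering.
#' @param seed Integer seed.
#' @param ... Passed to [train_mapper()].
#' @return data.frame (resolution, n_clusters, heldout_error, flagged) with
#'   attribute `first_flagged`.
#' @export
overcluster_diagnostic <- function(x, labels_at_resolutions, frac = 0.7,
                                   cap = 1000, min_train = 100,
                                   error_threshold = 0.1, seed = 1L, ...) {
  stopifnot(length(labels_at_resolutions) >= 1)
  res <- names(labels_at_resolutions)
  out <- data.frame(resolution = res,
                    n_clusters = NA_integer_,
                    heldout_error = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(res)) {
    labs <- labels_at_resolutions[[i]]
    sp <- split_train_validation(labs, frac = frac, cap = cap,
                                 min_train = min_train, seed = seed + i)
    model <- train_mapper(x, labs, rows = sp$train, seed = seed + i, ...)
    pred <- predict_labels(model, x[sp$heldout, , drop = FALSE])
    out$n_clusters[i] <- length(unique(labs))
    out$heldout_error[i] <- mean(pred$assigned != as.character(labs)[sp$heldout])
  }
  out$flagged <- out$heldout_error > error_threshold
  first <- if (length(res) >= 2 && any(out$flagged)) res[which(out$flagged)[1]] else NA
  attr(out, "first_flagged") <- first
  out
}
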