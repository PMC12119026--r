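test_that("train/validation split follows the per-cluster sampling protocol", {
  labels <- rep(c("big", "mid", "small"), c(2000, 100, 50))
  sp <- split_train_validation(labels, seed = 3)
  plan <- sp$plan
  # 2,000-cell cluster: capped at 1,000 unique training cells
  expect_equal(plan$n_train[plan$cluster == "big"], 1000)
  expect_false(plan$upsampled[plan$cluster == "big"])
  # 100-cell cluster: 70 unique drawn, upsampled to 100
  expect_equal(plan$n_unique[plan$cluster == "mid"], 70)
  expect_equal(plan$n_train[plan$cluster == "mid"], 100)
  # 50-cell cluster: 35 unique, bootstrapped to 100
  expect_equal(plan$n_unique[plan$cluster == "small"], 35)
  expect_equal(plan$n_train[plan$cluster == "small"], 100)
  # held-out = unsampled cells
  expect_equal(sum(labels[sp$heldout] == "mid"), 30)
  expect_length(intersect(unique(sp$train), sp$heldout), 0)
  # reproducible byte-identical split
  sp2 <- split_train_validation(labels, seed = 3)
  expect_identical(sp$train, sp2$train)
  expect_identical(sp$heldout, sp2$heldout)
  # singleton cluster: trained on the lone cell, empty held-out, warning
  expect_warning(sp3 <- split_train_validation(c("a", rep("b", 300)), seed = 1),
                 "single cell")
  expect_false(1 %in% sp3$heldout)
})

test_that("separable clusters are learned perfectly and probabilities are valid", {
  # two linearly separable blobs: held-out accuracy must be 100%
  x <- withr::with_seed(8, {
    blob <- matrix(rnorm(200 * 30), 200, 30)
    blob[101:200, 1:5] <- blob[101:200, 1:5] + 8
    toy_counts(blob - min(blob))
  })
  labs <- rep(c("A", "B"), each = 100)
  sp <- split_train_validation(labs, min_train = 50, seed = 5)
  model <- train_mapper(x, labs, rows = sp$train, nrounds = 15, seed = 5)
  pred <- predict_labels(model, x[sp$heldout, , drop = FALSE])
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6))
  expect_equal(mean(pred$assigned == labs[sp$heldout]), 1)
  # assignment rule: argmax iff max prob strictly above reject_factor / r
  r <- length(model$label_vocabulary)
  manual <- ifelse(pred$max_prob > 1.2 / r,
                   model$label_vocabulary[max.col(pred$prob, ties.method = "first")],
                   "Unassigned")
  expect_identical(pred$assigned, manual)
})

test_that("raising the rejection factor never assigns more cells", {
  sim <- fix_flat(k = 3, cells = 60, genes = 500)
  t1 <- which(sim$meta$timepoint == "T1")
  x <- sim$x[t1, ]
  labs <- sim$truth$cells$subclass[t1]
  model <- train_mapper(x, labs, nrounds = 8, seed = 5)
  n_assigned <- vapply(c(1.0, 1.2, 2.0, 2.9), function(rf)
    sum(predict_labels(model, x, reject_factor = rf)$assigned != "Unassigned"),
    numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("shuffled labels give chance-level held-out accuracy", {
  sim <- fix_flat(k = 3, cells = 60, genes = 500)
  t1 <- which(sim$meta$timepoint == "T1")
  x <- sim$x[t1, ]
  accs <- vapply(1:5, function(s) {
    labs <- withr::with_seed(s, sample(sim$truth$cells$subclass[t1]))
    sp <- split_train_validation(labs, seed = s)
    model <- train_mapper(x, labs, rows = sp$train, nrounds = 8, seed = s)
    pred <- predict_labels(model, x[sp$heldout, , drop = FALSE],
                           reject_factor = 0)  # no rejection: pure argmax
    mean(pred$assigned == labs[sp$heldout])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.12)
})

test_that("missing feature genes are zero-filled with a warning", {
  sim <- fix_flat(k = 3, cells = 60, genes = 500)
  t1 <- which(sim$meta$timepoint == "T1")
  x <- sim$x[t1, ]
  labs <- sim$truth$cells$subclass[t1]
  model <- train_mapper(x, labs, nrounds = 8, seed = 5)
  x_miss <- x[, -seq_len(10)]
  expect_warning(pred <- predict_labels(model, x_miss), "zero-filled")
  expect_length(pred$assigned, nrow(x_miss))
})

test_that("model serialisation writes an auditable JSON dump", {
  sim <- fix_flat(k = 3, cells = 60, genes = 500)
  t1 <- which(sim$meta$timepoint == "T1")
  model <- train_mapper(sim$x[t1, ], sim$truth$cells$subclass[t1],
                        nrounds = 5, seed = 5)
  dir <- withr::local_tempdir()
  save_mapper(model, file.path(dir, "model"))
  expect_true(file.exists(file.path(dir, "model", "model_dump.json")))
  feats <- read.table(file.path(dir, "model", "features.tsv"), header = TRUE)
  expect_equal(feats$feature, model$feature_genes)
})

test_that("frequency concordance detects only the shifted types", {
  sim <- fix_continuum()
  tc <- sim$truth$cells
  t1 <- sim$meta$condition == "T1"; t2 <- sim$meta$condition == "T2"
  fc <- frequency_concordance(tc$type[t1], tc$type[t2])
  expect_gt(fc$pearson, 0)
  shifted <- c("L23_A", "L23_B")
  tab <- fc$table
  off <- abs(log2(tab$fold)) >= log2(1.8)
  expect_true(all(tab$label[off] %in% shifted))
  expect_setequal(tab$label[off], shifted)
  # identical vectors -> r exactly 1
  fc2 <- frequency_concordance(tc$type[t1], tc$type[t1])
  expect_equal(fc2$pearson, 1)
  # closed-form Pearson on a known pair
  a <- c(0.5, 0.3, 0.2); b <- c(0.45, 0.35, 0.2)
  la <- rep(c("x", "y", "z"), a * 100); lb <- rep(c("x", "y", "z"), b * 100)
  fc3 <- frequency_concordance(la, lb)
  expect_equal(fc3$pearson, cor(a, b), tolerance = 1e-12)
  expect_error(frequency_concordance(rep("x", 5), rep("x", 5)), "constant")
})

test_that("over-clustering inflates the held-out validation error", {
  sim <- fix_flat(k = 3, cells = 100, genes = 500, seed = 77)
  t1 <- which(sim$meta$timepoint == "T1")
  x <- sim$x[t1, ]
  labs <- sim$truth$cells$subclass[t1]
  # split one true cluster in half at random -> unlearnable pair
  labs_over <- labs
  idx <- which(labs == "SC01")
  half <- withr::with_seed(1, sample(idx, length(idx) %/% 2))
  labs_over[half] <- "SC01_spurious"
  curve <- overcluster_diagnostic(
    x, list("1" = labs, "2" = labs_over),
    min_train = 50, nrounds = 8, seed = 11)
  expect_equal(nrow(curve), 2)
  expect_lt(curve$heldout_error[1], 0.1)
  expect_gt(curve$heldout_error[2], curve$heldout_error[1])
  expect_equal(attr(curve, "first_flagged"), "2")
  # a single resolution yields a length-1 curve and no flag
  one <- overcluster_diagnostic(x, list("1" = labs), min_train = 50,
                                nrounds = 8, seed = 11)
  expect_equal(nrow(one), 1)
  expect_true(is.na(attr(one, "first_flagged")))
})
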