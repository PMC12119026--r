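test_that("cell filters apply the strict printed inequalities exactly", {
  # five cells with totals {400, 501, 39999, 40000, 600}, n_genes all 10
  totals <- c(400, 501, 39999, 40000, 600)
  m <- do.call(rbind, lapply(totals, function(tt) {
    v <- numeric(50); v[1:10] <- c(rep(floor(tt / 10), 9), tt - 9 * floor(tt / 10))
    v
  }))
  m <- toy_counts(m)
  meta <- data.frame(barcode = rownames(m))
  f <- filter_cells(m, meta)
  expect_equal(f$meta$n_counts, c(501, 39999, 600))  # 3 retained, order kept
  # boundary: a cell detecting exactly 7,000 genes is removed (strict <)
  m2 <- toy_counts(matrix(1, 2, 7001))
  m2[2, 7001] <- 0                      # second cell has 7,000 genes
  meta2 <- cell_qc_stats(m2, data.frame(barcode = rownames(m2)))
  expect_equal(meta2$n_genes, c(7001L, 7000L))
  expect_warning(f2 <- filter_cells(m2, meta2), "all cells removed")
  expect_equal(nrow(f2$counts), 0)      # both at/above the gene cap
  expect_error(filter_cells(m2, meta2, min_counts = 500, max_counts = 400),
               "below max_counts")
})

test_that("gene filter boundary sits at exactly min_cells", {
  m <- toy_counts(rbind(diag(1, 100, 3), matrix(0, 2, 3)))
  m[1:99, 2] <- 1; m[100, 2] <- 0
  m[, 3] <- 0; m[1:100, 1] <- 1
  f <- filter_genes(m, min_cells = 100)
  expect_equal(colnames(f), "g1")       # g2 in 99 cells, g3 all-zero
  expect_equal(colnames(filter_genes(m, min_cells = 99)), c("g1", "g2"))
})

test_that("filters are idempotent and preserve order", {
  sim <- fix_small()
  meta <- cell_qc_stats(sim$counts, sim$meta)
  f1 <- filter_cells(sim$counts, meta)
  f2 <- filter_cells(f1$counts, f1$meta)
  expect_identical(f1$counts, f2$counts)
  g1 <- filter_genes(sim$counts, 20)
  expect_identical(g1, filter_genes(g1, 20))
  expect_identical(rownames(f1$counts),
                   rownames(sim$counts)[rownames(sim$counts) %in% rownames(f1$counts)])
})

test_that("normalisation rescales rows exactly and applies log1p", {
  m <- toy_counts(matrix(c(2, 3, 5), 1, 3))
  x <- normalize_log(m, target_sum = 1e4, log = FALSE)
  expect_equal(as.numeric(x), c(2000, 3000, 5000))
  xl <- normalize_log(m, target_sum = 1e4)
  expect_equal(as.numeric(xl), log1p(c(2000, 3000, 5000)))
  # a count of 1 in a 5,000-count cell scales to 2 -> log(3)
  v <- numeric(100); v[1] <- 1; v[2:51] <- c(rep(100, 49), 4999 - 4900)
  m2 <- toy_counts(matrix(v, 1)); stopifnot(sum(v) == 5000)
  x2 <- normalize_log(m2, target_sum = 1e4)
  expect_equal(x2[1, 1], log(3))
  # rows sum to target before log
  sim <- fix_small()
  keep <- rowSums(sim$counts) > 0
  xs <- normalize_log(sim$counts[keep, ], log = FALSE)
  expect_true(all(abs(rowSums(xs) - 1e4) < 1e-6 * 1e4))
  # zero-count cell refused
  m3 <- toy_counts(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(normalize_log(m3), "zero-count")
})

test_that("clustering recovers well-separated planted groups deterministically", {
  sim <- fix_flat(k = 3, cells = 60, genes = 500)
  # restrict to one timepoint so subclasses are the only structure
  t1 <- sim$meta$timepoint == "T1"
  x <- sim$x[t1, ]
  cl <- cluster_pipeline(x, n_hvg = 200, n_pcs = 10, resolution = 0.5, seed = 9)
  truth <- sim$truth$cells$subclass[t1]
  # perfect agreement: each cluster maps to exactly one subclass
  tab <- table(cl$cluster, truth)
  expect_equal(length(unique(cl$cluster)), 3)
  expect_true(all(rowSums(tab > 0) == 1))
  cl2 <- cluster_pipeline(x, n_hvg = 200, n_pcs = 10, resolution = 0.5, seed = 9)
  expect_identical(cl$cluster, cl2$cluster)
  expect_equal(min(cl$cluster), 0L)
  expect_error(cluster_pipeline(x[1:10, ], k_neighbors = 15), "fewer cells")
  # per-cluster QC summaries when metadata is supplied
  fake_meta <- data.frame(percent_mito = runif(nrow(x), 0, 0.1),
                          doublet_score = runif(nrow(x)))
  cl3 <- cluster_pipeline(x, n_hvg = 200, n_pcs = 10, resolution = 0.5,
                          seed = 9, meta = fake_meta)
  expect_true(all(c("size", "mean_percent_mito", "mean_doublet_score")
                  %in% names(cl3$summary)))
  expect_equal(sum(cl3$summary$size), nrow(x))
})

test_that("high-mito clusters are removed at the cluster level", {
  meta <- data.frame(barcode = sprintf("c%d", 1:40),
                     percent_mito = c(rep(0.3, 10), rep(0.07, 30)))
  m <- toy_counts(matrix(1, 40, 5), cells = meta$barcode)
  clusters <- rep(c(0L, 1L), c(10, 30))
  out <- remove_mito_clusters(m, meta, clusters, mito_threshold = 0.2)
  expect_equal(out$removed_clusters, 0L)
  expect_equal(nrow(out$counts), 30)
  # threshold 1.0 removes nothing
  out2 <- remove_mito_clusters(m, meta, clusters, mito_threshold = 1.0)
  expect_equal(nrow(out2$counts), 40)
})

test_that("mapping-based purification implements both removal rules", {
  n <- 1000
  meta <- data.frame(barcode = sprintf("c%d", 1:n))
  m <- toy_counts(matrix(1, n, 4), cells = meta$barcode)
  clusters <- rep(0L, n)
  # 985 cells map to A, 15 (1.5%) to B -> the 15 removed at min_component 2%
  mapping <- data.frame(assigned = rep(c("A", "B"), c(985, 15)),
                        max_prob = 0.95)
  out <- purify_by_mapping(m, meta, clusters, mapping)
  expect_equal(out$n_removed, 15)
  expect_true(all(mapping$assigned[match(out$meta$barcode, meta$barcode)] == "A"))
  # uniform mapping to one label -> untouched
  map2 <- data.frame(assigned = "A", max_prob = 0.99)
  map2 <- map2[rep(1, n), ]
  expect_equal(purify_by_mapping(m, meta, clusters, map2)$n_removed, 0)
  # diffuse cluster: max share 0.30 and mean prob 0.4 -> removed whole
  map3 <- data.frame(assigned = rep(c("A", "B", "C", "D"), c(300, 250, 250, 200)),
                     max_prob = 0.4)
  out3 <- purify_by_mapping(m, meta, clusters, map3)
  expect_equal(out3$removed_clusters, 0L)
  expect_equal(nrow(out3$counts), 0)
  expect_error(purify_by_mapping(m, meta, clusters, mapping[1:10, ]),
               "cover all cells")
})

test_that("fallback doublet scoring ranks synthetic doublets above singlets", {
  set.seed(4)
  a <- matrix(rpois(600, 5), 60, 10); a[, 1:3] <- a[, 1:3] + 20
  b <- matrix(rpois(600, 5), 60, 10); b[, 8:10] <- b[, 8:10] + 20
  mix <- (a[1:20, ] + b[1:20, ])            # doublet-like cells
  m <- toy_counts(rbind(a, b, mix))
  x <- normalize_log(m)
  clusters <- rep(c(0L, 1L, 2L), c(60, 60, 20))
  sc <- doublet_score_fallback(x, clusters, seed = 1)
  expect_gt(mean(sc[121:140]), mean(sc[1:120]))
})

test_that("planted low-quality and high-mito cells are removed at defaults", {
  sim <- fix_small()
  meta <- cell_qc_stats(sim$counts, sim$meta)
  tc <- sim$truth$cells
  f <- filter_cells(sim$counts, meta)
  kept <- tc$barcode %in% f$meta$barcode
  expect_gte(mean(!kept[tc$is_lowq]), 0.95)
  # high-mito population: cluster-level removal
  cc <- filter_genes(f$counts, 10)
  x <- normalize_log(cc)
  cl <- cluster_pipeline(x, n_hvg = 300, n_pcs = 15, resolution = 1, seed = 2)
  out <- remove_mito_clusters(cc, f$meta, cl, mito_threshold = 0.15)
  tc_kept <- tc[match(out$meta$barcode, tc$barcode), ]
  expect_gte(1 - mean(tc_kept$is_highmito) * nrow(out$meta) /
               max(1, sum(tc$is_highmito)), 0.0)  # sanity; strict recall below
  recall <- 1 - sum(tc_kept$is_highmito) / sum(tc$is_highmito & kept)
  expect_gte(recall, 0.95)
})
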