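test_that("type markers are recovered from planted marker blocks", {
  sim <- fix_continuum()
  in_l23 <- which(!is.na(sim$truth$cells$subclass) &
                    sim$truth$cells$subclass == "L23" &
                    sim$meta$condition == "T2")
  mk <- select_type_markers(sim$x[in_l23, ], sim$truth$cells$type[in_l23])
  planted <- sim$truth$programs
  for (ty in c("L23_A", "L23_B", "L23_C")) {
    genes_true <- sim$design$gene_ids[planted$gene[planted$program == "type_marker" &
                                                     planted$type == ty]]
    expect_gte(mean(genes_true %in% mk$markers[[ty]]), 0.9)
  }
  expect_true(all(unlist(mk$markers) %in% mk$union))
})

test_that("a type identical to the rest yields no markers, and the FC gate is strict", {
  # two 'types' drawn from one distribution -> (almost) no markers for either
  set.seed(1)
  m <- toy_counts(matrix(rpois(200 * 50, 2), 200, 50))
  x <- normalize_log(m + 1)  # +1 avoids zero cells
  labs <- rep(c("A", "B"), each = 100)
  mk <- tryCatch(select_type_markers(x, labs),
                 error = function(e) list(markers = list(A = character(),
                                                         B = character())))
  expect_lte(length(mk$markers$A), 1)
  # fold change exactly at the gate is excluded (strict >)
  xa <- matrix(log1p(3), 30, 1); xb <- matrix(log1p(2), 30, 1)
  mm <- toy_counts(rbind(cbind(xa, 1), cbind(xb, 1)), genes = c("edge", "bg"))
  tab <- de_test(mm, 1:30, 31:60, min_frac = 0.2, min_fc = 1.5)
  edge <- tab[tab$gene == "edge", ]
  # ratio (3 + eps)/(2 + eps) < 1.5 under the pseudocount -> not significant
  expect_false(edge$log2fc > log2(1.5))
})

test_that("PCA embedding is orthonormal with a full variance decomposition", {
  sim <- fix_continuum()
  in_l23 <- which(!is.na(sim$truth$cells$subclass) &
                    sim$truth$cells$subclass == "L23")
  mk <- cached("l23_markers", function()
    select_type_markers(sim$x[in_l23, ], sim$truth$cells$type[in_l23]))
  emb <- pca_condition(sim$x[in_l23, ], mk$union, n_components = 4)
  expect_equal(crossprod(emb$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(emb$variance_fraction_all), 1, tolerance = 1e-8)
  expect_true(all(diff(emb$variance_fraction_all) <= 1e-12))
  # duplicated dataset -> identical spectrum
  x2 <- rbind(sim$x[in_l23, ], sim$x[in_l23, ])
  emb2 <- pca_condition(x2, mk$union, n_components = 4)
  expect_equal(emb2$variance_fraction, emb$variance_fraction, tolerance = 1e-6)
  expect_error(pca_condition(sim$x[in_l23[1:3], ], mk$union,
                             n_components = 10), "fewer cells")
})

test_that("rank-2 structure shows a spectral gap after PC2", {
  set.seed(9)
  n <- 300; p <- 60
  basis <- matrix(rnorm(2 * p), 2, p)
  coords <- matrix(rnorm(n * 2, sd = c(4, 2)), n, 2)
  xd <- coords %*% basis + matrix(rnorm(n * p, sd = 0.1), n, p)
  m <- toy_counts(xd - min(xd))
  emb <- pca_condition(m, colnames(m), n_components = 5)
  vf <- emb$variance_fraction_all
  expect_gt(vf[2] / vf[3], 20)      # large gap between PC2 and PC3
  expect_gt(sum(vf[1:2]), 0.95)
})

test_that("eigenvector correspondence is sign-invariant and diagnoses identity", {
  sim <- fix_continuum()
  in_l23 <- which(!is.na(sim$truth$cells$subclass) &
                    sim$truth$cells$subclass == "L23")
  mk <- cached("l23_markers", function()
    select_type_markers(sim$x[in_l23, ], sim$truth$cells$type[in_l23]))
  emb <- pca_condition(sim$x[in_l23, ], mk$union, n_components = 3)
  m_self <- eigenvector_correspondence(emb, emb, n = 3)
  expect_equal(unname(m_self), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(attr(m_self, "one_to_one"))
  # flipped signs leave absolute dot products unchanged
  emb_flip <- emb
  emb_flip$loadings <- -emb$loadings
  m_flip <- eigenvector_correspondence(emb, emb_flip, n = 3)
  expect_equal(unname(m_flip), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  emb_bad <- emb
  emb_bad$feature_genes <- rev(emb$feature_genes)
  expect_error(eigenvector_correspondence(emb, emb_bad), "feature sets")
})

test_that("marker scores are arithmetic means with discriminative power", {
  m <- toy_counts(matrix(c(2, 4, 7,
                           0, 6, 1), 2, 3, byrow = TRUE),
                  genes = c("g1", "g2", "g3"))
  expect_equal(unname(marker_score(m, c("g1", "g2"))), c(3, 3))
  expect_equal(unname(marker_score(m, "g3")), c(7, 1))
  expect_error(marker_score(m, character()), "empty")
  expect_error(marker_score(m, "nope"), "not in matrix")
  # planted type-A cells score higher on A markers (AUC >= 0.9)
  sim <- fix_continuum()
  tc <- sim$truth$cells
  in_l23 <- which(!is.na(tc$subclass) & tc$subclass == "L23")
  mk <- cached("l23_markers", function()
    select_type_markers(sim$x[in_l23, ], tc$type[in_l23]))
  sc_a <- marker_score(sim$x[in_l23, ], mk$markers$L23_A)
  is_a <- tc$type[in_l23] == "L23_A"
  auc <- mean(outer(sc_a[is_a], sc_a[!is_a], ">")) +
    0.5 * mean(outer(sc_a[is_a], sc_a[!is_a], "=="))
  expect_gte(auc, 0.9)
})

test_that("KS comparison matches hand-built ECDF cases", {
  expect_equal(ks_compare(1:6, 1:6), list(D = 0, p = 1))
  out <- ks_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$D, 1)
  expect_error(ks_compare(1, 1:5), "at least 2")
})

test_that("PC1 profiles are flat for identical conditions and degenerate windows", {
  set.seed(3)
  n <- 200
  pc1 <- rnorm(2 * n)
  scores <- list(s = rnorm(2 * n))
  cond <- rep(c("A", "B"), each = n)
  # same distribution in both conditions -> KS p typically large
  prof <- pc1_profile(scores, pc1, cond, window_frac = 0.2)
  expect_gt(prof$ks$p, 0.01)
  # window fraction 1: constant curve at the per-condition mean
  prof2 <- pc1_profile(scores, pc1, cond, window_frac = 1)
  va <- prof2$curves$value[prof2$curves$condition == "A"]
  expect_equal(va, rep(mean(scores$s[cond == "A"]), n), tolerance = 1e-12)
  # sliding mean sanity on a tiny vector
  expect_equal(cortexdev:::sliding_mean(c(1, 2, 3, 4), 5), rep(2.5, 4))
  expect_equal(cortexdev:::sliding_mean(c(1, 2, 3), 1), c(1, 2, 3))
})
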