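#' Per-cell QC covariates
#'
#' Computes `n_counts` (total transcripts), `n_genes` (genes detected) and
#' `percent_mito` (fraction of counts from mitochondrial genes) and appends
#' them to the metadata.
#'
#' @param counts cells x genes sparse count matrix.
#' @param meta Per-cell metadata (row order matching `counts`).
#' @param is_mito Logical per gene; defaults to a `"mt-"` name prefix.
#' @return `meta` with columns `n_counts`, `n_genes`, `percent_mito`.
#' @export
cell_qc_stats <- function(counts, meta, is_mito = NULL) {
  counts <- as_sparse(counts)
  if (nrow(counts) != nrow(meta)) stopf("counts and meta disagree on cell number")
  if (is.null(is_mito)) is_mito <- grepl("^mt-", colnames(counts))
  meta$n_counts <- as.integer(round(rowSums(counts)))
  meta$n_genes <- as.integer(rowSums(counts > 0))
  mito <- if (any(is_mito)) rowSums(counts[, is_mito, drop = FALSE]) else 0
  meta$percent_mito <- ifelse(meta$n_counts > 0, mito / meta$n_counts, 0)
  meta
}

#' Filter cells on QC covariates
#'
#' Retains cells satisfying the strict inequalities
#' `n_genes < max_genes`, `n_counts < max_counts` and `n_counts > min_counts`;
#' optionally also `percent_mito < max_mito` (off by default, since the
#' cluster-level mitochondrial rule of [remove_mito_clusters()] is the
#' primary high-mito filter). Cell order is preserved.
#'
#' @param counts cells x genes sparse count matrix.
#' @param meta Metadata containing `n_counts`, `n_genes` (and `percent_mito`
#'   if `max_mito` is used); computed via [cell_qc_stats()] when absent.
#' @param max_genes,max_counts,min_counts Strict thresholds.
#' @param max_mito Optional strict per-cell mitochondrial-fraction cap, or
#'   `NULL` to disable.
#' @return List with filtered `counts` and `meta`.
#' @export
filter_cells <- function(counts, meta, max_genes = 7000, max_counts = 40000,
                         min_counts = 500, max_mito = NULL) {
  stopifnot(max_genes > 0, max_counts > 0, min_counts > 0)
  if (min_counts >= max_counts) stopf("min_counts must be below max_counts")
  counts <- as_sparse(counts)
  if (!all(c("n_counts", "n_genes") %in% names(meta)))
    meta <- cell_qc_stats(counts, meta)
  keep <- meta$n_genes < max_genes & meta$n_counts < max_counts &
    meta$n_counts > min_counts
  if (!is.null(max_mito)) keep <- keep & meta$percent_mito < max_mito
  if (!any(keep)) warnf("all cells removed by QC thresholds")
  list(counts = counts[keep, , drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

#' Filter genes by detection breadth
#'
#' Keeps genes that are nonzero in at least `min_cells` cells.
#'
#' @param counts cells x genes sparse count matrix.
#' @param min_cells Minimum number of cells in which a gene must be detected.
#' @return Filtered count matrix (gene order preserved).
#' @export
filter_genes <- function(counts, min_cells = 100) {
  stopifnot(min_cells >= 1)
  counts <- as_sparse(counts)
  keep <- colSums(counts > 0) >= min_cells
  counts[, keep, drop = FALSE]
}

#' Library-size normalisation with log transform
#'
#' Rescales each cell's counts to sum to `target_sum`, then applies
#' `log1p` (natural base). Sparsity is preserved.
#'
#' @param counts cells x genes sparse count matrix; every cell must have at
#'   least one count (filter first).
#' @param target_sum Per-cell total after rescaling.
#' @param log Apply the log1p transform (set `FALSE` for the linear scale).
#' @return Sparse normalised expression matrix.
#' @export
normalize_log <- function(counts, target_sum = 1e4, log = TRUE) {
  counts <- as_sparse(counts)
  rs <- rowSums(counts)
  if (any(rs == 0)) stopf("zero-count cell present; filter cells first")
  x <- Diagonal(x = target_sum / rs) %*% counts
  x <- as_sparse(x)
  if (log) x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  x
}

#' Undo the log1p transform on a normalised matrix
#' @param x Sparse log1p-normalised matrix.
#' @return Matrix on the linear normalised scale.
#' @export
delog <- function(x) {
  x <- as_sparse(x)
  x@x <- expm1(x@x)
  x
}

#' Highly variable gene selection (mean-dispersion binning)
#'
#' Computes per-gene mean and dispersion (variance/mean) on the de-logged
#' normalised scale, z-scores dispersion within mean bins, and returns the
#' top `n_hvg` genes by normalised dispersion.
#'
#' @param x Normalised log expression (cells x genes).
#' @param n_hvg Number of genes to select.
#' @param n_bins Number of mean bins.
#' @return Character vector of selected gene names (matrix column order).
#' @export
select_hvgs <- function(x, n_hvg = 2000, n_bins = 20) {
  x <- as_sparse(x)
  xe <- delog(x)
  mu <- colMeans(xe)
  ex2 <- colMeans(xe^2)
  v <- pmax(0, (ex2 - mu^2) * nrow(xe) / max(1, nrow(xe) - 1))
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- mu > 0
  bins <- cut(rank(mu[keep], ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- numeric(sum(keep))
  for (b in unique(bins)) {
    idx <- bins == b
    m <- mean(disp[keep][idx]); s <- sd(disp[keep][idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[keep][idx] - m) / s
  }
  genes <- colnames(x)[keep]
  n_hvg <- min(n_hvg, length(genes))
  sel <- genes[order(z, decreasing = TRUE)[seq_len(n_hvg)]]
  colnames(x)[colnames(x) %in% sel]
}

# z-score columns of a dense matrix, clipping extremes.
scale_clip <- function(xd, clip = 10) {
  xd <- scale(xd)
  xd[is.na(xd)] <- 0
  xd[xd > clip] <- clip
  xd[xd < -clip] <- -clip
  xd
}

# PCA via eigen-decomposition of the feature covariance (features are few).
# Returns scores (cells x k), loadings (features x k, orthonormal, sign fixed
# so the largest-magnitude loading is positive) and the full eigenvalue
# spectrum.
pca_eig <- function(xd, k) {
  xc <- sweep(xd, 2L, colMeans(xd))
  cv <- crossprod(xc) / max(1, nrow(xc) - 1)
  ee <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  k <- min(k, ncol(xd))
  load <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(xd)
  list(scores = xc %*% load, loadings = load, eigenvalues = vals)
}

# Exact k-nearest-neighbour indices in Euclidean space, blockwise.
knn_index <- function(s, k) {
  n <- nrow(s)
  if (n <= k) stopf("fewer cells than k_neighbors")
  nn <- matrix(0L, n, k)
  sq <- rowSums(s^2)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / 1024L))) {
    d2 <- outer(sq[ix], sq, "+") - 2 * s[ix, , drop = FALSE] %*% t(s)
    for (r in seq_along(ix)) {
      d2[r, ix[r]] <- Inf
      nn[ix[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  nn
}

#' Clustering pipeline: HVGs, PCA, kNN graph, Leiden
#'
#' Selects highly variable genes, z-scores them, reduces to `n_pcs`
#' principal components, builds a k-nearest-neighbour graph and partitions
#' it with the Leiden algorithm (modularity objective). Deterministic for a
#' fixed seed; cluster ids are contiguous from 0 in decreasing size order.
#'
#' @param x Normalised log expression (cells x genes).
#' @param n_hvg,n_pcs,k_neighbors,resolution Pipeline parameters.
#' @param seed Integer seed.
#' @param meta Optional cell metadata; when it carries `percent_mito` /
#'   `doublet_score`, per-cluster means are added to the summary.
#' @return List of class `cluster_assignment`: `cluster` (integer per cell),
#'   `resolution`, `summary` (per-cluster size and QC means), `hvg`, `pcs`.
#' @export
cluster_pipeline <- function(x, n_hvg = 2000, n_pcs = 40, k_neighbors = 15,
                             resolution = 1.0, seed = 1L, meta = NULL) {
  x <- as_sparse(x)
  if (k_neighbors < 2) stopf("k_neighbors must be >= 2")
  if (nrow(x) <= k_neighbors) stopf("fewer cells than k_neighbors")
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  hvg <- select_hvgs(x, n_hvg)
  xd <- scale_clip(as.matrix(x[, hvg, drop = FALSE]))
  pc <- pca_eig(xd, n_pcs)
  nn <- knn_index(pc$scores, k_neighbors)
  edges <- cbind(rep(seq_len(nrow(nn)), each = ncol(nn)), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    igraph::membership(cl)
  })
  # contiguous ids from 0, by decreasing cluster size (ties by first member)
  tab <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(tab) - 1L, names(tab))
  cluster <- unname(relab[as.character(memb)])
  summ <- as.data.frame(table(cluster = cluster), stringsAsFactors = FALSE)
  names(summ)[2] <- "size"
  if (!is.null(meta)) {
    for (col in intersect(c("percent_mito", "doublet_score"), names(meta))) {
      summ[[paste0("mean_", col)]] <-
        as.numeric(tapply(meta[[col]], cluster, mean))
    }
  }
  structure(list(
    cluster = as.integer(cluster),
    resolution = resolution,
    summary = summ,
    hvg = hvg,
    pcs = pc$scores
  ), class = "cluster_assignment")
}

#' Remove clusters with high mean mitochondrial content
#'
#' Drops, in their entirety, clusters whose mean `percent_mito` is at or
#' above `mito_threshold`.
#'
#' @param counts,meta Matrix and metadata (with `percent_mito`).
#' @param clusters Integer cluster id per cell (or a `cluster_assignment`).
#' @param mito_threshold Fraction at/above which a cluster is removed.
#' @return List with filtered `counts`, `meta`, `clusters` and the removed
#'   cluster ids.
#' @export
remove_mito_clusters <- function(counts, meta, clusters, mito_threshold = 0.2) {
  if (inherits(clusters, "cluster_assignment")) clusters <- clusters$cluster
  counts <- as_sparse(counts)
  if (length(clusters) != nrow(counts)) stopf("clusters must cover all cells")
  if (!"percent_mito" %in% names(meta)) meta <- cell_qc_stats(counts, meta)
  mm <- tapply(meta$percent_mito, clusters, mean)
  bad <- as.integer(names(mm)[mm >= mito_threshold])
  keep <- !(clusters %in% bad)
  list(counts = counts[keep, , drop = FALSE], meta = meta[keep, , drop = FALSE],
       clusters = clusters[keep], removed_clusters = bad)
}

#' Purify clusters using a reference mapping
#'
#' Two-stage cluster purification: (a) clusters whose mapping to the
#' reference taxonomy is diffuse or low-confidence (per `confidence_rules`)
#' are removed whole; (b) within retained clusters, cells whose mapped
#' reference label accounts for less than `min_component` of the cluster are
#' removed. Unassigned cells count toward cluster size but are not removed
#' by the component rule.
#'
#' @param counts,meta Matrix and metadata.
#' @param clusters Integer cluster id per cell.
#' @param mapping A `mapping_result` (see [predict_labels()]) covering all
#'   cells, or a data.frame with columns `assigned` and `max_prob`.
#' @param min_component Minimum within-cluster share for a mapped label.
#' @param confidence_rules List with `max_share` and `mean_prob`: a cluster
#'   is diffuse when its largest assigned-label share is below `max_share`
#'   AND its mean top assignment probability is below `mean_prob`.
#' @return List with filtered `counts`, `meta`, `clusters`, plus
#'   `removed_clusters` and the number of cells removed by each rule.
#' @export
purify_by_mapping <- function(counts, meta, clusters, mapping,
                              min_component = 0.02,
                              confidence_rules = list(max_share = 0.5,
                                                      mean_prob = 0.5)) {
  if (inherits(clusters, "cluster_assignment")) clusters <- clusters$cluster
  counts <- as_sparse(counts)
  if (inherits(mapping, "mapping_result"))
    mapping <- data.frame(assigned = mapping$assigned, max_prob = mapping$max_prob,
                          stringsAsFactors = FALSE)
  if (nrow(mapping) != nrow(counts)) stopf("mapping must cover all cells")
  keep <- rep(TRUE, nrow(counts))
  removed_clusters <- integer()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    lab <- mapping$assigned[in_cl]
    shares <- table(lab[lab != "Unassigned"]) / sum(in_cl)
    max_share <- if (length(shares)) max(shares) else 0
    diffuse <- max_share < confidence_rules$max_share &&
      mean(mapping$max_prob[in_cl]) < confidence_rules$mean_prob
    if (diffuse) {
      keep[in_cl] <- FALSE
      removed_clusters <- c(removed_clusters, cl)
    } else {
      minor <- names(shares)[shares < min_component]
      keep[in_cl & mapping$assigned %in% minor] <- FALSE
    }
  }
  list(counts = counts[keep, , drop = FALSE], meta = meta[keep, , drop = FALSE],
       clusters = clusters[keep], removed_clusters = removed_clusters,
       n_removed = sum(!keep))
}

#' Naive doublet-score plumbing
#'
#' Stand-in scoring used when no external doublet caller output is
#' available: synthesises candidate doublet centroids by averaging random
#' cell pairs and scores each cell by its maximum Pearson correlation to a
#' centroid minus its correlation to its own cluster centroid. Intended for
#' plumbing and synthetic data only, not as a published-quality method.
#'
#' @param x Normalised log expression (cells x genes).
#' @param clusters Integer cluster id per cell.
#' @param n_candidates Number of synthetic doublet centroids.
#' @param seed Integer seed.
#' @return Numeric score per cell (higher = more doublet-like).
#' @export
doublet_score_fallback <- function(x, clusters, n_candidates = 200, seed = 1L) {
  x <- as_sparse(x)
  with_seed(seed, {
    cl_ids <- sort(unique(clusters))
    cent <- vapply(cl_ids, function(cl)
      colMeans(x[clusters == cl, , drop = FALSE]), numeric(ncol(x)))
    pairs <- matrix(sample.int(length(cl_ids), 2L * n_candidates, replace = TRUE),
                    ncol = 2L)
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs)) return(rep(0, nrow(x)))
    dc <- (cent[, pairs[, 1], drop = FALSE] + cent[, pairs[, 2], drop = FALSE]) / 2
    xd <- as.matrix(x)
    own <- cent[, match(clusters, cl_ids), drop = FALSE]
    cor_max <- apply(cor(t(xd), dc), 1L, max)
    cor_own <- diag(cor(t(xd), own))
    pmax(0, cor_max - cor_own + 0.5)
  })
}
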