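# Marker-based PCA analysis of a cell-type continuum (layer 2/3 style):
# per-condition PCA on a fixed marker feature set, eigenvector
# correspondence across conditions, per-cell marker scores and
# distribution comparisons along PC1.

#' Select one-vs-rest type markers and their union
#'
#' Per type, runs a one-vs-rest [de_test()] and keeps genes that are
#' upregulated in the type with fold change strictly above `min_fc`,
#' FDR < `alpha`, and expressed in more than `min_frac` of the type's
#' cells. The union over types is the fixed PCA feature set used for all
#' conditions.
#'
#' @param x Normalised log expression (cells x genes).
#' @param type_labels Type label per cell (>= 2 types).
#' @param min_fc Fold-change gate (ratio scale, strict).
#' @param min_frac Expression-fraction gate within the type.
#' @param alpha FDR level.
#' @return List: `markers` (named list of gene sets per type), `union`
#'   (ordered as in the matrix), `table` (the combined DE table).
#' @export
select_type_markers <- function(x, type_labels, min_fc = 1.5, min_frac = 0.2,
                                alpha = 0.05) {
  x <- as_sparse(x)
  types <- sort(unique(as.character(type_labels)))
  if (length(types) < 2) stopf("need at least 2 types")
  tabs <- list(); markers <- list()
  for (ty in types) {
    ia <- which(type_labels == ty); ib <- which(type_labels != ty)
    tab <- de_test(x, ia, ib, min_frac = min_frac, min_fc = min_fc,
                   alpha = alpha, group = ty,
                   contrast = sprintf("%s-vs-rest", ty))
    sel <- tab$log2fc > log2(min_fc) & tab$fdr < alpha &
      tab$frac_expr_a > min_frac
    markers[[ty]] <- tab$gene[sel]
    tabs[[ty]] <- tab
  }
  union_set <- colnames(x)[colnames(x) %in% unique(unlist(markers))]
  if (!length(union_set)) stopf("no markers found for any type")
  list(markers = markers, union = union_set, table = do.call(rbind, tabs))
}

#' PCA of one condition on a fixed marker feature set
#'
#' Centers (optionally scales) the feature submatrix and computes the full
#' eigen-decomposition; loadings are orthonormal with the sign fixed so the
#' largest-magnitude loading of each component is positive. Feature genes
#' missing from the matrix are zero-filled with a warning.
#'
#' @param x Normalised log expression of one condition (cells x genes).
#' @param feature_genes Ordered marker union (shared across conditions).
#' @param n_components Components to retain.
#' @param scale. Scale features to unit variance before PCA.
#' @return `embedding` object: `feature_genes`, `loadings` (features x k),
#'   `scores` (cells x k), `variance_fraction` (length k),
#'   `variance_fraction_all` (full spectrum, sums to 1).
#' @export
pca_condition <- function(x, feature_genes, n_components = 4, scale. = FALSE) {
  x <- as_sparse(x)
  if (n_components > nrow(x)) stopf("fewer cells than components")
  miss <- setdiff(feature_genes, colnames(x))
  if (length(miss)) {
    warnf("%d feature genes absent; zero-filled", length(miss))
    pad <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                        dims = c(nrow(x), length(miss)),
                        dimnames = list(rownames(x), miss))
    x <- cbind(x, pad)
  }
  xd <- as.matrix(x[, feature_genes, drop = FALSE])
  if (scale.) xd <- scale_clip(xd, clip = Inf)
  pc <- pca_eig(xd, n_components)
  vf <- pc$eigenvalues / sum(pc$eigenvalues)
  structure(list(feature_genes = feature_genes,
                 loadings = pc$loadings,
                 scores = pc$scores,
                 variance_fraction = vf[seq_len(ncol(pc$loadings))],
                 variance_fraction_all = vf,
                 scaled = scale.),
            class = "embedding")
}

#' Correspondence between principal eigenvectors of two embeddings
#'
#' Entry (i, j) is the absolute dot product of loading i of `e1` with
#' loading j of `e2` (equal to the correlation of centered loadings up to
#' centering). A 1:1 correspondence is flagged when rows and columns are
#' mutual best hits on the diagonal.
#'
#' @param e1,e2 `embedding` objects over identical feature sets.
#' @param n Number of components to compare.
#' @return `n x n` matrix of absolute dot products with attributes
#'   `one_to_one` (logical) and `pearson` (Pearson correlation of loadings).
#' @export
eigenvector_correspondence <- function(e1, e2, n = 2) {
  if (!identical(e1$feature_genes, e2$feature_genes))
    stopf("embeddings use different feature sets")
  n <- min(n, ncol(e1$loadings), ncol(e2$loadings))
  l1 <- e1$loadings[, seq_len(n), drop = FALSE]
  l2 <- e2$loadings[, seq_len(n), drop = FALSE]
  m <- abs(crossprod(l1, l2))
  dimnames(m) <- list(paste0("PC", seq_len(n)), paste0("PC", seq_len(n)))
  one_to_one <- all(apply(m, 1L, which.max) == seq_len(n)) &&
    all(apply(m, 2L, which.max) == seq_len(n))
  attr(m, "one_to_one") <- one_to_one
  attr(m, "pearson") <- abs(cor(l1, l2))
  m
}

#' Per-cell marker-set score
#'
#' The arithmetic mean of the set's expression values in each cell.
#'
#' @param x Normalised log expression (cells x genes).
#' @param gene_set Nonempty character vector of genes.
#' @return Numeric score per cell.
#' @export
marker_score <- function(x, gene_set) {
  if (!length(gene_set)) stopf("empty gene set")
  x <- as_sparse(x)
  if (!all(gene_set %in% colnames(x))) stopf("gene set not in matrix")
  rowMeans(x[, gene_set, drop = FALSE])
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param scores_a,scores_b Numeric samples (each of size >= 2).
#' @return List with `D` and `p` (two-sided).
#' @export
ks_compare <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stopf("need at least 2 observations per sample")
  kt <- suppressWarnings(ks.test(scores_a, scores_b, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Marker-score profiles along PC1 with cross-condition KS tests
#'
#' Orders cells by their PC1 coordinate within each condition, smooths each
#' marker score with a sliding-window mean, and KS-compares each score's
#' distribution between all condition pairs.
#'
#' @param scores Named list (or data.frame) of per-cell marker scores, e.g.,
#'   one [marker_score()] vector per type.
#' @param pc1 Per-cell PC1 coordinate.
#' @param condition_labels Condition per cell.
#' @param window_frac Sliding-window width as a fraction of cells (1 gives
#'   a constant curve at the global mean).
#' @return List: `curves` (condition, score set, PC1 order index, pc1,
#'   smoothed value), `ks` (score set, condition pair, D, p).
#' @export
pc1_profile <- function(scores, pc1, condition_labels, window_frac = 0.1) {
  scores <- as.data.frame(scores)
  stopifnot(nrow(scores) == length(pc1),
            length(pc1) == length(condition_labels))
  conds <- unique(condition_labels)
  curves <- list(); kss <- list()
  for (cc in conds) {
    in_c <- condition_labels == cc
    ord <- order(pc1[in_c])
    n <- sum(in_c)
    w <- max(1L, round(window_frac * n))
    for (sn in names(scores)) {
      v <- scores[[sn]][in_c][ord]
      sm <- sliding_mean(v, w)
      curves[[length(curves) + 1L]] <- data.frame(
        condition = cc, score = sn, rank = seq_len(n),
        pc1 = sort(pc1[in_c]), value = sm, stringsAsFactors = FALSE)
    }
  }
  if (length(conds) >= 2) {
    prs <- combn(conds, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      for (sn in names(scores)) {
        kt <- ks_compare(scores[[sn]][condition_labels == a],
                         scores[[sn]][condition_labels == b])
        kss[[length(kss) + 1L]] <- data.frame(
          score = sn, condition_a = a, condition_b = b,
          D = kt$D, p = kt$p, stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = do.call(rbind, curves),
       ks = if (length(kss)) do.call(rbind, kss) else NULL)
}

# Centered sliding-window mean with edge truncation; w = 1 returns the
# input, w >= n returns the global mean everywhere.
sliding_mean <- function(v, w) {
  n <- length(v)
  if (w >= n) return(rep(mean(v), n))
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + (w - 1L - half))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}
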