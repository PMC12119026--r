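# Differential expression: fold changes and Wilcoxon rank-sum tests.

resolve_cells <- function(x, cells) {
  if (is.logical(cells)) {
    stopifnot(length(cells) == nrow(x))
    which(cells)
  } else if (is.character(cells)) {
    idx <- match(cells, rownames(x))
    if (anyNA(idx)) stopf("unknown cell identifiers")
    idx
  } else as.integer(cells)
}

#' Per-gene log2 fold change between two cell groups
#'
#' Means are computed on the de-logged normalised scale (`expm1` of the
#' log1p-normalised values), so the fold change is a ratio of mean
#' normalised counts:
#' `log2((mean_a + pseudo) / (mean_b + pseudo))`.
#'
#' @param x Normalised log expression (cells x genes).
#' @param cells_a,cells_b Disjoint, nonempty cell index/name/logical vectors.
#' @param pseudo Pseudocount guarding against zero means.
#' @return Named numeric vector of per-gene log2 fold changes (a over b).
#' @export
fold_change <- function(x, cells_a, cells_b, pseudo = 1e-9) {
  x <- as_sparse(x)
  ia <- resolve_cells(x, cells_a); ib <- resolve_cells(x, cells_b)
  if (!length(ia) || !length(ib)) stopf("empty group")
  if (length(intersect(ia, ib))) stopf("groups must be disjoint")
  xe <- delog(x)
  ma <- colMeans(xe[ia, , drop = FALSE])
  mb <- colMeans(xe[ib, , drop = FALSE])
  setNames(log2((ma + pseudo) / (mb + pseudo)), colnames(x))
}

# Exact two-sided rank-sum p by exhausting all C(n, na) group assignments of
# the pooled values; p = P(|S - E| >= |S_obs - E|) under the permutation null.
rank_sum_exact <- function(va, vb) {
  pooled <- c(va, vb)
  n <- length(pooled); na <- length(va)
  r <- rank(pooled)
  s_obs <- sum(r[seq_len(na)])
  e <- na * (n + 1) / 2
  splits <- combn(n, na)
  s_all <- colSums(matrix(r[splits], nrow = na))
  mean(abs(s_all - e) >= abs(s_obs - e) - 1e-9)
}

# Normal approximation with mid-ranks, tie-corrected variance and continuity
# correction (matches the large-sample Wilcoxon convention).
rank_sum_normal <- function(r_a, n, na, tie_term) {
  nb <- n - na
  w <- sum(r_a)
  mu <- na * (n + 1) / 2
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(0, z)))
}

#' Two-sided Wilcoxon rank-sum test for one gene
#'
#' Uses exhaustive enumeration of rank splits when both groups have at most
#' `exact_max` observations (exact even under ties), otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param va,vb Numeric value vectors for the two groups.
#' @param exact_max Group-size bound for the exact path.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(va, vb, exact_max = 8L) {
  if (!length(va) || !length(vb)) stopf("empty group")
  if (length(va) <= exact_max && length(vb) <= exact_max)
    return(rank_sum_exact(va, vb))
  pooled <- c(va, vb)
  r <- rank(pooled)
  tt <- table(pooled)
  rank_sum_normal(r[seq_along(va)], length(pooled), length(va),
                  sum(tt^3 - tt))
}

#' Wilcoxon differential expression between two cell groups
#'
#' Candidate genes are those expressed (nonzero) in more than `min_frac` of
#' the cells of at least one group. Each candidate gets a two-sided rank-sum
#' p-value; Benjamini-Hochberg FDR is applied across candidates within the
#' contrast. A gene is flagged significant when its fold change exceeds
#' `min_fc` (as a ratio, either direction) and FDR < `alpha`.
#'
#' @param x Normalised log expression (cells x genes).
#' @param cells_a,cells_b Disjoint, nonempty cell selections.
#' @param min_frac Expression-fraction gate in (0, 1).
#' @param min_fc Fold-change gate (> 1, ratio scale).
#' @param alpha FDR significance level.
#' @param group,contrast Labels recorded in the output.
#' @param pseudo Pseudocount for [fold_change()].
#' @return data.frame (one row per candidate gene): `gene`, `group`,
#'   `contrast`, `log2fc`, `frac_expr_a`, `frac_expr_b`, `p`, `fdr`,
#'   `significant`, `direction`.
#' @export
de_test <- function(x, cells_a, cells_b, min_frac = 0.4, min_fc = 2,
                    alpha = 0.05, group = NA_character_,
                    contrast = "a-vs-b", pseudo = 1e-9) {
  stopifnot(min_frac > 0, min_frac < 1, min_fc > 1)
  x <- as_sparse(x)
  ia <- resolve_cells(x, cells_a); ib <- resolve_cells(x, cells_b)
  if (!length(ia) || !length(ib)) stopf("empty group")
  if (length(intersect(ia, ib))) stopf("groups must be disjoint")

  xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
  fa <- colSums(xa > 0) / length(ia)
  fb <- colSums(xb > 0) / length(ib)
  cand <- which(fa > min_frac | fb > min_frac)
  lfc <- fold_change(x, ia, ib, pseudo = pseudo)

  na <- length(ia); nb <- length(ib); n <- na + nb
  exact <- na <= 8L && nb <= 8L
  p <- vapply(cand, function(j) {
    va <- col_dense(xa, j); vb <- col_dense(xb, j)
    if (exact) return(rank_sum_exact(va, vb))
    pooled <- c(va, vb)
    r <- rank(pooled)
    tt <- tabulate(match(pooled, unique(pooled)))
    rank_sum_normal(r[seq_len(na)], n, na, sum(tt^3 - tt))
  }, numeric(1))

  fdr <- p.adjust(p, method = "BH")
  lfc_c <- lfc[cand]
  data.frame(
    gene = colnames(x)[cand],
    group = group,
    contrast = contrast,
    log2fc = unname(lfc_c),
    frac_expr_a = unname(fa[cand]),
    frac_expr_b = unname(fb[cand]),
    p = p,
    fdr = fdr,
    significant = abs(lfc_c) > log2(min_fc) & fdr < alpha,
    direction = ifelse(lfc_c >= 0, "up", "down"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
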