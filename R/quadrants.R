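# SV/tDE quadrant scoring, category enrichment, set intersections and
# cross-region overlap statistics.

#' One-vs-rest subclass marker table at each timepoint
#'
#' For every (subclass, timepoint) pair, tests the subclass's cells against
#' all other subclasses of the same timepoint with [de_test()]. The
#' resulting fold changes feed the SV score.
#'
#' @param x Normalised log expression (cells x genes).
#' @param subclass,timepoint Per-cell label vectors.
#' @param min_frac,min_fc,pseudo Passed to [de_test()].
#' @return A `DETable` data.frame with an extra `timepoint` column.
#' @export
subclass_markers_table <- function(x, subclass, timepoint, min_frac = 0.4,
                                   min_fc = 2, pseudo = 1e-9) {
  x <- as_sparse(x)
  stopifnot(length(subclass) == nrow(x), length(timepoint) == nrow(x))
  out <- list()
  for (tp in unique(timepoint)) {
    in_tp <- timepoint == tp
    for (s in unique(subclass[in_tp])) {
      ia <- which(in_tp & subclass == s)
      ib <- which(in_tp & subclass != s)
      if (!length(ia) || !length(ib)) next
      tab <- de_test(x, ia, ib, min_frac = min_frac, min_fc = min_fc,
                     group = s, contrast = sprintf("%s-vs-rest@%s", s, tp),
                     pseudo = pseudo)
      tab$timepoint <- tp
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}

#' Per-subclass temporal differential expression table
#'
#' For each subclass, tests the second timepoint against the first
#' (fold change = later over earlier). Feeds the tDE score.
#'
#' @inheritParams subclass_markers_table
#' @param timepoints Optional length-2 ordered timepoint pair; defaults to
#'   the sorted unique timepoints.
#' @return A `DETable` data.frame.
#' @export
temporal_table <- function(x, subclass, timepoint, timepoints = NULL,
                           min_frac = 0.4, min_fc = 2, pseudo = 1e-9) {
  x <- as_sparse(x)
  if (is.null(timepoints)) timepoints <- sort(unique(timepoint))
  if (length(timepoints) != 2) stopf("exactly two timepoints required")
  out <- list()
  for (s in unique(subclass)) {
    ia <- which(subclass == s & timepoint == timepoints[2])
    ib <- which(subclass == s & timepoint == timepoints[1])
    if (!length(ia) || !length(ib))
      stopf("subclass '%s' missing a timepoint", s)
    out[[length(out) + 1L]] <- de_test(
      x, ia, ib, min_frac = min_frac, min_fc = min_fc, group = s,
      contrast = sprintf("%s-vs-%s", timepoints[2], timepoints[1]),
      pseudo = pseudo)
  }
  do.call(rbind, out)
}

#' Subclass-variability (SV) score
#'
#' Per gene, the maximum absolute one-vs-rest log2 fold change over all
#' (subclass, timepoint) marker contrasts, capped at `cap`. Genes absent
#' from the marker table (failing the expression filter everywhere) get no
#' score.
#'
#' @param marker_table Output of [subclass_markers_table()].
#' @param cap Score cap (log2 units).
#' @return Named numeric vector of SV scores.
#' @export
sv_score <- function(marker_table, cap = 2) {
  if (is.null(marker_table$timepoint))
    stopf("marker table lacks a timepoint column")
  agg <- tapply(abs(marker_table$log2fc), marker_table$gene, max)
  agg <- agg[!is.na(agg)]
  setNames(pmin(as.numeric(agg), cap), names(agg))
}

#' Temporal differential-expression (tDE) score
#'
#' Per gene, the maximum absolute temporal log2 fold change over subclasses,
#' capped at `cap`.
#'
#' @param temporal_table Output of [temporal_table()].
#' @param cap Score cap (log2 units).
#' @return Named numeric vector of tDE scores.
#' @export
tde_score <- function(temporal_table, cap = 2) {
  agg <- tapply(abs(temporal_table$log2fc), temporal_table$gene, max)
  agg <- agg[!is.na(agg)]
  setNames(pmin(as.numeric(agg), cap), names(agg))
}

#' Assign SV/tDE quadrants
#'
#' Stratifies scored genes into four quadrants at a fold-change threshold
#' (internally `t = log2(fc_threshold)`): Q1 subclass-specific temporal
#' (`sv >= t, tde >= t`), Q2 global temporal (`sv < t, tde >= t`), Q3 static
#' non-specific (`sv < t, tde < t`), Q4 static identity (`sv >= t,
#' tde < t`). Genes scored on only one axis get 0 on the other.
#'
#' @param sv,tde Named score vectors from [sv_score()] / [tde_score()].
#' @param fc_threshold Threshold as a fold-change ratio.
#' @param class_context Optional label recorded in the output.
#' @return data.frame: `gene`, `sv_score`, `tde_score`, `quadrant`
#'   (and `class_context` if given).
#' @export
assign_quadrants <- function(sv, tde, fc_threshold = 2,
                             class_context = NA_character_) {
  t0 <- log2(fc_threshold)
  genes <- union(names(sv), names(tde))
  s <- ifelse(genes %in% names(sv), sv[genes], 0)
  d <- ifelse(genes %in% names(tde), tde[genes], 0)
  quadrant <- ifelse(s >= t0,
                     ifelse(d >= t0, "Q1", "Q4"),
                     ifelse(d >= t0, "Q2", "Q3"))
  out <- data.frame(gene = genes, sv_score = unname(s), tde_score = unname(d),
                    quadrant = quadrant, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.na(class_context)) out$class_context <- class_context
  out
}

#' Full quadrant scoring for one neuronal class
#'
#' Convenience wrapper: computes the marker and temporal tables, the SV and
#' tDE scores, and the quadrant assignment.
#'
#' @inheritParams subclass_markers_table
#' @param fc_threshold Quadrant threshold (ratio scale).
#' @param cap Score cap (log2 units).
#' @param class_context Optional class label for the output.
#' @return List: `quadrants` (data.frame), `sv`, `tde`, `marker_table`,
#'   `temporal_table`.
#' @export
score_quadrants <- function(x, subclass, timepoint, min_frac = 0.4,
                            min_fc = 2, fc_threshold = 2, cap = 2,
                            class_context = NA_character_) {
  mk <- subclass_markers_table(x, subclass, timepoint, min_frac = min_frac,
                               min_fc = min_fc)
  tm <- temporal_table(x, subclass, timepoint, min_frac = min_frac,
                       min_fc = min_fc)
  sv <- sv_score(mk, cap = cap)
  td <- tde_score(tm, cap = cap)
  list(quadrants = assign_quadrants(sv, td, fc_threshold = fc_threshold,
                                    class_context = class_context),
       sv = sv, tde = td, marker_table = mk, temporal_table = tm)
}

#' Gene-category enrichment per quadrant
#'
#' For every (quadrant, category) pair, builds the 2x2 table of quadrant
#' membership against category membership over the scored-gene universe,
#' computes the two-sided Fisher exact p-value and the sample odds ratio
#' `(a*d)/(b*c)` (Haldane 0.5 correction when exactly one cell is zero,
#' flagged), and Bonferroni-adjusts over all pairs. Calls: `enriched`
#' (p_adj <= alpha, OR > 1), `depleted` (p_adj <= alpha, OR < 1), otherwise
#' `neither`.
#'
#' @param quadrants Quadrant table from [assign_quadrants()].
#' @param categories data.frame with columns `gene`, `category`; genes
#'   outside the scored universe are dropped.
#' @param alpha Significance level on the adjusted p-value.
#' @return data.frame: `quadrant`, `category`, `a`..`d`, `odds_ratio`,
#'   `haldane`, `p`, `p_adj`, `call`.
#' @export
category_enrichment <- function(quadrants, categories, alpha = 0.05) {
  universe <- quadrants$gene
  categories <- categories[categories$gene %in% universe, , drop = FALSE]
  quads <- sort(unique(quadrants$quadrant))
  cats <- sort(unique(categories$category))
  n_tests <- length(quads) * length(cats)
  rows <- list()
  for (q in quads) {
    in_q <- universe %in% quadrants$gene[quadrants$quadrant == q]
    for (cc in cats) {
      in_c <- universe %in% categories$gene[categories$category == cc]
      a <- sum(in_q & in_c); b <- sum(in_q & !in_c)
      c0 <- sum(!in_q & in_c); d <- sum(!in_q & !in_c)
      p <- fisher.test(matrix(c(a, b, c0, d), 2, byrow = TRUE))$p.value
      haldane <- FALSE
      if (sum(c(a, b, c0, d) == 0) == 1) {
        or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c0 + 0.5))
        haldane <- TRUE
      } else if (b * c0 == 0 && a * d == 0) {
        or <- NaN
      } else if (b * c0 == 0) {
        or <- Inf
      } else {
        or <- (a * d) / (b * c0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        quadrant = q, category = cc, a = a, b = b, c = c0, d = d,
        odds_ratio = or, haldane = haldane, p = p,
        p_adj = min(1, p * n_tests), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$call <- ifelse(out$p_adj > alpha, "neither",
                     ifelse(is.nan(out$odds_ratio), "neither",
                            ifelse(out$odds_ratio > 1, "enriched",
                                   ifelse(out$odds_ratio < 1, "depleted",
                                          "neither"))))
  out
}

#' Exclusive set-intersection summary of significant genes
#'
#' Counts, per regulation direction, how many significant genes fall in each
#' exclusive subclass combination (every gene counted exactly once, in the
#' combination of all subclasses where it is significant). Combinations
#' below `min_set` are suppressed from the display table but retained in the
#' totals.
#'
#' @param de A `DETable` (possibly rbind-ed over subclasses) with columns
#'   `gene`, `group`, `significant`, `direction`.
#' @param min_set Minimum combination size shown.
#' @return List: `counts` (direction, combination, n, shown), `totals`
#'   (per direction), `fraction_specific` (significant genes exclusive to a
#'   single subclass), `down_up_ratio`.
#' @export
intersection_summary <- function(de, min_set = 4) {
  sig <- de[de$significant, , drop = FALSE]
  rows <- list()
  n_spec <- 0L; n_tot <- 0L
  for (dir in c("down", "up")) {
    dd <- sig[sig$direction == dir, , drop = FALSE]
    if (!nrow(dd)) next
    combo <- tapply(dd$group, dd$gene, function(g) paste(sort(unique(g)), collapse = "+"))
    tab <- table(combo)
    n_tot <- n_tot + length(combo)
    n_spec <- n_spec + sum(!grepl("\\+", combo))
    rows[[dir]] <- data.frame(direction = dir, combination = names(tab),
                              n = as.integer(tab),
                              shown = as.integer(tab) >= min_set,
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  totals <- c(down = sum(sig$direction == "down"),
              up = sum(sig$direction == "up"))
  list(counts = counts,
       totals = totals,
       fraction_specific = if (n_tot > 0) n_spec / n_tot else NA_real_,
       down_up_ratio = if (totals["up"] > 0) unname(totals["down"] / totals["up"]) else NA_real_)
}

#' Hypergeometric overlap of two gene lists
#'
#' Upper-tail hypergeometric test of the overlap `k` between `list1`
#' (`K` genes) and `list2` (`n` genes) drawn from a universe of `N` genes:
#' `p = P(X >= k)`, Bonferroni-multiplied by `n_tests`.
#'
#' @param list1,list2 Gene sets (subsets of `universe`).
#' @param universe Background gene set.
#' @param n_tests Bonferroni factor (e.g., number of subclasses tested).
#' @return One-row data.frame: `N`, `K`, `n`, `k`, `p`, `p_adj`.
#' @export
hypergeom_overlap <- function(list1, list2, universe, n_tests = 1) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  list1 <- unique(list1); list2 <- unique(list2)
  if (!all(list1 %in% universe) || !all(list2 %in% universe))
    stopf("gene lists must be subsets of the universe")
  N <- length(universe); K <- length(list1); n <- length(list2)
  k <- length(intersect(list1, list2))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(N = N, K = K, n = n, k = k, p = p,
             p_adj = min(1, p * n_tests))
}
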