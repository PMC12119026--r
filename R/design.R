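#' Construct a simulation design with planted ground truth
#'
#' Defines the generative model for a synthetic single-nucleus RNA-seq
#' experiment: a hierarchy of classes, subclasses and types observed across
#' timepoints and perturbation conditions, with planted gene programs
#' (subclass markers, type markers, subclass-specific and global temporal
#' programs, immediate-early-gene induction, perturbation responses), a
#' three-type continuum subclass with a compositional shift between
#' timepoints, and doublet / low-quality / high-mitochondrial artifacts.
#'
#' Counts are drawn gene-wise from a negative-binomial (Gamma-Poisson) model
#' with mean `baseline * 2^(sum of applicable planted log2 effects) * size
#' factor`; library sizes are log-normal. The default taxonomy has 12
#' subclasses (8 glutamatergic, 4 GABAergic) comprising 45 types, observed at
#' two ages (`T1`, `T2`) plus two `T2` perturbation conditions, mirroring a
#' developmental whisker-deprivation design.
#'
#' @param subclasses Character vector of subclass names.
#' @param class_of_subclass Character vector (same length) assigning each
#'   subclass to `"glutamatergic"` or `"GABAergic"`.
#' @param types_per_subclass Integer vector: number of types per subclass.
#' @param conditions Ordered character vector of condition labels.
#' @param timepoint_of_condition Character vector mapping each condition to a
#'   timepoint label; temporal programs act on timepoints, perturbation
#'   programs on individual conditions.
#' @param cells_per_type Integer scalar or types x conditions matrix of
#'   singlet cell numbers. For the continuum subclass the per-condition
#'   totals are reallocated across its three types by `composition`.
#' @param n_genes,n_mito_genes Total genes and mitochondrial genes.
#' @param programs Planted-effect table; see [default_gene_programs()]. Rows
#'   with `NA` subclass/type/timepoint/condition apply to all.
#' @param baseline Optional per-gene relative baseline expression; drawn
#'   log-normally when `NULL`.
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2), scalar or per gene.
#' @param library_size_lognormal Length-2 `(meanlog, sdlog)` of the singlet
#'   library-size distribution.
#' @param mito_fraction Expected mitochondrial fraction for healthy cells.
#' @param continuum_subclass Name of the subclass simulated as a three-type
#'   continuum, or `NA` for none.
#' @param composition 3 x conditions matrix of type frequencies for the
#'   continuum subclass (columns sum to 1). Default halves type A and
#'   doubles type B between `T1` and the `T2` conditions.
#' @param continuum_shapes 3 x 2 matrix of Beta shapes placing the three
#'   types along the latent coordinate.
#' @param doublet_rate,lowq_rate,highmito_rate Artifact fractions (of the
#'   singlet count per condition).
#' @param highmito_range Range of per-cell mitochondrial fractions for the
#'   planted high-mito population.
#' @param n_replicates Biological replicates per condition.
#' @param seed Integer seed; a fixed seed makes [simulate_counts()] output
#'   byte-identical.
#'
#' @return An object of class `sim_design`.
#' @seealso [simulate_counts()], [default_gene_programs()]
#' @export
sim_design <- function(subclasses = NULL,
                       class_of_subclass = NULL,
                       types_per_subclass = NULL,
                       conditions = c("T1", "T2", "T2_pertA", "T2_pertB"),
                       timepoint_of_condition = c("T1", "T2", "T2", "T2"),
                       cells_per_type = 30,
                       n_genes = 2000,
                       n_mito_genes = 13,
                       programs = NULL,
                       baseline = NULL,
                       dispersion = 0.5,
                       library_size_lognormal = c(meanlog = log(3000), sdlog = 0.35),
                       mito_fraction = 0.05,
                       continuum_subclass = "L23",
                       composition = NULL,
                       continuum_shapes = rbind(A = c(2, 14), B = c(10, 10), C = c(14, 2)),
                       doublet_rate = 0.05,
                       lowq_rate = 0.03,
                       highmito_rate = 0.03,
                       highmito_range = c(0.2, 0.4),
                       n_replicates = 2,
                       seed = 1L) {
  if (is.null(subclasses)) {
    subclasses <- c("L23", "L4", "L5IT", "L5PT", "L5NP", "L6CT", "L6IT", "L6b",
                    "Pvalb", "Sst", "Vip", "Lamp5")
    class_of_subclass <- rep(c("glutamatergic", "GABAergic"), c(8, 4))
    types_per_subclass <- c(3, 4, 4, 4, 3, 4, 4, 3, 5, 5, 3, 3)
  }
  check_ids(subclasses, "subclass")
  if (is.null(class_of_subclass)) class_of_subclass <- rep("glutamatergic", length(subclasses))
  if (is.null(types_per_subclass)) types_per_subclass <- rep(3L, length(subclasses))
  stopifnot(length(class_of_subclass) == length(subclasses),
            length(types_per_subclass) == length(subclasses))
  if (anyDuplicated(conditions)) stopf("condition labels not unique")
  if (length(timepoint_of_condition) != length(conditions))
    stopf("timepoint_of_condition must match conditions")
  names(timepoint_of_condition) <- conditions
  if (any(dispersion <= 0)) stopf("dispersion must be positive")
  if (!is.na(continuum_subclass)) {
    if (!continuum_subclass %in% subclasses)
      stopf("continuum subclass '%s' not in subclasses", continuum_subclass)
    if (types_per_subclass[match(continuum_subclass, subclasses)] != 3L)
      stopf("continuum subclass must have exactly 3 types")
  }

  types <- data.frame(
    type = unlist(mapply(function(s, k) paste(s, LETTERS[seq_len(k)], sep = "_"),
                         subclasses, types_per_subclass, SIMPLIFY = FALSE)),
    subclass = rep(subclasses, types_per_subclass),
    stringsAsFactors = FALSE
  )
  n_types <- nrow(types)

  if (is.matrix(cells_per_type)) {
    stopifnot(nrow(cells_per_type) == n_types, ncol(cells_per_type) == length(conditions))
    cells <- cells_per_type
  } else {
    cells <- matrix(as.integer(cells_per_type), n_types, length(conditions))
  }
  if (any(cells < 0)) stopf("cells_per_type entries must be >= 0")
  dimnames(cells) <- list(types$type, conditions)

  if (is.null(composition) && !is.na(continuum_subclass)) {
    composition <- vapply(conditions, function(cc) {
      if (timepoint_of_condition[[cc]] == timepoint_of_condition[[conditions[1]]])
        c(0.40, 0.25, 0.35) else c(0.20, 0.50, 0.30)
    }, numeric(3))
    rownames(composition) <- types$type[types$subclass == continuum_subclass]
  }
  if (!is.na(continuum_subclass)) {
    if (any(abs(colSums(composition) - 1) > 1e-9))
      stopf("composition columns must sum to 1")
    # Reallocate the continuum subclass's per-condition totals by composition.
    rows <- which(types$subclass == continuum_subclass)
    for (j in seq_along(conditions)) {
      tot <- sum(cells[rows, j])
      cells[rows, j] <- round_to_total(composition[, j], tot)
    }
  }

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (n_mito_genes > 0)
    gene_ids[(n_genes - n_mito_genes + 1L):n_genes] <-
      sprintf("mt-g%02d", seq_len(n_mito_genes))
  is_mito <- grepl("^mt-", gene_ids)

  if (is.null(programs)) {
    n_usable <- n_genes - n_mito_genes
    base_sizes <- c(marker = 20, q1 = 10, type = 8, q2 = 60, hk = 100,
                    ieg = 15, pert = 10)
    need <- length(subclasses) * (base_sizes["marker"] + base_sizes["q1"]) +
      nrow(types) * base_sizes["type"] + sum(base_sizes[c("q2", "hk", "ieg", "pert")])
    sc <- min(1, 0.8 * n_usable / need)
    sz <- pmax(floor(base_sizes * sc), 1)
    programs <- default_gene_programs(
      n_usable, subclasses, types, conditions, timepoint_of_condition,
      continuum_subclass,
      n_marker_per_subclass = sz[["marker"]], n_type_marker = sz[["type"]],
      n_q1_per_subclass = sz[["q1"]], n_q2 = sz[["q2"]], n_hk = sz[["hk"]],
      n_ieg = sz[["ieg"]], n_pert = sz[["pert"]], seed = seed)
  }
  stopifnot(all(c("gene", "program", "subclass", "type", "timepoint",
                  "condition", "log2fc", "quadrant") %in% names(programs)))
  if (any(!is.finite(programs$log2fc))) stopf("planted effects must be finite")
  if (any(programs$gene > n_genes - n_mito_genes))
    stopf("programs may not target mitochondrial genes")

  if (is.null(baseline)) {
    baseline <- with_seed(seed + 101L, {
      b <- rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
      # program genes get a detectability floor so planted effects are
      # measurable above the expression filter
      prog <- unique(programs$gene)
      b[prog] <- pmax(b[prog], rlnorm(length(prog), meanlog = 1.6, sdlog = 0.4))
      b
    })
  }
  stopifnot(length(baseline) == n_genes, all(baseline > 0))
  # fix the mitochondrial mass at the designed fraction of total baseline
  if (n_mito_genes > 0) {
    tot <- sum(baseline[!is_mito])
    baseline[is_mito] <- mito_fraction / (1 - mito_fraction) * tot / n_mito_genes
  }

  design <- structure(list(
    subclasses = subclasses,
    class_of_subclass = setNames(class_of_subclass, subclasses),
    types = types,
    conditions = conditions,
    timepoint_of_condition = timepoint_of_condition,
    cells_per_type = cells,
    n_genes = n_genes,
    n_mito_genes = n_mito_genes,
    gene_ids = gene_ids,
    is_mito = is_mito,
    programs = programs,
    baseline = baseline,
    dispersion = rep_len(dispersion, n_genes),
    library_size_lognormal = library_size_lognormal,
    mito_fraction = mito_fraction,
    continuum_subclass = continuum_subclass,
    composition = if (is.na(continuum_subclass)) NULL else composition,
    continuum_shapes = continuum_shapes,
    doublet_rate = doublet_rate,
    lowq_rate = lowq_rate,
    highmito_rate = highmito_rate,
    highmito_range = highmito_range,
    n_replicates = n_replicates,
    seed = as.integer(seed)
  ), class = "sim_design")
  design
}

#' Default planted gene-program table
#'
#' Builds a disjoint assignment of genes to planted programs. Quadrant truth
#' labels follow the SV/tDE plane: subclass-restricted temporal programs are
#' Q1, global temporal programs Q2, static subclass and type markers Q4, and
#' everything else (housekeeping, immediate-early genes, perturbation
#' responses, unprogrammed genes) Q3 with respect to the two control
#' timepoints.
#'
#' @param n_usable Number of non-mitochondrial genes available.
#' @param subclasses,types,conditions,timepoint_of_condition Taxonomy pieces
#'   as in [sim_design()].
#' @param continuum_subclass Continuum subclass name or `NA`.
#' @param n_marker_per_subclass,n_type_marker,n_q1_per_subclass,n_q2,n_hk,n_ieg,n_pert
#'   Program sizes.
#' @param effect_range Magnitude range (log2 units) for planted effects.
#' @param seed Integer seed for effect-size draws.
#' @return A data.frame with one row per (gene, effect context).
#' @export
default_gene_programs <- function(n_usable, subclasses, types, conditions,
                                  timepoint_of_condition,
                                  continuum_subclass = NA,
                                  n_marker_per_subclass = 20,
                                  n_type_marker = 8,
                                  n_q1_per_subclass = 10,
                                  n_q2 = 60,
                                  n_hk = 100,
                                  n_ieg = 15,
                                  n_pert = 10,
                                  effect_range = c(1.5, 3),
                                  seed = 1L) {
  tps <- unique(timepoint_of_condition)
  t2 <- if (length(tps) > 1) tps[2] else tps[1]
  pertA <- conditions[!timepoint_of_condition %in% tps[1]][-1][1]  # first perturbed condition
  pertB <- if (length(conditions) >= 4) conditions[4] else NA
  with_seed(seed + 7L, {
    nxt <- 0L
    take <- function(k) {
      if (nxt + k > n_usable) stopf("not enough genes for the default programs")
      g <- nxt + seq_len(k); nxt <<- nxt + k; g
    }
    eff <- function(k, signed = FALSE) {
      e <- runif(k, effect_range[1], effect_range[2])
      if (signed) e <- e * sample(c(-1, 1), k, replace = TRUE)
      e
    }
    rows <- list()
    add <- function(gene, program, subclass = NA, type = NA, timepoint = NA,
                    condition = NA, log2fc, quadrant) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, program = program, subclass = subclass, type = type,
        timepoint = timepoint, condition = condition, log2fc = log2fc,
        quadrant = quadrant, stringsAsFactors = FALSE)
    }
    for (s in subclasses) {
      add(take(n_marker_per_subclass), "subclass_marker", subclass = s,
          log2fc = eff(n_marker_per_subclass), quadrant = "Q4")
      add(take(n_q1_per_subclass), "temporal_subclass", subclass = s,
          timepoint = t2, log2fc = eff(n_q1_per_subclass, signed = TRUE),
          quadrant = "Q1")
    }
    for (i in seq_len(nrow(types)))
      add(take(n_type_marker), "type_marker", subclass = types$subclass[i],
          type = types$type[i], log2fc = eff(n_type_marker), quadrant = "Q4")
    add(take(n_q2), "temporal_global", timepoint = t2,
        log2fc = eff(n_q2, signed = TRUE), quadrant = "Q2")
    add(take(n_hk), "housekeeping", log2fc = 0, quadrant = "Q3")
    if (!is.na(pertA) && n_ieg > 0)
      add(take(n_ieg), "ieg", condition = pertA,
          log2fc = runif(n_ieg, 1.5, 2.5), quadrant = "Q3")
    if (!is.na(pertB) && n_pert > 0)
      add(take(n_pert), "pert", subclass = subclasses[min(2, length(subclasses))],
          condition = pertB, log2fc = eff(n_pert, signed = TRUE), quadrant = "Q3")
    do.call(rbind, rows)
  })
}

# Deterministic largest-remainder allocation of n into proportions p.
round_to_total <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design: %d subclasses / %d types, %d conditions, %d genes (%d mito)\n",
              length(x$subclasses), nrow(x$types), length(x$conditions),
              x$n_genes, x$n_mito_genes))
  cat(sprintf("  singlet cells: %d; programs: %d planted effects; seed %d\n",
              sum(x$cells_per_type), nrow(x$programs), x$seed))
  invisible(x)
}
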