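# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small full-featured simulation: default taxonomy at miniature scale.
fix_small <- function() cached("small", function() {
  design <- sim_design(cells_per_type = 12, n_genes = 600, seed = 101)
  c(list(design = design), simulate_counts(design))
})

# Flat fixture: k subclasses, one type each, two timepoints, no artifacts.
fix_flat <- function(k = 4, cells = 80, genes = 800, seed = 202) {
  key <- sprintf("flat_%d_%d_%d_%d", k, cells, genes, seed)
  cached(key, function() {
    design <- sim_design(
      subclasses = sprintf("SC%02d", seq_len(k)),
      class_of_subclass = rep("glutamatergic", k),
      types_per_subclass = rep(1L, k),
      conditions = c("T1", "T2"), timepoint_of_condition = c("T1", "T2"),
      cells_per_type = cells, n_genes = genes, continuum_subclass = NA,
      doublet_rate = 0, lowq_rate = 0, highmito_rate = 0, seed = seed)
    sim <- simulate_counts(design)
    c(list(design = design, x = normalize_log(sim$counts)), sim)
  })
}

# Continuum fixture: a 3-type continuum subclass plus stable subclasses,
# with the compositional shift between T1 and T2.
fix_continuum <- function(cells_continuum = 300, cells_stable = 150,
                          genes = 800, seed = 303) {
  key <- sprintf("cont_%d_%d_%d_%d", cells_continuum, cells_stable, genes, seed)
  cached(key, function() {
    k <- 4
    cpt <- matrix(cells_stable, 3 + (k - 1) * 2, 2)
    cpt[1:3, ] <- cells_continuum  # continuum rows reallocated by composition
    design <- sim_design(
      subclasses = c("L23", sprintf("ST%d", seq_len(k - 1))),
      class_of_subclass = rep("glutamatergic", k),
      types_per_subclass = c(3L, rep(2L, k - 1)),
      conditions = c("T1", "T2"), timepoint_of_condition = c("T1", "T2"),
      cells_per_type = cpt, n_genes = genes, continuum_subclass = "L23",
      doublet_rate = 0, lowq_rate = 0, highmito_rate = 0, seed = seed)
    sim <- simulate_counts(design)
    c(list(design = design, x = normalize_log(sim$counts)), sim)
  })
}

# Hand-built tiny count matrix with exact values.
toy_counts <- function(values, cells = NULL, genes = NULL) {
  m <- as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  rownames(m) <- cells %||% sprintf("cell%d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
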