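# End-to-end orchestration: synthesize -> QC -> quadrants -> label transfer
# -> continuum PCA -> cross-region overlap, with a machine-readable manifest
# and summary report.

default_config <- function() {
  list(
    output_dir = "cortexdev_run",
    seed = 1L,
    simulate = list(cells_per_type = 20, n_genes = 1000, n_mito_genes = 13,
                    doublet_rate = 0.05, lowq_rate = 0.03, highmito_rate = 0.03),
    qc = list(max_genes = 7000, max_counts = 40000, min_counts = 500,
              min_cells_per_gene = 20, mito_cluster_threshold = 0.2,
              doublet_score_max = 0.5, n_hvg = 500, n_pcs = 20,
              k_neighbors = 15, resolution = 1.0, target_sum = 1e4),
    quadrants = list(fc_threshold = 2, cap = 2, min_frac = 0.4, min_fc = 2,
                     exclude_replicates = character()),
    map = list(frac = 0.7, cap = 1000, min_train = 100, reject_factor = 1.2,
               nrounds = 20),
    l23 = list(min_fc = 1.5, min_frac = 0.2, n_components = 4,
               window_frac = 0.1),
    overlap = list(enabled = TRUE, n_tests = NULL)
  )
}

validate_config <- function(cfg) {
  qc <- cfg$qc
  if (!is.null(qc$min_counts) && !is.null(qc$max_counts) &&
      qc$min_counts >= qc$max_counts)
    stopf("config error at qc.min_counts / qc.max_counts: min_counts (%s) must be below max_counts (%s)",
          qc$min_counts, qc$max_counts)
  num_fields <- list(c("qc", "max_genes"), c("qc", "max_counts"),
                     c("qc", "min_counts"), c("quadrants", "fc_threshold"),
                     c("quadrants", "cap"), c("map", "reject_factor"))
  for (f in num_fields) {
    v <- cfg[[f[1]]][[f[2]]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0))
      stopf("config error at %s.%s: expected a positive number", f[1], f[2])
  }
  invisible(cfg)
}

merge_config <- function(user, defaults = default_config()) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-data generation, QC (cell/gene filters,
#' normalisation, clustering, mitochondrial-cluster removal, doublet-score
#' filter), SV/tDE quadrant scoring with category enrichment, classifier
#' label transfer with held-out validation and frequency concordance,
#' continuum-subclass PCA profiling, and a cross-region temporal-overlap
#' analysis against a second simulated region. Every stage writes TSV/JSON
#' outputs under `output_dir`, and a manifest records all thresholds,
#' seeds, per-stage counts and output hashes. A stage failure is recorded
#' in the manifest and later stages are skipped.
#'
#' @param config Path to a YAML config file, or a config list. Missing
#'   fields fall back to defaults.
#' @return The run manifest (list), invisibly. Also written as
#'   `manifest.json` in `output_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(merge_config(config))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  manifest <- list(package_version = as.character(utils::packageVersion("cortexdev")),
                   config = cfg, stages = list(), errors = list())
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (length(manifest$errors)) return(invisible(NULL))
    rec <- tryCatch(fn(), error = function(e) e)
    if (inherits(rec, "error")) {
      manifest$errors[[name]] <<- conditionMessage(rec)
    } else {
      rec$outputs <- stage_hashes(out, rec$files %||% character())
      manifest$stages[[name]] <<- rec
    }
    save_manifest()
  }

  run_stage("simulate", function() {
    design <- do.call(sim_design, c(cfg$simulate, list(seed = seed)))
    sim <- simulate_counts(design)
    write_fixture(sim$counts, sim$meta, sim$truth,
                  file.path(out, "sim"), overwrite = TRUE)
    state$sim <- sim; state$design <- design
    list(n_cells = nrow(sim$counts), n_genes = ncol(sim$counts),
         seed = seed, files = "sim")
  })

  run_stage("qc", function() {
    qc <- cfg$qc
    sim <- state$sim
    meta <- cell_qc_stats(sim$counts, sim$meta)
    f1 <- filter_cells(sim$counts, meta, max_genes = qc$max_genes,
                       max_counts = qc$max_counts, min_counts = qc$min_counts)
    n_after_cells <- nrow(f1$counts)
    cc <- filter_genes(f1$counts, min_cells = qc$min_cells_per_gene)
    xn <- normalize_log(cc, target_sum = qc$target_sum)
    cl <- cluster_pipeline(xn, n_hvg = qc$n_hvg, n_pcs = qc$n_pcs,
                           k_neighbors = qc$k_neighbors,
                           resolution = qc$resolution, seed = seed)
    f2 <- remove_mito_clusters(cc, f1$meta[, names(f1$meta) != "cluster"],
                               cl, mito_threshold = qc$mito_cluster_threshold)
    keep_db <- f2$meta$doublet_score < qc$doublet_score_max
    counts <- f2$counts[keep_db, , drop = FALSE]
    meta <- f2$meta[keep_db, , drop = FALSE]
    meta$cluster <- f2$clusters[keep_db]
    x <- normalize_log(counts, target_sum = qc$target_sum)
    truth <- state$sim$truth$cells
    meta <- cbind(meta, truth[match(meta$barcode, truth$barcode),
                              c("class", "subclass", "type", "is_doublet",
                                "is_lowq", "is_highmito")])
    tsv_write(meta, file.path(out, "cells_qc.tsv"))
    state$x <- x; state$meta <- meta; state$counts <- counts
    list(n_input = nrow(sim$counts), n_after_cell_filter = n_after_cells,
         n_genes_kept = ncol(cc), removed_mito_clusters = f2$removed_clusters,
         n_final = nrow(counts), thresholds = qc, files = "cells_qc.tsv")
  })

  run_stage("quadrants", function() {
    qd <- cfg$quadrants
    meta <- state$meta
    # quadrants use the two control conditions only; low-depth replicates
    # can be blacklisted from DE without touching other stages
    ctrl <- !is.na(meta$subclass) & !meta$is_doublet &
      meta$condition %in% state$design$conditions[1:2] &
      !(meta$replicate %in% (qd$exclude_replicates %||% character()))
    sq <- score_quadrants(state$x[ctrl, , drop = FALSE],
                          meta$subclass[ctrl], meta$timepoint[ctrl],
                          min_frac = qd$min_frac, min_fc = qd$min_fc,
                          fc_threshold = qd$fc_threshold, cap = qd$cap)
    tsv_write(sq$quadrants, file.path(out, "quadrants.tsv"))
    genes_truth <- state$sim$truth$genes
    cats <- genes_truth[genes_truth$program %in% c("housekeeping", "ieg"),
                        c("gene", "program")]
    names(cats) <- c("gene", "category")
    enr <- if (nrow(cats)) category_enrichment(sq$quadrants, cats) else NULL
    if (!is.null(enr)) tsv_write(enr, file.path(out, "enrichment.tsv"))
    state$quadrants <- sq
    list(n_scored = nrow(sq$quadrants),
         quadrant_sizes = as.list(table(sq$quadrants$quadrant)),
         files = c("quadrants.tsv", if (!is.null(enr)) "enrichment.tsv"))
  })

  run_stage("map", function() {
    mp <- cfg$map
    meta <- state$meta
    ref_cond <- state$design$conditions[2]
    ref <- which(meta$condition == ref_cond & !is.na(meta$subclass))
    labs <- meta$subclass[ref]
    sp <- split_train_validation(labs, frac = mp$frac, cap = mp$cap,
                                 min_train = mp$min_train, seed = seed)
    model <- train_mapper(state$x[ref, , drop = FALSE], labs,
                          rows = sp$train, nrounds = mp$nrounds, seed = seed)
    heldout <- predict_labels(model, state$x[ref[sp$heldout], , drop = FALSE],
                              reject_factor = mp$reject_factor)
    acc <- mean(heldout$assigned == labs[sp$heldout])
    preds <- list()
    for (cond in setdiff(state$design$conditions, ref_cond)) {
      idx <- which(meta$condition == cond & !is.na(meta$subclass))
      if (!length(idx)) next
      pr <- predict_labels(model, state$x[idx, , drop = FALSE],
                           reject_factor = mp$reject_factor)
      fc <- frequency_concordance(labs, pr$assigned[pr$assigned != "Unassigned"])
      preds[[cond]] <- list(n = length(idx),
                            unassigned = mean(pr$assigned == "Unassigned"),
                            pearson = fc$pearson)
      tsv_write(data.frame(barcode = meta$barcode[idx],
                           assigned = pr$assigned, max_prob = pr$max_prob),
                file.path(out, sprintf("mapping_%s.tsv", cond)))
    }
    state$mapping_accuracy <- acc
    list(reference = ref_cond, heldout_accuracy = acc, conditions = preds,
         files = grep("^mapping_", list.files(out), value = TRUE))
  })

  run_stage("l23", function() {
    l2 <- cfg$l23
    meta <- state$meta
    contsc <- state$design$continuum_subclass
    if (is.na(contsc)) return(list(skipped = "no continuum subclass"))
    ref_cond <- state$design$conditions[2]
    in_ref <- which(meta$condition == ref_cond & !is.na(meta$subclass) &
                      meta$subclass == contsc)
    mk <- select_type_markers(state$x[in_ref, , drop = FALSE],
                              meta$type[in_ref], min_fc = l2$min_fc,
                              min_frac = l2$min_frac)
    conds <- state$design$conditions[1:2]
    embs <- list(); profiles <- list()
    for (cond in conds) {
      idx <- which(meta$condition == cond & !is.na(meta$subclass) &
                     meta$subclass == contsc)
      emb <- pca_condition(state$x[idx, , drop = FALSE], mk$union,
                           n_components = l2$n_components)
      embs[[cond]] <- emb
    }
    corr <- eigenvector_correspondence(embs[[1]], embs[[2]], n = 2)
    idx_all <- which(!is.na(meta$subclass) & meta$subclass == contsc &
                       meta$condition %in% conds)
    sc <- lapply(mk$markers, function(g)
      if (length(g)) marker_score(state$x[idx_all, , drop = FALSE], g) else NULL)
    sc <- sc[!vapply(sc, is.null, logical(1))]
    emb_all <- pca_condition(state$x[idx_all, , drop = FALSE], mk$union,
                             n_components = 2)
    prof <- pc1_profile(sc, emb_all$scores[, 1], meta$condition[idx_all],
                        window_frac = l2$window_frac)
    tsv_write(prof$ks, file.path(out, "l23_ks.tsv"))
    tsv_write(data.frame(component = seq_along(embs[[1]]$variance_fraction),
                         variance_fraction = embs[[1]]$variance_fraction),
              file.path(out, "l23_variance.tsv"))
    list(n_markers = length(mk$union),
         correspondence_diag = as.numeric(diag(corr)),
         one_to_one = attr(corr, "one_to_one"),
         ks_min_p = min(prof$ks$p),
         files = c("l23_ks.tsv", "l23_variance.tsv"))
  })

  run_stage("overlap", function() {
    ov <- cfg$overlap
    if (!isTRUE(ov$enabled)) return(list(skipped = "disabled"))
    meta <- state$meta
    # second region: independent draw from the same generative design
    design2 <- state$design; design2$seed <- seed + 1000L
    sim2 <- simulate_counts(design2)
    m2 <- cell_qc_stats(sim2$counts, sim2$meta)
    f2 <- filter_cells(sim2$counts, m2, max_genes = cfg$qc$max_genes,
                       max_counts = cfg$qc$max_counts,
                       min_counts = cfg$qc$min_counts)
    x2 <- normalize_log(filter_genes(f2$counts, cfg$qc$min_cells_per_gene))
    t2 <- sim2$truth$cells[match(f2$meta$barcode, sim2$truth$cells$barcode), ]
    ok2 <- !is.na(t2$subclass) & f2$meta$condition %in% state$design$conditions[1:2]
    tt2 <- temporal_table(x2[ok2, , drop = FALSE], t2$subclass[ok2],
                          f2$meta$timepoint[ok2],
                          min_frac = cfg$quadrants$min_frac,
                          min_fc = cfg$quadrants$min_fc)
    tt1 <- state$quadrants$temporal_table
    subclasses <- intersect(unique(tt1$group), unique(tt2$group))
    n_tests <- ov$n_tests %||% length(subclasses)
    rows <- list()
    for (dir in c("down", "up")) {
      universe <- union(tt1$gene[tt1$significant & tt1$direction == dir],
                        tt2$gene[tt2$significant & tt2$direction == dir])
      if (!length(universe)) next
      for (s in subclasses) {
        l1 <- intersect(tt1$gene[tt1$group == s & tt1$significant &
                                   tt1$direction == dir], universe)
        l2g <- intersect(tt2$gene[tt2$group == s & tt2$significant &
                                    tt2$direction == dir], universe)
        r <- hypergeom_overlap(l1, l2g, universe, n_tests = n_tests)
        r$subclass <- s; r$direction <- dir
        rows[[length(rows) + 1L]] <- r
      }
    }
    res <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(res)) tsv_write(res, file.path(out, "overlap.tsv"))
    list(n_subclasses = length(subclasses), n_tests = n_tests,
         files = if (!is.null(res)) "overlap.tsv")
  })

  save_manifest()
  invisible(manifest)
}

stage_hashes <- function(out, files) {
  if (!length(files)) return(NULL)
  paths <- file.path(out, files)
  hashes <- list()
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (dir.exists(p)) {
      fs <- list.files(p, full.names = TRUE)
      hashes[[files[i]]] <- unname(tools::md5sum(fs))
    } else if (file.exists(p)) {
      hashes[[files[i]]] <- unname(tools::md5sum(p))
    }
  }
  hashes
}

#' Aggregate pipeline outputs into a JSON summary
#'
#' Reads the manifest and stage TSVs from a [run_pipeline()] output
#' directory and writes `report.json` with per-stage counts, quadrant
#' sizes, enrichment calls, mapping accuracy and KS results. Missing stage
#' outputs are listed under `incomplete`.
#'
#' @param dir Pipeline output directory.
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json in %s", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  rep <- list(incomplete = character())
  grab <- function(file, fn) {
    p <- file.path(dir, file)
    if (file.exists(p)) fn(p)
    else { rep$incomplete <<- c(rep$incomplete, file); NULL }
  }
  st <- mf$stages
  rep$counts <- list(simulated_cells = st$simulate$n_cells,
                     qc_final_cells = st$qc$n_final,
                     genes_kept = st$qc$n_genes_kept)
  qd <- grab("quadrants.tsv", tsv_read)
  if (!is.null(qd)) rep$quadrant_sizes <- as.list(table(qd$quadrant))
  enr <- grab("enrichment.tsv", tsv_read)
  if (!is.null(enr))
    rep$enrichment_calls <- as.list(table(paste(enr$quadrant, enr$category,
                                                enr$call, sep = ":")))
  rep$mapping_accuracy <- st$map$heldout_accuracy
  ks <- grab("l23_ks.tsv", tsv_read)
  if (!is.null(ks)) rep$ks <- ks
  ovl <- file.path(dir, "overlap.tsv")
  if (file.exists(ovl)) rep$overlap <- tsv_read(ovl)
  rep$errors <- mf$errors
  jsonlite::write_json(rep, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(rep)
}
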