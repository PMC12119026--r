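#' Simulate a count matrix with planted ground truth
#'
#' Draws a sparse cells x genes raw count matrix from the negative-binomial
#' generative model described by a [sim_design()]: per-cell means are
#' `baseline * 2^(sum of applicable planted log2 effects)`, renormalised and
#' scaled by a log-normal library size. Cells of the continuum subclass get
#' type-marker effects interpolated along a latent coordinate `u` drawn from
#' a type-specific Beta. Doublets are sums of two random singlets of the same
#' condition; low-quality cells receive library sizes below the standard
#' retention floor; high-mito cells have their mitochondrial mass inflated to
#' a designed fraction.
#'
#' @param design A [sim_design()] object.
#' @return A list with components:
#' \describe{
#'   \item{counts}{`dgCMatrix`, cells x genes, raw integer counts.}
#'   \item{meta}{data.frame: `barcode`, `replicate`, `condition`, `timepoint`,
#'     `doublet_score` (noisy score emulating an external doublet caller).}
#'   \item{truth}{list of `cells` (true class/subclass/type, continuum
#'     coordinate `u`, artifact flags), `genes` (planted program table with
#'     quadrant labels; unprogrammed genes are Q3), and `composition`
#'     (true type-frequency vectors per condition).}
#' }
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (any(design$dispersion <= 0)) stopf("non-positive dispersion")
  if (anyDuplicated(design$conditions)) stopf("condition labels not unique")

  with_seed(design$seed, {
    ng <- design$n_genes
    size <- 1 / design$dispersion          # NB size = 1/phi
    lsl <- design$library_size_lognormal
    cont <- design$continuum_subclass
    cont_types <- if (!is.na(cont)) design$types$type[design$types$subclass == cont] else character()

    blocks <- list()   # sparse triplet blocks
    cellrec <- list()
    n_cells_done <- 0L

    draw_block <- function(mu) {
      # mu: genes x cells dense mean matrix -> sparse triplets appended
      cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = rep(size, ncol(mu))),
                    nrow(mu), ncol(mu))
      nz <- which(cnt > 0, arr.ind = TRUE)
      blocks[[length(blocks) + 1L]] <<- list(
        i = n_cells_done + nz[, 2L], j = nz[, 1L], x = cnt[nz])
      n_cells_done <<- n_cells_done + ncol(mu)
      invisible(NULL)
    }

    rel_expr <- function(eff) {
      # eff: genes x cells log2 effect matrix -> per-cell relative expression
      m <- design$baseline * 2^eff
      sweep(m, 2L, colSums(m), "/")
    }

    # shared (non type-specific) log2 effect for a (subclass, condition)
    shared_effect <- function(sc, cond) {
      pr <- design$programs
      tp <- design$timepoint_of_condition[[cond]]
      sel <- (is.na(pr$subclass) | pr$subclass == sc) & is.na(pr$type) &
        (is.na(pr$timepoint) | pr$timepoint == tp) &
        (is.na(pr$condition) | pr$condition == cond)
      eff <- numeric(ng)
      if (any(sel)) {
        agg <- rowsum(pr$log2fc[sel], pr$gene[sel])
        eff[as.integer(rownames(agg))] <- agg[, 1L]
      }
      eff
    }
    type_effect <- function(ty) {
      pr <- design$programs
      sel <- !is.na(pr$type) & pr$type == ty
      eff <- numeric(ng)
      if (any(sel)) {
        agg <- rowsum(pr$log2fc[sel], pr$gene[sel])
        eff[as.integer(rownames(agg))] <- agg[, 1L]
      }
      eff
    }

    inflate_mito <- function(p, target) {
      # rescale mito mass of a relative-expression column to `target`
      m <- sum(p[design$is_mito])
      if (m <= 0 || m >= 1) return(p)
      f <- target * (1 - m) / (m * (1 - target))
      p[design$is_mito] <- p[design$is_mito] * f
      p / sum(p)
    }

    chunked <- function(n, chunk = 500L) split(seq_len(n), ceiling(seq_len(n) / chunk))

    for (cond in design$conditions) {
      tp <- design$timepoint_of_condition[[cond]]
      cond_first <- n_cells_done + 1L
      for (ti in seq_len(nrow(design$types))) {
        ty <- design$types$type[ti]
        sc <- design$types$subclass[ti]
        nct <- design$cells_per_type[ty, cond]
        if (nct == 0L) next
        base_eff <- shared_effect(sc, cond)
        if (!is.na(cont) && sc == cont) {
          shp <- design$continuum_shapes[match(ty, cont_types), ]
          u <- rbeta(nct, shp[1], shp[2])
          M <- vapply(cont_types, type_effect, numeric(ng))  # genes x 3
          shp3 <- design$continuum_shapes
          W <- rbind(dbeta(u, shp3[1, 1], shp3[1, 2]),
                     dbeta(u, shp3[2, 1], shp3[2, 2]),
                     dbeta(u, shp3[3, 1], shp3[3, 2]))
          W <- sweep(W, 2L, colSums(W), "/")                 # 3 x cells memberships
          L <- rlnorm(nct, lsl[1], lsl[2])
          for (ix in chunked(nct)) {
            eff <- base_eff + M %*% W[, ix, drop = FALSE]
            mu <- sweep(rel_expr(eff), 2L, L[ix], "*")
            draw_block(mu)
          }
          cellrec[[length(cellrec) + 1L]] <- data.frame(
            condition = cond, timepoint = tp, subclass = sc, type = ty,
            u = u, is_doublet = FALSE, is_lowq = FALSE, is_highmito = FALSE,
            stringsAsFactors = FALSE)
        } else {
          eff1 <- base_eff + type_effect(ty)
          p <- rel_expr(matrix(eff1, ncol = 1))[, 1L]
          L <- rlnorm(nct, lsl[1], lsl[2])
          for (ix in chunked(nct)) draw_block(outer(p, L[ix]))
          cellrec[[length(cellrec) + 1L]] <- data.frame(
            condition = cond, timepoint = tp, subclass = sc, type = ty,
            u = rep(NA_real_, nct), is_doublet = FALSE, is_lowq = FALSE,
            is_highmito = FALSE, stringsAsFactors = FALSE)
        }
      }
      n_singlet <- n_cells_done - cond_first + 1L

      # planted artifacts: low-quality, high-mito, then doublets
      art <- function(n_art, lowq, himi) {
        if (n_art == 0L) return(invisible(NULL))
        avail <- which(design$cells_per_type[, cond] > 0)
        ti <- avail[sample.int(length(avail), n_art, replace = TRUE)]
        for (k in seq_len(n_art)) {
          ty <- design$types$type[ti[k]]; sc <- design$types$subclass[ti[k]]
          # degraded (high-mito) nuclei lose their type signature and converge
          # to the shared baseline profile, as in dying cells
          eff1 <- if (himi) numeric(ng) else shared_effect(sc, cond) + type_effect(ty)
          p <- rel_expr(matrix(eff1, ncol = 1))[, 1L]
          if (himi) p <- inflate_mito(p, runif(1, design$highmito_range[1],
                                               design$highmito_range[2]))
          L <- if (lowq) runif(1, 50, 450) else rlnorm(1, lsl[1], lsl[2])
          draw_block(matrix(p * L, ncol = 1))
          cellrec[[length(cellrec) + 1L]] <<- data.frame(
            condition = cond, timepoint = tp, subclass = sc, type = ty,
            u = NA_real_, is_doublet = FALSE, is_lowq = lowq,
            is_highmito = himi, stringsAsFactors = FALSE)
        }
      }
      art(round(design$lowq_rate * n_singlet), lowq = TRUE, himi = FALSE)
      art(round(design$highmito_rate * n_singlet), lowq = FALSE, himi = TRUE)

      n_doub <- round(design$doublet_rate * n_singlet)
      if (n_doub > 0L) {
        # doublet = draw at the summed mean profiles of two random singlets,
        # each with its own library size (expected size ~ 2x singlet mean)
        parents <- do.call(rbind, cellrec)
        parents <- parents[parents$condition == cond & !parents$is_doublet &
                             !parents$is_lowq & !parents$is_highmito, ]
        pairs <- matrix(sample.int(nrow(parents), 2L * n_doub, replace = TRUE),
                        ncol = 2L)
        for (k in seq_len(n_doub)) {
          mu_tot <- numeric(ng)
          for (pi in pairs[k, ]) {
            ty <- parents$type[pi]; sc <- parents$subclass[pi]
            eff1 <- shared_effect(sc, cond) + type_effect(ty)
            p <- rel_expr(matrix(eff1, ncol = 1))[, 1L]
            mu_tot <- mu_tot + p * rlnorm(1, lsl[1], lsl[2])
          }
          draw_block(matrix(mu_tot, ncol = 1))
          cellrec[[length(cellrec) + 1L]] <- data.frame(
            condition = cond, timepoint = tp, subclass = NA_character_,
            type = NA_character_, u = NA_real_, is_doublet = TRUE,
            is_lowq = FALSE, is_highmito = FALSE, stringsAsFactors = FALSE)
        }
      }
    }

    cells <- do.call(rbind, cellrec)
    n_cells <- nrow(cells)
    stopifnot(n_cells == n_cells_done)
    barcodes <- sprintf("%s_c%06d", cells$condition, seq_len(n_cells))
    cells$barcode <- barcodes
    cells$class <- ifelse(is.na(cells$subclass), NA_character_,
                          unname(design$class_of_subclass[cells$subclass]))

    trip <- list(
      i = unlist(lapply(blocks, `[[`, "i")),
      j = unlist(lapply(blocks, `[[`, "j")),
      x = unlist(lapply(blocks, `[[`, "x")))
    counts <- sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                           dims = c(n_cells, ng),
                           dimnames = list(barcodes, design$gene_ids))

    replicate <- paste0(cells$condition, "_r",
                        sample.int(design$n_replicates, n_cells, replace = TRUE))
    doublet_score <- ifelse(cells$is_doublet, rbeta(n_cells, 12, 3), rbeta(n_cells, 2, 18))
    meta <- data.frame(barcode = barcodes, replicate = replicate,
                       condition = cells$condition, timepoint = cells$timepoint,
                       doublet_score = doublet_score, stringsAsFactors = FALSE)

    genes_truth <- data.frame(gene = design$gene_ids,
                              program = "none", quadrant = "Q3",
                              stringsAsFactors = FALSE)
    pr <- design$programs
    first <- !duplicated(pr$gene)
    genes_truth$program[pr$gene[first]] <- pr$program[first]
    genes_truth$quadrant[pr$gene[first]] <- pr$quadrant[first]
    genes_truth$quadrant[design$is_mito] <- NA_character_

    truth <- list(
      cells = cells[, c("barcode", "class", "subclass", "type", "u",
                        "is_doublet", "is_lowq", "is_highmito")],
      genes = genes_truth,
      programs = pr,
      composition = design$composition
    )
    list(counts = counts, meta = meta, truth = truth)
  })
}
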