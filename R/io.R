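#' Write a simulated dataset as a plain-text fixture directory
#'
#' Writes `matrix.mtx` (Matrix Market integer coordinate, cells x genes),
#' `genes.tsv` (`gene_id`, `gene_name`, `is_mito`), `cells.tsv` (the cell
#' metadata), and, when ground truth is supplied, `truth_cells.tsv`,
#' `truth_genes.tsv` and `truth_composition.tsv`. The layout round-trips
#' losslessly through [read_fixture()].
#'
#' @param counts cells x genes sparse count matrix with dimnames.
#' @param meta Per-cell metadata data.frame (first column `barcode`).
#' @param truth Optional ground-truth list as returned by [simulate_counts()].
#' @param dir Output directory.
#' @param is_mito Logical per gene; defaults to `grepl("^mt-", colnames(counts))`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(counts, meta, truth = NULL, dir, is_mito = NULL,
                          overwrite = FALSE) {
  counts <- as_sparse(counts)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stopf("directory '%s' exists and is not empty (use overwrite = TRUE)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(is_mito)) is_mito <- grepl("^mt-", colnames(counts))

  write_mtx_int(counts, file.path(dir, "matrix.mtx"))
  genes <- data.frame(gene_id = colnames(counts), gene_name = colnames(counts),
                      is_mito = is_mito, stringsAsFactors = FALSE)
  tsv_write(genes, file.path(dir, "genes.tsv"))
  tsv_write(meta, file.path(dir, "cells.tsv"))
  if (!is.null(truth)) {
    tsv_write(truth$cells, file.path(dir, "truth_cells.tsv"))
    tsv_write(truth$genes, file.path(dir, "truth_genes.tsv"))
    if (!is.null(truth$composition)) {
      comp <- data.frame(type = rownames(truth$composition),
                         truth$composition, check.names = FALSE)
      tsv_write(comp, file.path(dir, "truth_composition.tsv"))
    }
  }
  invisible(dir)
}

#' Read a fixture directory
#'
#' @param dir Directory written by [write_fixture()] (or following the same
#'   layout).
#' @return List with `counts` (cells x genes `dgCMatrix`), `genes`, `meta`
#'   and, if present, `truth`.
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir)) stopf("no such directory: %s", dir)
  m <- as_sparse(readMM(file.path(dir, "matrix.mtx")))
  genes <- tsv_read(file.path(dir, "genes.tsv"))
  meta <- tsv_read(file.path(dir, "cells.tsv"))
  if (nrow(m) != nrow(meta) || ncol(m) != nrow(genes))
    stopf("matrix dimensions do not match metadata")
  dimnames(m) <- list(meta$barcode, genes$gene_id)
  out <- list(counts = m, genes = genes, meta = meta)
  tc <- file.path(dir, "truth_cells.tsv")
  if (file.exists(tc)) {
    comp_path <- file.path(dir, "truth_composition.tsv")
    comp <- NULL
    if (file.exists(comp_path)) {
      cdf <- tsv_read(comp_path)
      comp <- as.matrix(cdf[, -1, drop = FALSE])
      rownames(comp) <- cdf$type
    }
    out$truth <- list(cells = tsv_read(tc),
                      genes = tsv_read(file.path(dir, "truth_genes.tsv")),
                      composition = comp)
  }
  out
}

# Matrix Market "integer general" coordinate writer. Matrix::writeMM only
# emits the real field for dgCMatrix, so raw counts are written here with
# the integer header that count-matrix tooling expects; readMM reads both.
write_mtx_int <- function(m, path) {
  m <- as_sparse(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x)) {
    tm <- as(m, "TsparseMatrix")
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  }
  invisible(path)
}

tsv_write <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_read <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "")
}
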