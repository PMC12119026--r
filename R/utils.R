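# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
# All stochastic operations in the package funnel through this so that no
# function leaves global RNG side effects.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce to dgCMatrix (cells x genes) preserving dimnames.
as_sparse <- function(x) {
  if (is(x, "dgCMatrix")) return(x)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Extract column j of a cells x genes dgCMatrix as a dense vector.
col_dense <- function(x, j) {
  v <- numeric(nrow(x))
  idx <- (x@p[j] + 1L):x@p[j + 1L]
  if (x@p[j + 1L] > x@p[j]) v[x@i[idx] + 1L] <- x@x[idx]
  v
}

# Check that `ids` are unique non-empty strings.
check_ids <- function(ids, what) {
  if (anyDuplicated(ids)) stopf("duplicate %s identifiers", what)
  if (any(!nzchar(ids))) stopf("empty %s identifier", what)
  invisible(ids)
}
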