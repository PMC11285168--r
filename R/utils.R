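# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and an integer index.
# Plain multiplicative hash kept inside 32-bit signed range so set.seed()
# never overflows; distinct (seed, index) pairs map to distinct streams for
# the index ranges used here (gene indices, stage offsets).
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 104729) %% 2147483629L)
}

# Evaluate fn under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# counts tibble (gene_id + sample columns) -> integer matrix
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  m
}

matrix_to_tbl <- function(m) {
  out <- as_tibble(as.data.frame(m))
  tibble::add_column(out, gene_id = rownames(m), .before = 1L)
}
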