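#' Build an EC20-anchored dilution-series exposure design
#'
#' Constructs the concentration layout used throughout the package: a vehicle
#' control (0) plus a geometric dilution series ending at the anchor
#' concentration (typically the compound's EC20), with a fixed number of
#' replicates per concentration.
#'
#' @param anchor_uM Top (anchor) concentration in µM; must be positive.
#' @param n_dilutions Number of dilution steps below the anchor (>= 0). The
#'   design has `n_dilutions + 2` concentrations including the control.
#' @param dilution_factor Ratio between successive concentrations (> 1).
#' @param n_replicates Replicates per concentration (>= 2).
#'
#' @return A `dose_design` object: a list with `concentrations` (ascending,
#'   starting at 0), `n_replicates`, `anchor`, and `dilution_factor`. Use
#'   [design_samples()] for the per-sample layout as a tibble.
#'
#' @examples
#' make_design(2.92, n_dilutions = 3, dilution_factor = 10, n_replicates = 3)
#' @export
make_design <- function(anchor_uM, n_dilutions = 3, dilution_factor = 10,
                        n_replicates = 3) {
  stopifnot_scalar_num(anchor_uM, "anchor_uM", positive = TRUE)
  stopifnot_scalar_num(n_dilutions, "n_dilutions")
  stopifnot_scalar_num(dilution_factor, "dilution_factor")
  stopifnot_scalar_num(n_replicates, "n_replicates")
  if (dilution_factor <= 1) abort("`dilution_factor` must be > 1.")
  if (n_dilutions < 0) abort("`n_dilutions` must be >= 0.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  conc <- anchor_uM / dilution_factor^(n_dilutions:0)
  structure(
    list(
      concentrations = c(0, conc),
      n_replicates = as.integer(n_replicates),
      anchor = anchor_uM,
      dilution_factor = dilution_factor
    ),
    class = "dose_design"
  )
}

#' @export
print.dose_design <- function(x, ...) {
  cat("<dose_design> ", length(x$concentrations), " concentrations x ",
      x$n_replicates, " replicates\n", sep = "")
  cat("  conc (uM): ", paste(signif(x$concentrations, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-sample layout of a dose design
#'
#' @param design A [make_design()] object.
#' @return Tibble with `sample_id`, `concentration_uM`, `replicate`.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "dose_design"))
  grid <- expand.grid(
    replicate = paste0("R", seq_len(design$n_replicates)),
    concentration_uM = design$concentrations,
    stringsAsFactors = FALSE
  )
  tibble(
    sample_id = sprintf("S%02d_c%s_%s", seq_len(nrow(grid)),
                        format(grid$concentration_uM, trim = TRUE,
                               scientific = FALSE, drop0trailing = TRUE),
                        grid$replicate),
    concentration_uM = grid$concentration_uM,
    replicate = grid$replicate
  )
}

# Validate a sample sheet against the counts tibble and return it ordered
# as the count columns.
align_samples <- function(counts, samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "concentration_uM", "replicate") %in% names(samples)))
  ids <- setdiff(names(counts), "gene_id")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_ids in sample sheet")
  missing <- setdiff(ids, samples$sample_id)
  if (length(missing)) {
    abort(paste0("samples missing from sheet: ", paste(missing, collapse = ", ")))
  }
  samples[match(ids, samples$sample_id), , drop = FALSE]
}
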