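#' Simulate a dose-series RNA-seq count matrix from ground truth
#'
#' Draws negative-binomial counts per gene and sample. The expected count of
#' gene g in sample j is `baseline_mean[g] * 2^curve_g(conc_j)`, rescaled per
#' sample so expected column totals match that sample's library size.
#' Library sizes jitter lognormally (sd 0.1 on the log scale) around
#' `library_size`, emulating depth variation between sequencing libraries.
#' Counts are drawn gene by gene from a per-gene seeded stream, so enlarging
#' the truth table never reshuffles counts of existing genes.
#'
#' @param truth Truth tibble from [make_truth()].
#' @param design A [make_design()] object.
#' @param library_size Target reads per sample (expected column sum).
#' @param seed Integer seed; identical `(truth, design, library_size, seed)`
#'   give bit-identical matrices.
#'
#' @return A `tpod_experiment`: list with `counts` (tibble, `gene_id` +
#'   one integer column per sample), `samples` (sample sheet tibble),
#'   `design`, and `truth`.
#' @export
simulate_counts <- function(truth, design, library_size = 5e5, seed = 1) {
  stopifnot(inherits(design, "dose_design"))
  stopifnot(is.data.frame(truth), nrow(truth) > 0)
  if (any(truth$dispersion < 0)) abort("negative dispersion in truth table")
  if (any(truth$baseline_mean <= 0)) abort("baseline_mean must be > 0")
  samples <- design_samples(design)
  n_s <- nrow(samples)
  n_g <- nrow(truth)
  conc <- samples$concentration_uM

  # expected (unscaled) mean matrix, deterministic given truth
  log2shift <- t(vapply(truth$curve, eval_truth_curve, numeric(n_s), conc = conc))
  mu <- truth$baseline_mean * 2^log2shift

  # sample-level depth jitter from its own stream
  lib <- with_seed(child_seed(seed, 999999L), function() {
    library_size * rlnorm(n_s, meanlog = -0.1^2 / 2, sdlog = 0.1)
  })
  scale_j <- lib / colSums(mu)

  counts <- matrix(0L, n_g, n_s,
                   dimnames = list(truth$gene_id, samples$sample_id))
  for (g in seq_len(n_g)) {
    mu_g <- mu[g, ] * scale_j
    phi <- truth$dispersion[g]
    counts[g, ] <- with_seed(child_seed(seed, g), function() {
      if (phi == 0) rpois(n_s, mu_g) else rnbinom(n_s, mu = mu_g, size = 1 / phi)
    })
  }

  samples$library_target <- lib
  structure(
    list(counts = matrix_to_tbl(counts), samples = samples,
         design = design, truth = truth),
    class = "tpod_experiment"
  )
}

#' @export
print.tpod_experiment <- function(x, ...) {
  cat("<tpod_experiment> ", nrow(x$counts), " genes x ", nrow(x$samples),
      " samples\n", sep = "")
  print(x$design)
  cat("  responsive genes: ", sum(x$truth$responsive), "\n", sep = "")
  invisible(x)
}
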