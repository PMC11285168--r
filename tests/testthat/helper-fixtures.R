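# Shared fixtures, built in code at test time.

tbbpa_design <- function(n_replicates = 3) {
  make_design(2.92, n_dilutions = 3, dilution_factor = 10,
              n_replicates = n_replicates)
}

bpa_design <- function(n_replicates = 3) {
  make_design(48.3, n_dilutions = 3, dilution_factor = 10,
              n_replicates = n_replicates)
}

# tiny experiment reused by io / pipeline tests
small_experiment <- function(n_genes = 120, seed = 7) {
  d <- tbbpa_design()
  tr <- make_truth(d, n_genes = n_genes, prop_responsive = 0.15, seed = seed)
  simulate_counts(tr, d, library_size = 5e4, seed = seed)
}

# per-sample concentrations for a design
design_conc <- function(design) design_samples(design)$concentration_uM

# simulate one gene's normalized log2 profile from a curve + gaussian noise
sim_gene_profile <- function(curve, design, baseline = 5, sigma = 0.3,
                             seed = 1) {
  conc <- design_conc(design)
  set.seed(seed)
  baseline + tpodr:::eval_truth_curve(curve, conc) + rnorm(length(conc), 0, sigma)
}

# two-arm (control vs treated) NB experiment with a minority of genes
# carrying solid log2 shifts, for DE calibration
sim_two_arm <- function(n_genes = 1000, n_resp = 100, n_rep = 3, seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(60), 1.3)
  phi <- rlnorm(n_genes, log(0.05), 0.4)
  lfc <- c(runif(n_resp, 1, 2.5) * sample(c(-1, 1), n_resp, replace = TRUE),
           rep(0, n_genes - n_resp))
  mu <- cbind(matrix(base, n_genes, n_rep),
              matrix(base * 2^lfc, n_genes, n_rep))
  m <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / phi, 2 * n_rep)),
              n_genes)
  colnames(m) <- paste0("s", seq_len(2 * n_rep))
  counts <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)))
  for (j in seq_len(ncol(m))) counts[[colnames(m)[j]]] <- m[, j]
  samples <- tibble::tibble(
    sample_id = colnames(m),
    concentration_uM = rep(c(0, 10), each = n_rep),
    replicate = rep(paste0("R", seq_len(n_rep)), 2)
  )
  list(counts = counts, samples = samples,
       gene_id = counts$gene_id, responsive = lfc != 0, lfc = lfc)
}

# toy GMT written to a temp file
write_toy_gmt <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}
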