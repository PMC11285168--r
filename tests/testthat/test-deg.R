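mk_counts <- function(m) {
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(m)))) |>
    dplyr::bind_cols(tibble::as_tibble(as.data.frame(m)))
}

mk_sheet <- function(counts, conc, repl = NULL) {
  ids <- setdiff(names(counts), "gene_id")
  tibble::tibble(sample_id = ids, concentration_uM = conc,
                 replicate = repl %||% paste0("R", seq_along(ids)))
}

test_that("median-of-ratios factors absorb depth differences", {
  set.seed(1)
  base <- rpois(50, 100) + 1
  m <- cbind(s1 = base, s2 = 2 * base)
  sf <- size_factors(mk_counts(m))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  m3 <- cbind(a = base, b = base, c = base)
  expect_equal(unname(size_factors(mk_counts(m3))), rep(1, 3))

  expect_equal(unname(size_factors(mk_counts(cbind(only = base)))), 1)
})

test_that("log2 normalization matches hand-computed values", {
  m <- matrix(c(0, 7, 10), 3, 1, dimnames = list(NULL, "s1"))
  norm <- normalize_log2(mk_counts(m), factors = c(s1 = 1), pseudocount = 1)
  expect_equal(norm$s1, c(0, 3, log2(11)))
  norm2 <- normalize_log2(mk_counts(matrix(10, 1, 1,
                                           dimnames = list(NULL, "s1"))),
                          factors = c(s1 = 2), pseudocount = 1)
  expect_equal(norm2$s1, log2(6))
  expect_error(normalize_log2(mk_counts(m), factors = c(s1 = -1)), "factor")
})

test_that("identical arms give near-zero fold change and large p", {
  set.seed(9)
  base <- rpois(80, 60) + 5
  m <- matrix(rep(base, 6), ncol = 6)
  colnames(m) <- paste0("s", 1:6)
  counts <- mk_counts(m)
  sheet <- mk_sheet(counts, rep(c(0, 10), each = 3),
                    rep(paste0("R", 1:3), 2))
  res <- nb_test(counts, sheet)
  expect_true(all(abs(res$log2fc) < 1e-6))
  expect_true(all(res$p >= 0.5))
})

test_that("DEG thresholds implement the FDR and 1.5-fold gates", {
  rec <- tibble::tibble(gene_id = c("a", "b", "c"),
                        log2fc = c(0.60, 0.50, 3.0),
                        q = c(0.04, 0.04, 0.06))
  out <- call_degs(rec)
  expect_identical(out$is_deg, c(TRUE, FALSE, FALSE))
})

test_that("null simulation keeps the type-I error near nominal", {
  d <- make_design(10, 0, 10, 3)
  tr <- make_truth(d, n_genes = 2000, prop_responsive = 0, seed = 21)
  sim <- simulate_counts(tr, d, library_size = 2e5, seed = 21)
  res <- nb_test(sim$counts, sim$samples)
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  n <- sum(!is.na(res$p))
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("a 4-fold shift is recovered with accurate fold change", {
  d <- make_design(10, 0, 10, 3)
  set.seed(31)
  n_genes <- 300
  base <- rep(100, n_genes)
  shift <- c(rep(4, 20), rep(1, n_genes - 20))
  mu <- outer(base, rep(1, 6))
  mu[, 4:6] <- mu[, 4:6] * shift
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), nrow = n_genes)
  colnames(m) <- paste0("s", 1:6)
  counts <- mk_counts(m)
  sheet <- mk_sheet(counts, rep(c(0, 10), each = 3),
                    rep(paste0("R", 1:3), 2))
  res <- nb_test(counts, sheet)
  hits <- res[res$gene_id %in% sprintf("g%03d", 1:20), ]
  # mean fold change unbiased within Monte-Carlo error of the 20 genes
  se_lfc <- sd(hits$log2fc) / sqrt(nrow(hits))
  expect_lt(abs(mean(hits$log2fc) - 2), 3 * se_lfc)
  expect_gt(mean(abs(hits$log2fc - 2) < 0.5), 0.8)
  expect_gt(mean(hits$is_deg), 0.9)
})

test_that("BH adjustment preserves the p-value ordering", {
  exp_ <- small_experiment()
  res <- nb_test(exp_$counts, exp_$samples)
  ok <- !is.na(res$p)
  expect_identical(order(res$p[ok]), order(res$q[ok], res$p[ok]))
  expect_true(all(res$q[ok] >= res$p[ok]))
})

test_that("common depth scaling leaves fold changes unchanged", {
  exp_ <- small_experiment()
  res1 <- nb_test(exp_$counts, exp_$samples)
  scaled <- exp_$counts
  for (nm in setdiff(names(scaled), "gene_id")) {
    scaled[[nm]] <- scaled[[nm]] * 3L
  }
  res2 <- nb_test(scaled, exp_$samples)
  j <- match(res1$gene_id, res2$gene_id)
  ok <- !is.na(res1$log2fc) & !is.na(res2$log2fc[j])
  expect_equal(res1$log2fc[ok], res2$log2fc[j][ok], tolerance = 0.02)
})

test_that("raising the fold cutoff never adds DEGs", {
  exp_ <- small_experiment()
  res <- nb_test(exp_$counts, exp_$samples)
  n15 <- sum(call_degs(res, lfc_cut = 0.585)$is_deg)
  n20 <- sum(call_degs(res, lfc_cut = 1)$is_deg)
  expect_lte(n20, n15)
})

test_that("all-zero genes are reported with missing statistics", {
  exp_ <- small_experiment(n_genes = 40)
  counts <- exp_$counts
  for (nm in setdiff(names(counts), "gene_id")) counts[[nm]][1] <- 0L
  res <- nb_test(counts, exp_$samples)
  row <- res[res$gene_id == counts$gene_id[1], ]
  expect_true(is.na(row$p))
  expect_false(row$is_deg)
})
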