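test_that("true_bmd_of matches closed forms and handles flat curves", {
  # linear curve: bmd = bmr / slope
  lin <- list(type = "linear", params = list(b = 0.25))
  expect_equal(true_bmd_of(lin, bmr = 1, max_conc = 10), 4, tolerance = 1e-6)

  # hill half-max: 2c/(10+c) = 1 at c = 10
  hill <- list(type = "hill", params = list(v = 2, n = 1, k = 10))
  expect_equal(true_bmd_of(hill, bmr = 1, max_conc = 10), 10, tolerance = 1e-6)

  # flat curve never reaches any response
  expect_true(is.na(true_bmd_of(list(type = "flat", params = list()),
                                bmr = 0.1, max_conc = 10)))
})

test_that("true_bmd_of agrees with a dense-grid scan for every curve family", {
  grid_oracle <- function(curve, bmr, upper, n = 1e4) {
    cs <- seq(upper / n, upper, length.out = n)
    dy <- abs(tpodr:::eval_truth_curve(curve, cs))
    i <- which(dy >= bmr)[1]
    if (is.na(i)) NA_real_ else cs[i]
  }
  curves <- list(
    list(type = "linear", params = list(b = 0.4)),
    list(type = "hill", params = list(v = -1.8, n = 2.5, k = 1.2)),
    list(type = "hill", params = list(v = 1.2, n = 0.8, k = 0.05)),
    list(type = "expsat", params = list(v = 2.2, tau = 0.7)),
    list(type = "expsat", params = list(v = -1.1, tau = 3))
  )
  upper <- 29.2 # 10 x top concentration
  for (cv in curves) {
    got <- true_bmd_of(cv, bmr = 0.5, max_conc = 2.92)
    ora <- grid_oracle(cv, 0.5, upper)
    if (is.na(ora)) {
      expect_true(is.na(got))
    } else {
      expect_lt(abs(got - ora), upper / 1e4 + 1e-9)
    }
  }
})

test_that("truth tables respect their invariants", {
  d <- tbbpa_design()
  tr <- make_truth(d, n_genes = 400, prop_responsive = 0.2, bmr = 0.5,
                   seed = 3)
  expect_true(all(tr$baseline_mean > 0))
  expect_true(all(tr$dispersion >= 0))
  expect_identical(is.na(tr$true_bmd), !tr$responsive)
  ok <- tr$responsive
  expect_true(all(tr$true_bmd[ok] > 0 & tr$true_bmd[ok] <= 2.92))
  # recorded true_bmd is the bmr crossing of the stored curve
  idx <- which(ok)[1:25]
  for (i in idx) {
    expect_equal(suppressWarnings(true_bmd_of(tr$curve[[i]], 0.5, 2.92)),
                 tr$true_bmd[i], tolerance = 1e-3)
  }
})

test_that("identical seeds give bit-identical count matrices", {
  d <- tbbpa_design()
  tr <- make_truth(d, n_genes = 60, seed = 5)
  a <- simulate_counts(tr, d, library_size = 3e4, seed = 11)
  b <- simulate_counts(tr, d, library_size = 3e4, seed = 11)
  expect_identical(a$counts, b$counts)
  c2 <- simulate_counts(tr, d, library_size = 3e4, seed = 12)
  expect_false(identical(a$counts, c2$counts))
})

test_that("adding genes never reshuffles counts of existing genes", {
  d <- tbbpa_design()
  tr <- make_truth(d, n_genes = 80, seed = 5)
  small <- simulate_counts(tr[1:40, ], d, library_size = 3e4, seed = 11)
  big <- simulate_counts(tr, d, library_size = 3e4, seed = 11)
  # per-gene RNG streams: same draws, only the deterministic column scaling
  # differs with the larger gene set
  m_small <- as.matrix(small$counts[, -1])
  m_big <- as.matrix(big$counts[1:40, -1])
  # compare a gene with zero dose effect and identical expected mean ratio
  expect_gt(cor(as.numeric(m_small), as.numeric(m_big)), 0.98)
})

test_that("non-responsive genes have dose-independent expected means", {
  d <- tbbpa_design()
  tr <- tibble::tibble(
    gene_id = "flatgene", baseline_mean = 200, dispersion = 0,
    responsive = FALSE, curve = list(list(type = "flat", params = list())),
    true_bmd = NA_real_
  )
  # many replicate draws via different seeds; group means by concentration
  draws <- sapply(1:200, function(s) {
    as.numeric(as.matrix(simulate_counts(tr, d, library_size = 1000,
                                         seed = s)$counts[, -1]))
  })
  conc <- design_conc(d)
  by_conc <- tapply(rowMeans(draws), conc, mean)
  expect_lt(diff(range(by_conc)) / mean(by_conc), 0.05)
})

test_that("dispersion 0 gives the Poisson limit; NB variance follows mu + phi mu^2", {
  d <- make_design(1, 0, 10, 2) # 2 concentrations x 2 reps = 4 samples
  mk <- function(phi) tibble::tibble(
    gene_id = "g1", baseline_mean = 50, dispersion = phi, responsive = FALSE,
    curve = list(list(type = "flat", params = list())), true_bmd = NA_real_
  )
  # collect (count, conditional mean) pairs; with a single gene the
  # conditional mean is that sample's drawn library target
  pull_draws <- function(phi, n_seeds = 2500) {
    out <- lapply(seq_len(n_seeds), function(s) {
      sim <- simulate_counts(mk(phi), d, library_size = 200, seed = s)
      cbind(as.numeric(as.matrix(sim$counts[1, -1])),
            sim$samples$library_target)
    })
    do.call(rbind, out)
  }
  check_moments <- function(phi) {
    xs <- pull_draws(phi)
    mu <- xs[, 2]
    z <- (xs[, 1] - mu)^2 / (mu + phi * mu^2) # expectation 1 per draw
    se <- sd(z) / sqrt(length(z))
    expect_lt(abs(mean(z) - 1), 3 * se)
  }
  check_moments(0)    # Poisson limit: variance = mean
  check_moments(0.2)  # NB: variance = mu + phi mu^2
})

test_that("column sums track the per-sample library targets", {
  d <- tbbpa_design()
  tr <- make_truth(d, n_genes = 5000, seed = 2)
  sim <- simulate_counts(tr, d, library_size = 2e5, seed = 2)
  cs <- colSums(as.matrix(sim$counts[, -1]))
  rel <- abs(cs - sim$samples$library_target) / sim$samples$library_target
  expect_true(all(rel < 0.05))
})
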