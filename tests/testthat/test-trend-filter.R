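test_that("pava reproduces hand-worked monotone fits and conserves mass", {
  expect_equal(pava(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pava(c(1, 3, 2, 5)), c(1, 2.5, 2.5, 5))
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(5)
    w <- runif(5, 0.5, 3)
    fit <- pava(x, w)
    expect_true(all(diff(fit) >= -1e-12))
    expect_equal(sum(fit * w), sum(x * w), tolerance = 1e-9)
    # decreasing direction mirrors the increasing fit
    expect_equal(pava(x, w, direction = -1), -pava(-x, w), tolerance = 1e-12)
  }
})

test_that("pava equals brute-force monotone least squares on small cases", {
  # oracle: optimize over all monotone vectors on a fine grid of candidate
  # level sets via isotonic projections of every partition
  brute <- function(x, w) {
    n <- length(x)
    best <- NULL
    # enumerate partitions of 1..n into consecutive blocks
    parts <- function(start) {
      if (start > n) return(list(list()))
      out <- list()
      for (end in start:n) {
        for (rest in parts(end + 1)) {
          out <- c(out, list(c(list(start:end), rest)))
        }
      }
      out
    }
    for (pt in parts(1)) {
      lev <- vapply(pt, function(ix) sum(x[ix] * w[ix]) / sum(w[ix]),
                    numeric(1))
      if (any(diff(lev) < 0)) next
      fit <- numeric(n)
      for (j in seq_along(pt)) fit[pt[[j]]] <- lev[j]
      sse <- sum(w * (x - fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
    best$fit
  }
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(5)
    w <- runif(5, 0.5, 2)
    expect_equal(pava(x, w), brute(x, w), tolerance = 1e-9)
  }
})

test_that("williams statistic matches the hand-worked 3-group case", {
  # control mean 0, doses 1 and 2, n = 3 each, pooled s2 = 1
  base <- c(-1, 0, 1) / sqrt(2) * sqrt(2) # sd chosen so pooled s2 = 1
  vals <- c(base + 0, base + 1, base + 2)
  conc <- rep(c(0, 1, 2), each = 3)
  s2 <- sum(tapply(vals, conc, function(v) sum((v - mean(v))^2))) / (9 - 3)
  expect_equal(s2, 1)
  st <- williams_stat(vals, conc, direction = 1)
  expect_equal(as.numeric(st), 2 / sqrt(2 / 3), tolerance = 1e-9)
})

test_that("the statistic is symmetric under sign flips and shift-invariant", {
  set.seed(5)
  conc <- rep(c(0, 0.1, 1, 10), each = 3)
  vals <- rnorm(12) + conc / 8
  sp <- williams_stat(vals, conc, direction = 1)
  sm <- williams_stat(-vals, conc, direction = -1)
  expect_equal(as.numeric(sp), as.numeric(sm), tolerance = 1e-12)
  shifted <- williams_stat(vals + 7.3, conc, direction = 1)
  expect_equal(as.numeric(sp), as.numeric(shifted), tolerance = 1e-9)
})

test_that("constant genes give statistic 0 and p 1", {
  d <- tbbpa_design()
  conc <- design_conc(d)
  m <- tibble::tibble(gene_id = "flat")
  vals <- rep(5, length(conc))
  for (i in seq_along(conc)) m[[paste0("s", i)]] <- vals[i]
  sheet <- tibble::tibble(sample_id = paste0("s", seq_along(conc)),
                          concentration_uM = conc,
                          replicate = rep(paste0("R", 1:3), 5))
  res <- williams_trend(m, sheet, n_permutations = 999, seed = 1)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
  expect_false(res$passes)
})

test_that("monotone 2-fold shifts pass and the fc gate shrinks the pass set", {
  d <- tbbpa_design()
  conc <- design_conc(d)
  set.seed(6)
  n_genes <- 60
  m <- matrix(rnorm(n_genes * length(conc), 5, 0.15), n_genes)
  # first 20 genes ramp up to +1 log2 (2-fold) at the top dose
  ramp <- log2(2) * (conc / max(conc))^0.3
  m[1:20, ] <- m[1:20, ] + rep(ramp, each = 20)
  counts <- tibble::tibble(gene_id = sprintf("g%02d", 1:n_genes))
  for (i in seq_along(conc)) counts[[paste0("s", i)]] <- m[, i]
  sheet <- tibble::tibble(sample_id = paste0("s", seq_along(conc)),
                          concentration_uM = conc,
                          replicate = rep(paste0("R", 1:3), 5))
  res <- williams_trend(counts, sheet, n_permutations = 1999, seed = 2)
  expect_gt(mean(res$passes[1:20]), 0.8)
  stricter <- res$p < 0.05 & res$max_fc >= 2.5
  expect_true(all(which(stricter) %in% which(res$passes)))
  expect_true(all(res$max_fc >= 1))
  # direction of the planted signal is recovered
  expect_true(all(res$direction[1:20] == 1))
})

test_that("permutation p is invariant to adding a constant", {
  d <- tbbpa_design()
  conc <- design_conc(d)
  set.seed(7)
  vals <- rnorm(length(conc), 5, 0.3) + 0.2 * log10(conc + 0.001)
  mk <- function(v) {
    counts <- tibble::tibble(gene_id = "g1")
    for (i in seq_along(conc)) counts[[paste0("s", i)]] <- v[i]
    counts
  }
  sheet <- tibble::tibble(sample_id = paste0("s", seq_along(conc)),
                          concentration_uM = conc,
                          replicate = rep(paste0("R", 1:3), 5))
  r1 <- williams_trend(mk(vals), sheet, n_permutations = 999, seed = 3)
  r2 <- williams_trend(mk(vals + 4.2), sheet, n_permutations = 999, seed = 3)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-9)
  expect_equal(r1$p, r2$p)
})
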