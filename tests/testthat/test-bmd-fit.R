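conc5 <- function() rep(c(0, 0.00292, 0.0292, 0.292, 2.92), each = 3)

test_that("model evaluation matches closed forms and anchors at background", {
  expect_equal(evaluate_model("hill", list(a = 0, v = 2, n = 1, k = 10), 10), 1)
  expect_equal(evaluate_model("power", list(a = 1, b = 0.5, p = 2), 4), 9)
  params <- list(
    linear = list(a = 2, b = 1),
    poly2 = list(a = 2, b = 1, d = -0.1),
    power = list(a = 2, b = 1, p = 1.5),
    hill = list(a = 2, v = 1, n = 2, k = 1),
    exp2 = list(a = 2, b = 0.5, s = 1),
    exp3 = list(a = 2, b = 0.5, d = 2, s = -1),
    exp4 = list(a = 2, b = 0.5, cc = 3),
    exp5 = list(a = 2, b = 0.5, cc = 0.5, d = 2)
  )
  for (mid in names(params)) {
    expect_equal(evaluate_model(mid, params[[mid]], 0), 2,
                 info = mid, tolerance = 1e-12)
  }
})

test_that("out-of-bound parameters are rejected", {
  expect_error(evaluate_model("power", list(a = 0, b = 1, p = 20), 1),
               "exponent")
  expect_error(evaluate_model("hill", list(a = 0, v = 1, n = 0.2, k = 1), 1),
               "coefficient")
  expect_error(evaluate_model("hill", list(a = 0, v = 1, n = 1, k = -1), 1),
               "k must be")
  expect_error(evaluate_model("exp5", list(a = 0, b = 1, cc = 2, d = 25), 1),
               "shape")
  expect_error(evaluate_model("linear", list(a = 0, b = 1), -1), ">= 0")
})

test_that("noiseless linear data are interpolated essentially exactly", {
  conc <- conc5()
  y <- 3 + 0.7 * conc
  f <- fit_model(y, conc, "linear")
  expect_lt(abs(f$params$b - 0.7), 1e-6)
  expect_lt(f$rss, 1e-10)
})

test_that("noiseless hill parameters are recovered to 1e-3 relative", {
  conc <- conc5()
  truth <- list(a = 5, v = 2, n = 2, k = 0.3)
  y <- evaluate_model("hill", truth, conc)
  f <- fit_model(y, conc, "hill")
  for (nm in names(truth)) {
    expect_lt(abs(f$params[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 1e-3)
  }
})

test_that("AIC bookkeeping is consistent for nested polynomials", {
  conc <- conc5()
  set.seed(12)
  y <- 2 + 0.5 * conc + rnorm(length(conc), 0, 0.1)
  flin <- fit_model(y, conc, "linear")
  fq <- fit_model(y, conc, "poly2")
  # poly2 nests linear: likelihood never lower, AIC penalty at most +2
  expect_gte(fq$loglik, flin$loglik - 1e-6)
  expect_lte(fq$aic, flin$aic + 2 + 1e-6)
  expect_equal(flin$aic, 2 * 3 - 2 * flin$loglik)
})

test_that("nested exponential models never lose likelihood", {
  conc <- conc5()
  set.seed(13)
  for (i in 1:6) {
    y <- 5 + 1.5 * (1 - exp(-conc / 0.3)) + rnorm(length(conc), 0, 0.2)
    f2 <- fit_model(y, conc, "exp2"); f3 <- fit_model(y, conc, "exp3")
    f4 <- fit_model(y, conc, "exp4"); f5 <- fit_model(y, conc, "exp5")
    expect_gte(f3$loglik, f2$loglik - 1e-6)
    expect_gte(f5$loglik, f4$loglik - 1e-6)
  }
})

test_that("model selection prefers curvature when the truth is sigmoidal", {
  conc <- conc5()
  y <- evaluate_model("hill", list(a = 5, v = 2, n = 3, k = 0.1), conc)
  fits <- lapply(c("linear", "hill", "exp4"), function(m) fit_model(y, conc, m))
  best <- select_best(fits)
  expect_true(best$model_id %in% c("hill", "exp4"))
  expect_lt(best$aic, fits[[1]]$aic)
})

test_that("score ties break toward fewer parameters then suite order", {
  mk <- function(id, npar, score) {
    structure(list(model_id = id, npar = npar, aic = score, aicc = score),
              class = "dr_fit")
  }
  f1 <- mk("hill", 4L, 10); f2 <- mk("linear", 2L, 10); f3 <- mk("poly2", 3L, 12)
  expect_identical(select_best(list(f1, f2, f3))$model_id, "linear")
  f4 <- mk("exp2", 2L, 10)
  expect_identical(select_best(list(f4, f2))$model_id, "linear")
  expect_null(select_best(list(NULL, NULL)))
})

test_that("BMD solves the benchmark-response crossing", {
  conc <- conc5()
  ylin <- 1 + 1 * conc
  flin <- fit_model(ylin, conc, "linear")
  expect_equal(compute_bmd(flin, control_sd = 1, bmr_factor = 1), 1,
               tolerance = 1e-6)

  # hill: 2c/(10+c) = 1 at c = 10 (conc rescaled so 10 is in range)
  conc2 <- rep(c(0, 1, 3, 10, 30), each = 3)
  yh <- evaluate_model("hill", list(a = 0, v = 2, n = 1, k = 10), conc2)
  fh <- fit_model(yh, conc2, "hill")
  expect_equal(compute_bmd(fh, 1, 1), 10, tolerance = 1e-3)

  # doubling the benchmark response never shrinks the BMD
  b1 <- compute_bmd(fh, 0.4, 1)
  b2 <- compute_bmd(fh, 0.8, 1)
  expect_gte(b2, b1)
})

test_that("bounds collapse onto the BMD for noiseless data", {
  conc <- conc5()
  set.seed(14)
  y <- 5 + 1.2 * (conc / 2.92) + rnorm(length(conc), 0, 1e-6)
  f <- fit_model(y, conc, "linear")
  bmd <- compute_bmd(f, 0.4, 1)
  bb <- bmd_bounds(f, y, conc, bmd, 0.4)
  expect_lt(bb$bmdu / bb$bmdl, 1.05)
  expect_true(bb$bmdl <= bmd && bmd <= bb$bmdu)
})

test_that("profile and bootstrap intervals agree on a moderate-noise gene", {
  conc <- conc5()
  set.seed(15)
  y <- 5 + 0.8 * (conc / 2.92) + rnorm(length(conc), 0, 0.15)
  f <- fit_model(y, conc, "linear")
  bmd <- compute_bmd(f, 0.3, 1)
  prof <- bmd_bounds(f, y, conc, bmd, 0.3)
  boot <- tpodr:::boot_bmd_interval(f, y, conc, 0.3, 0.90, 2000, 1)
  expect_identical(prof$method, "profile")
  expect_lt(abs(log(prof$bmdl / boot$bmdl)), log(1.25))
  expect_lt(abs(log(prof$bmdu / boot$bmdu)), log(1.25))
})

test_that("BMD estimates are exactly scale-equivariant", {
  conc <- conc5()
  set.seed(16)
  y <- 5 + 1.5 * (1 - exp(-conc / 0.2)) + rnorm(length(conc), 0, 0.2)
  counts <- tibble::tibble(gene_id = "g1")
  for (i in seq_along(conc)) counts[[paste0("s", i)]] <- y[i]
  sheet <- function(cc) tibble::tibble(
    sample_id = paste0("s", seq_along(cc)), concentration_uM = cc,
    replicate = rep(paste0("R", 1:3), 5))
  r1 <- fit_dose_response(counts, sheet(conc), seed = 2)
  r2 <- fit_dose_response(counts, sheet(conc * 100), seed = 2)
  expect_equal(r2$bmd, r1$bmd * 100, tolerance = 1e-6)
  expect_equal(r2$bmdl, r1$bmdl * 100, tolerance = 0.02)
  expect_equal(r2$bmdu, r1$bmdu * 100, tolerance = 0.02)
})

test_that("interval ordering bmdl <= bmd <= bmdu holds across a simulation", {
  d <- tbbpa_design()
  tr <- make_truth(d, n_genes = 40, prop_responsive = 1, seed = 18)
  conc <- design_conc(d)
  norm <- tibble::tibble(gene_id = tr$gene_id)
  set.seed(18)
  prof <- t(vapply(tr$curve, tpodr:::eval_truth_curve, numeric(length(conc)),
                   conc = conc))
  mat <- 5 + prof + matrix(rnorm(length(prof), 0, 0.3), nrow(prof))
  for (i in seq_along(conc)) norm[[paste0("s", i)]] <- mat[, i]
  sheet <- tibble::tibble(sample_id = paste0("s", seq_along(conc)),
                          concentration_uM = conc,
                          replicate = rep(paste0("R", 1:3), 5))
  fits <- fit_dose_response(norm, sheet, seed = 3)
  ok <- is.finite(fits$bmd) & is.finite(fits$bmdl) & is.finite(fits$bmdu)
  expect_gt(sum(ok), 20)
  expect_true(all(fits$bmdl[ok] <= fits$bmd[ok] + 1e-9))
  expect_true(all(fits$bmd[ok] <= fits$bmdu[ok] + 1e-9))
})
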