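# Ground-truth dose-response curves for the simulator. Curves live on the
# log2-expression scale: curve(c) is the log2 shift relative to control, so
# curve(0) = 0 for every family.

TRUTH_CURVES <- c("flat", "linear", "hill", "expsat")

# Evaluate a truth curve (log2 shift) at concentrations conc.
eval_truth_curve <- function(curve, conc) {
  p <- curve$params
  switch(curve$type,
    flat = rep(0, length(conc)),
    # slope b in log2 units per µM
    linear = p$b * conc,
    # sigmoidal: v * c^n / (k^n + c^n)
    hill = ifelse(conc == 0, 0, p$v * conc^p$n / (p$k^p$n + conc^p$n)),
    # saturating exponential: v * (1 - exp(-c / tau))
    expsat = p$v * (1 - exp(-conc / p$tau)),
    abort(sprintf("unknown truth curve type '%s'", curve$type))
  )
}

# Smallest c > 0 where |f(c) - f(0)| = bmr, scanning (0, upper] on a dense
# log-spaced grid then polishing with uniroot. Returns list(bmd, multiple).
first_crossing <- function(f, bmr, upper, n_grid = 400L) {
  f0 <- f(0)
  g <- function(c) abs(f(c) - f0) - bmr
  grid <- c(0, exp(seq(log(upper * 1e-7), log(upper), length.out = n_grid)))
  gv <- vapply(grid, g, numeric(1))
  sign_change <- which(gv[-1] * gv[-length(gv)] <= 0 & gv[-1] != gv[-length(gv)])
  if (!length(sign_change)) {
    return(list(bmd = NA_real_, multiple = FALSE))
  }
  i <- sign_change[1]
  root <- if (grid[i] == 0 && gv[i + 1] == 0) {
    grid[i + 1]
  } else {
    tryCatch(
      uniroot(g, lower = max(grid[i], upper * 1e-12), upper = grid[i + 1],
              tol = upper * 1e-10)$root,
      error = function(e) grid[i + 1]
    )
  }
  list(bmd = root, multiple = length(sign_change) > 1L)
}

#' Concentration at which a ground-truth curve reaches a benchmark response
#'
#' Solves `|curve(c) - curve(0)| = bmr` for the smallest positive
#' concentration by a bracketing root search on a dense log grid; used as the
#' oracle for BMD-recovery testing of the fitting machinery.
#'
#' @param curve A list with `type` (one of `"flat"`, `"linear"`, `"hill"`,
#'   `"expsat"`) and `params` (named list of curve parameters on the log2
#'   scale), as stored in the truth table's `curve` list-column.
#' @param bmr Benchmark response in log2 units (> 0).
#' @param max_conc Top design concentration; the search extends to
#'   `10 * max_conc`.
#' @return The crossing concentration in µM, or `NA` if the curve never
#'   departs from control by `bmr` within the search range. A non-monotone
#'   curve with several crossings returns the smallest, with a warning.
#' @export
true_bmd_of <- function(curve, bmr, max_conc) {
  stopifnot_scalar_num(bmr, "bmr", positive = TRUE)
  stopifnot_scalar_num(max_conc, "max_conc", positive = TRUE)
  if (curve$type == "flat") return(NA_real_)
  res <- first_crossing(function(c) eval_truth_curve(curve, c), bmr,
                        upper = 10 * max_conc)
  if (res$multiple) warn("curve crosses the benchmark response more than once; returning the smallest crossing")
  res$bmd
}

# Solve curve parameters so that the curve crosses +/- bmr exactly at c_star.
# amp is the signed asymptotic (hill/expsat) or top-dose (linear) amplitude;
# |amp| must exceed bmr for the saturating shapes.
solve_truth_curve <- function(shape, c_star, amp, bmr, hill_n, cmax) {
  s <- sign(amp)
  v <- abs(amp)
  switch(shape,
    linear = list(type = "linear", params = list(b = s * bmr / c_star)),
    hill = {
      k <- c_star * (v / bmr - 1)^(1 / hill_n)
      list(type = "hill", params = list(v = s * v, n = hill_n, k = k))
    },
    expsat = {
      tau <- -c_star / log(1 - bmr / v)
      list(type = "expsat", params = list(v = s * v, tau = tau))
    }
  )
}

#' Simulate a per-gene ground-truth table for a dose design
#'
#' Draws baseline expression, negative-binomial dispersion, and — for a
#' minority of responsive genes — a dose-response curve on the log2 scale.
#' Responsive genes split evenly across Hill (sigmoidal), saturating
#' exponential, and linear shapes, half up- and half down-regulated. Each
#' responsive gene is assigned a target benchmark-dose concentration first
#' (log-uniform over the nonzero design range by default, or drawn from
#' `bmd_log10_mix`) and its curve parameters are solved so the log2 shift
#' crosses `bmr` exactly there; `true_bmd` therefore always lies inside the
#' tested range. Asymptotic amplitudes are drawn between `2 * bmr` and 3
#' log2 units; linear-shape targets are kept in the top decade so slopes
#' stay physiological.
#'
#' @param design A [make_design()] object.
#' @param n_genes Number of genes.
#' @param prop_responsive Fraction of genes given a dose-dependent shift.
#' @param bmr Benchmark response (log2 units) defining `true_bmd`. The
#'   default (`NULL`) uses the per-sample log2-scale noise SD implied by the
#'   median dispersion, `sqrt(exp(dispersion_meanlog)) / log(2)`, so
#'   recorded true BMDs correspond to the 1-SD benchmark response the
#'   analysis applies downstream.
#' @param bmd_log10_mix Optional Gaussian-mixture spec for target BMDs on the
#'   log10 µM axis: a list with `means`, `sds`, `weights`. Draws are clipped
#'   to the nonzero design range.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters for baseline
#'   mean counts (before library-size scaling).
#' @param dispersion_meanlog,dispersion_sdlog Lognormal parameters for the
#'   NB dispersion phi (variance = mu + phi * mu^2).
#' @param seed Integer seed.
#'
#' @return Tibble with columns `gene_id`, `baseline_mean`, `dispersion`,
#'   `responsive`, `curve` (list-column), `true_bmd`.
#' @export
make_truth <- function(design, n_genes = 5000, prop_responsive = 0.10,
                       bmr = NULL, bmd_log10_mix = NULL,
                       baseline_meanlog = log(60), baseline_sdlog = 1.3,
                       dispersion_meanlog = log(0.05), dispersion_sdlog = 0.4,
                       seed = 1) {
  stopifnot(inherits(design, "dose_design"))
  stopifnot_scalar_num(n_genes, "n_genes", positive = TRUE)
  bmr <- bmr %||% (sqrt(exp(dispersion_meanlog)) / log(2))
  stopifnot_scalar_num(bmr, "bmr", positive = TRUE)
  if (prop_responsive < 0 || prop_responsive > 1) {
    abort("`prop_responsive` must be in [0, 1].")
  }
  cmax <- max(design$concentrations)
  cmin <- min(design$concentrations[design$concentrations > 0])
  with_seed(child_seed(seed, 0L), function() {
    n_resp <- round(n_genes * prop_responsive)
    responsive <- c(rep(TRUE, n_resp), rep(FALSE, n_genes - n_resp))
    shape <- rep(NA_character_, n_genes)
    if (n_resp > 0) {
      shape[seq_len(n_resp)] <- rep_len(c("hill", "expsat", "linear"), n_resp)
    }
    baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    phi <- rlnorm(n_genes, dispersion_meanlog, dispersion_sdlog)
    amp <- runif(n_genes, max(2 * bmr, 0.585), 3) *
      sample(c(-1, 1), n_genes, replace = TRUE)
    target <- if (is.null(bmd_log10_mix)) {
      exp(runif(n_genes, log(cmin), log(cmax)))
    } else {
      comp <- sample(seq_along(bmd_log10_mix$means), n_genes, replace = TRUE,
                     prob = bmd_log10_mix$weights)
      draw <- rnorm(n_genes, bmd_log10_mix$means[comp], bmd_log10_mix$sds[comp])
      pmin(pmax(10^draw, cmin / 2), cmax)
    }
    # keep linear targets in the top decade: slope = bmr / target, so small
    # targets would imply enormous top-dose shifts
    lin <- !is.na(shape) & shape == "linear"
    target[lin] <- pmax(target[lin], cmax / 8)
    hill_n <- runif(n_genes, 1, 4)
    curves <- purrr::pmap(
      list(responsive, shape, target, amp, hill_n),
      function(resp, sh, cs, a, n) {
        if (!resp) return(list(type = "flat", params = list()))
        solve_truth_curve(sh, cs, a, bmr, n, cmax)
      }
    )
    tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      baseline_mean = baseline,
      dispersion = phi,
      responsive = responsive,
      curve = curves,
      true_bmd = ifelse(responsive, target, NA_real_)
    )
  })
}
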