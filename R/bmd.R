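# Benchmark-dose computation and confidence bounds for fitted dose-response
# models. The BMD solves |f(c) - f(0)| = bmr; bounds come from a
# profile-likelihood interval on the BMD (the model is re-parameterized so
# the scale parameter is determined by the BMD constraint), with a
# parametric-bootstrap percentile interval as fallback.

#' Benchmark dose of a fitted model
#'
#' Smallest concentration `c > 0` at which the fitted curve departs from its
#' background by `bmr_factor * control_sd` log2 units, found by a bracketed
#' root search on `(0, 10 * conc_max]`.
#'
#' @param fit A `dr_fit` from [fit_model()].
#' @param control_sd Control/background standard deviation (log2 units).
#' @param bmr_factor Benchmark response as a multiple of `control_sd`
#'   (default 1).
#' @return BMD in µM, or `NA` if the curve never reaches the benchmark
#'   response within the search range.
#' @export
compute_bmd <- function(fit, control_sd, bmr_factor = 1) {
  stopifnot(inherits(fit, "dr_fit"))
  stopifnot_scalar_num(control_sd, "control_sd")
  stopifnot_scalar_num(bmr_factor, "bmr_factor", positive = TRUE)
  bmr <- bmr_factor * control_sd
  if (bmr <= 0) return(NA_real_)
  f <- function(c) evaluate_model(fit$model_id, fit$params, c)
  first_crossing(f, bmr, upper = 10 * fit$conc_max)$bmd
}

# warm nonlinear start vector (scaled space) from a fitted model
warm_from_fit <- function(fit) {
  ps <- fit$params_scaled
  switch(fit$model_id,
    power = ps$p,
    hill = c(ps$n, log(ps$k)),
    exp2 = log(max(ps$b, 1e-6)),
    exp3 = c(log(max(ps$b, 1e-6)), ps$d),
    exp4 = log(max(ps$b, 1e-6)),
    exp5 = c(log(max(ps$b, 1e-6)), ps$d),
    NULL
  )
}

# profiled RSS under the constraint f(delta) - f(0) = Delta (scaled space)
profile_rss <- function(fit, delta, Delta, y, t) {
  model_id <- fit$model_id
  guard <- function(x) if (!is.finite(x) || abs(x) < 1e-12) NA_real_ else x
  if (model_id == "linear") {
    b <- Delta / delta
    r <- y - b * t
    return(sum((r - mean(r))^2))
  }
  if (model_id == "poly2") {
    f <- ls_fit(y - (Delta / delta) * t, t^2 - delta * t)
    return(f$rss)
  }
  sgn <- fit$params_scaled$s %||% NA
  obj <- function(th) {
    rss <- switch(model_id,
      power = {
        p <- th[1]
        bcf <- Delta / delta^p
        r <- y - bcf * ifelse(t == 0, 0, t^p)
        sum((r - mean(r))^2)
      },
      hill = {
        n <- th[1]; k <- exp(th[2])
        v <- Delta * (k^n + delta^n) / delta^n
        bas <- ifelse(t == 0, 0, t^n / (k^n + t^n))
        r <- y - v * bas
        sum((r - mean(r))^2)
      },
      exp2 = {
        b <- exp(th[1])
        den <- guard(exp(sgn * b * delta) - 1)
        if (is.na(den)) return(1e30)
        a <- Delta / den
        sum((y - a * exp(sgn * b * t))^2)
      },
      exp3 = {
        b <- exp(th[1])
        den <- guard(exp(sgn * (b * delta)^th[2]) - 1)
        if (is.na(den)) return(1e30)
        a <- Delta / den
        h <- exp(sgn * ifelse(t == 0, 0, (b * t)^th[2]))
        sum((y - a * h)^2)
      },
      exp4 = {
        # f = A + B exp(-b t); constraint: B (exp(-b delta) - 1) = Delta
        b <- exp(th[1])
        den <- guard(exp(-b * delta) - 1)
        if (is.na(den)) return(1e30)
        B <- Delta / den
        r <- y - B * exp(-b * t)
        sum((r - mean(r))^2)
      },
      exp5 = {
        b <- exp(th[1])
        den <- guard(exp(-(b * delta)^th[2]) - 1)
        if (is.na(den)) return(1e30)
        B <- Delta / den
        r <- y - B * exp(-ifelse(t == 0, 0, (b * t)^th[2]))
        sum((r - mean(r))^2)
      }
    )
    safe_rss(rss)
  }
  box <- nl_box(model_id)
  warm <- warm_from_fit(fit)
  warm <- pmin(pmax(warm, box$lo), box$hi)
  mid <- (box$lo + box$hi) / 2
  starts <- rbind(warm, mid)
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = box$lo, upper = box$hi, control = list(maxit = 100)),
      error = function(e) NULL
    )
    if (!is.null(res) && res$value < best) best <- res$value
  }
  best
}

#' Confidence bounds on a benchmark dose
#'
#' Two-sided profile-likelihood interval on the BMD at level `confidence`
#' (default 90%, i.e. a 95% one-sided BMDL): the model is constrained to
#' pass through the benchmark response at a candidate BMD, the remaining
#' parameters are re-optimized, and the bound sits where the concentrated
#' Gaussian deviance `n log(RSS_c / RSS_hat)` rises by the chi-square(1)
#' quantile. If profiling fails on a side, a parametric-bootstrap percentile
#' interval (refitting the selected model on `n_boot` resamples) is used and
#' flagged. A side that never crosses within the search box `[bmd/1e4,
#' 100 * conc_max]` returns the box edge flagged `"boundary"`.
#'
#' @param fit A `dr_fit`.
#' @param values,conc The data the model was fitted to.
#' @param bmd The BMD from [compute_bmd()] (µM).
#' @param bmr Benchmark response in log2 units (`bmr_factor * control_sd`).
#' @param confidence Two-sided coverage (default 0.90).
#' @param n_boot Bootstrap draws for the fallback (default 2000).
#' @param seed Seed for the bootstrap fallback.
#' @return List with `bmdl`, `bmdu`, `method` (`"profile"` or
#'   `"bootstrap"`), `flag` (`"ok"` or `"boundary"`).
#' @export
bmd_bounds <- function(fit, values, conc, bmd, bmr, confidence = 0.90,
                       n_boot = 2000, seed = 1) {
  stopifnot(inherits(fit, "dr_fit"), is.finite(bmd), bmd > 0, bmr > 0)
  cmax <- fit$conc_max
  t <- conc / cmax
  n <- length(values)
  f0 <- evaluate_model(fit$model_id, fit$params, 0)
  fb <- evaluate_model(fit$model_id, fit$params, bmd)
  s_resp <- sign(fb - f0)
  if (s_resp == 0) s_resp <- 1
  Delta <- s_resp * bmr
  # reference RSS: the constrained optimum at the BMD itself equals the
  # unconstrained optimum in exact arithmetic; take the better of the two so
  # optimizer slack at tiny RSS cannot push the deviance negative
  rss_at_bmd <- tryCatch(
    profile_rss(fit, bmd / cmax, Delta, values, conc / cmax),
    error = function(e) Inf
  )
  rss_hat <- max(min(fit$rss, rss_at_bmd), n * SIGMA2_FLOOR)
  Tcrit <- qchisq(confidence, 1)
  dev <- function(ld) {
    rc <- max(profile_rss(fit, exp(ld), Delta, values, t), n * SIGMA2_FLOOR)
    n * log(rc / rss_hat) - Tcrit
  }
  t_bmd <- bmd / cmax
  lo_box <- t_bmd * 1e-4
  hi_box <- 100

  side <- function(edge, lower_side) {
    d_edge <- tryCatch(dev(log(edge)), error = function(e) NA_real_)
    if (!is.finite(d_edge)) return(NULL)
    if (d_edge <= 0) return(list(val = edge * cmax, flag = "boundary"))
    root <- tryCatch(
      uniroot(dev,
              lower = if (lower_side) log(edge) else log(t_bmd),
              upper = if (lower_side) log(t_bmd) else log(edge),
              tol = 5e-3)$root,
      error = function(e) NA_real_
    )
    if (!is.finite(root)) return(NULL)
    list(val = exp(root) * cmax, flag = "ok")
  }

  lo <- side(lo_box, TRUE)
  hi <- side(hi_box, FALSE)
  if (!is.null(lo) && !is.null(hi)) {
    return(list(bmdl = min(lo$val, bmd), bmdu = max(hi$val, bmd),
                method = "profile",
                flag = if (lo$flag == "boundary" || hi$flag == "boundary")
                  "boundary" else "ok"))
  }
  boot_bmd_interval(fit, values, conc, bmr, confidence, n_boot, seed)
}

# parametric bootstrap percentile interval on the BMD, refitting the
# selected model on simulated residuals
boot_bmd_interval <- function(fit, values, conc, bmr, confidence, n_boot,
                              seed) {
  cmax <- fit$conc_max
  t <- conc / cmax
  mu <- evaluate_model(fit$model_id, fit$params, conc)
  warm <- warm_from_fit(fit)
  draws <- with_seed(child_seed(seed, 4242L), function() {
    vapply(seq_len(n_boot), function(i) {
      ystar <- mu + rnorm(length(values), 0, fit$sigma)
      f <- tryCatch(
        fit_scaled(fit$model_id, ystar, t, n_starts = 3L,
                   warm = if (is.null(warm)) NULL else rbind(warm)),
        error = function(e) NULL
      )
      if (is.null(f)) return(NA_real_)
      ff <- finish_fit(fit$model_id, f, length(values), cmax)
      g <- function(c) evaluate_model(ff$model_id, ff$params, c)
      first_crossing(g, bmr, upper = 10 * cmax)$bmd
    }, numeric(1))
  })
  ok <- draws[is.finite(draws)]
  if (length(ok) < n_boot / 4) {
    return(list(bmdl = NA_real_, bmdu = NA_real_, method = "bootstrap",
                flag = "boundary"))
  }
  alpha <- (1 - confidence) / 2
  qs <- quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(bmdl = qs[1], bmdu = qs[2], method = "bootstrap", flag = "ok")
}

#' Fit the dose-response suite and compute BMDs for many genes
#'
#' Runs [fit_model()] for every model in the suite on each gene, selects the
#' lowest-AIC model, and computes the BMD and its profile-likelihood bounds.
#' Genes are typically those passing the Williams trend prefilter.
#'
#' @param norm Normalized log2 expression tibble from [normalize_log2()].
#' @param samples Sample sheet tibble.
#' @param genes Character vector of gene ids to fit (default: all rows).
#' @param models Model suite (default: all eight).
#' @param bmr_factor Benchmark response in multiples of the control SD.
#' @param control_sd How the per-gene control/background SD defining the
#'   benchmark response is estimated: `"moderated"` (default; the selected
#'   model's residual SD shrunk toward the cohort median on the variance
#'   scale, stabilising the BMR at 3 replicates), `"residual"` (the
#'   unshrunk degrees-of-freedom-corrected residual SD), or `"control"`
#'   (sample SD of the control replicates).
#' @param criterion Model-selection score, `"aicc"` (default) or `"aic"`;
#'   see [select_best()].
#' @param confidence Two-sided confidence level for the BMD bounds.
#' @param n_starts Multi-start points per nonlinear model.
#' @param seed Seed (bootstrap fallback only; profiling is deterministic).
#' @return A `tpod_fits` tibble: `gene_id`, `model`, `params` (list-column),
#'   `npar`, `loglik`, `aic`, `bmd`, `bmdl`, `bmdu`, `control_sd`, `bmr`,
#'   `fit_status`, `bound_method`. Attributes `max_conc` and
#'   `min_nonzero_conc` record the design range for [postfilter_bmds()].
#' @export
fit_dose_response <- function(norm, samples, genes = NULL,
                              models = MODEL_IDS, bmr_factor = 1,
                              control_sd = c("moderated", "residual",
                                             "control"),
                              criterion = c("aicc", "aic"),
                              confidence = 0.90, n_starts = 7L, seed = 1) {
  control_sd <- match.arg(control_sd)
  criterion <- match.arg(criterion)
  samples <- align_samples(norm, samples)
  conc <- samples$concentration_uM
  m <- counts_to_matrix(norm)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) abort(paste0("genes not in matrix: ",
                                      paste(head(missing, 5), collapse = ", ")))
    m <- m[genes, , drop = FALSE]
  }
  cmax <- max(conc)
  t <- conc / cmax
  n <- length(conc)

  # pass 1: fit the suite and select the best model per gene
  best_fits <- purrr::map(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    fits <- list()
    for (mid in models) {
      f <- tryCatch(
        fit_scaled(mid, y, t, n_starts = n_starts,
                   warm = nested_warm(mid, fits)),
        error = function(e) NULL
      )
      fits[[mid]] <- if (is.null(f)) NULL else finish_fit(mid, f, n, cmax)
    }
    select_best(fits, criterion = criterion)
  })

  sig_res <- vapply(best_fits, function(b) {
    if (is.null(b)) NA_real_
    else sqrt(max(b$rss / max(n - b$npar, 1), SIGMA2_FLOOR))
  }, numeric(1))

  # pass 2: benchmark response, BMD, bounds
  sd_use <- switch(control_sd,
    residual = sig_res,
    control = vapply(seq_len(nrow(m)),
                     function(i) sd(m[i, conc == 0]), numeric(1)),
    moderated = {
      fin <- is.finite(sig_res)
      if (sum(fin) >= 10) {
        s0sq <- median(sig_res[fin]^2)
        d0 <- 8
        df_i <- vapply(best_fits, function(b) {
          if (is.null(b)) NA_real_ else max(n - b$npar, 1)
        }, numeric(1))
        sqrt((d0 * s0sq + df_i * sig_res^2) / (d0 + df_i))
      } else {
        sig_res
      }
    }
  )

  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    gid <- rownames(m)[i]
    best <- best_fits[[i]]
    if (is.null(best)) {
      return(tibble(gene_id = gid, model = NA_character_,
                    params = list(NULL), npar = NA_integer_,
                    loglik = NA_real_, aic = NA_real_, bmd = NA_real_,
                    bmdl = NA_real_, bmdu = NA_real_, control_sd = NA_real_,
                    bmr = NA_real_, fit_status = "failed",
                    bound_method = NA_character_))
    }
    y <- m[i, ]
    sd_ctrl <- sd_use[i]
    bmr <- bmr_factor * sd_ctrl
    bmd <- compute_bmd(best, sd_ctrl, bmr_factor)
    bb <- list(bmdl = NA_real_, bmdu = NA_real_, method = NA_character_,
               flag = "ok")
    if (is.finite(bmd)) {
      bb <- bmd_bounds(best, y, conc, bmd, bmr, confidence = confidence,
                       seed = seed)
    }
    status <- if (bb$flag == "boundary" || best$status == "boundary") {
      "boundary"
    } else {
      "ok"
    }
    tibble(gene_id = gid, model = best$model_id, params = list(best$params),
           npar = best$npar, loglik = best$loglik, aic = best$aic,
           bmd = bmd, bmdl = bb$bmdl, bmdu = bb$bmdu,
           control_sd = sd_ctrl, bmr = bmr, fit_status = status,
           bound_method = bb$method)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "max_conc") <- cmax
  attr(out, "min_nonzero_conc") <- min(conc[conc > 0])
  class(out) <- c("tpod_fits", class(out))
  out
}
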