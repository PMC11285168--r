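# Maximum-likelihood fitting of the continuous model suite under
# homoscedastic Gaussian error on the log2 scale. All nonlinear searches run
# on the scaled concentration t = c / c_top with fixed parameter boxes, so
# fitted BMDs are exactly scale-equivariant; parameters are converted back
# to natural µM units in the returned records.

SIGMA2_FLOOR <- 1e-18

# ordinary least squares of y on cbind(1, B); returns coef + rss
ls_fit <- function(y, B) {
  X <- cbind(1, B)
  f <- .lm.fit(X, y)
  list(coef = f$coefficients, rss = sum(f$residuals^2))
}

# pure scaling fit y ~ a * h
proj_fit <- function(y, h) {
  den <- sum(h * h)
  a <- if (den > 0) sum(y * h) / den else 0
  list(a = a, rss = sum((y - a * h)^2))
}

gauss_loglik <- function(rss, n) {
  s2 <- max(rss / n, SIGMA2_FLOOR)
  -n / 2 * (log(2 * pi * s2) + 1)
}

# scaled-parameter -> natural-parameter conversion
params_to_natural <- function(model_id, p, cmax) {
  q <- p
  switch(model_id,
    linear = { q$b <- p$b / cmax },
    poly2 = { q$b <- p$b / cmax; q$d <- p$d / cmax^2 },
    power = { q$b <- p$b / cmax^p$p },
    hill = { q$k <- p$k * cmax },
    exp2 = , exp3 = , exp4 = , exp5 = { q$b <- p$b / cmax }
  )
  q
}

safe_rss <- function(x) if (is.finite(x)) x else 1e30

# model-specific profiled RSS objectives over the nonlinear parameters;
# linear parameters are solved analytically. th is the nonlinear vector.
rss_nonlinear <- function(model_id, th, y, t) {
  switch(model_id,
    power = {
      b <- ifelse(t == 0, 0, t^th[1])
      safe_rss(ls_fit(y, b)$rss)
    },
    hill = {
      n <- th[1]; k <- exp(th[2])
      b <- ifelse(t == 0, 0, t^n / (k^n + t^n))
      safe_rss(ls_fit(y, b)$rss)
    },
    exp2 = {
      h <- exp(th[2] * exp(th[1]) * t) # th[1] = log rate, th[2] = sign
      safe_rss(proj_fit(y, h)$rss)
    },
    exp3 = {
      h <- exp(th[3] * ifelse(t == 0, 0, (exp(th[1]) * t)^th[2]))
      safe_rss(proj_fit(y, h)$rss)
    },
    exp4 = safe_rss(exp45_profiled(y, exp(-exp(th[1]) * t))$rss),
    exp5 = {
      h <- exp(-ifelse(t == 0, 0, (exp(th[1]) * t)^th[2]))
      safe_rss(exp45_profiled(y, h)$rss)
    }
  )
}

# exp4/exp5 are linear in (A, B) once written f = A + B exp(-(b t)^d),
# with a = A + B (background) and cc = A / a (asymptote ratio); solve the
# linear part analytically and reject parameterizations with nonpositive
# background or asymptote
exp45_profiled <- function(y, h) {
  f <- ls_fit(y, h)
  A <- f$coef[1]; B <- f$coef[2]
  a <- A + B
  if (!is.finite(a) || a <= 1e-8 || !is.finite(A) || A / a <= 1e-6 ||
      A / a > 1e6) {
    return(list(rss = 1e30, a = NA_real_, cc = NA_real_))
  }
  list(rss = f$rss, a = a, cc = A / a)
}

# nonlinear parameter boxes in scaled space (named rows lo, hi)
nl_box <- function(model_id) {
  switch(model_id,
    power = list(lo = 0.5, hi = 18),
    hill = list(lo = c(0.5, log(1e-5)), hi = c(18, log(30))),
    # exponential rates are searched on the log scale: the dilution series
    # spans ~3 decades, so the rate must too
    exp2 = list(lo = log(1e-6), hi = log(1e4)),
    exp3 = list(lo = c(log(1e-6), 1), hi = c(log(1e4), 18)),
    exp4 = list(lo = log(1e-6), hi = log(1e4)),
    exp5 = list(lo = c(log(1e-6), 1), hi = c(log(1e4), 18)),
    NULL
  )
}

# multi-start bounded minimisation of rss_nonlinear; extra_starts are rows
# in the nonlinear parameter space (e.g. warm starts from a nested model)
optim_nl <- function(model_id, y, t, n_starts, extra_starts = NULL) {
  box <- nl_box(model_id)
  d <- length(box$lo)
  fixed_sign <- model_id %in% c("exp2", "exp3")
  obj_dim <- d
  grid <- det_lhs(max(n_starts, 5L), obj_dim)
  starts <- sweep(sweep(grid, 2, box$hi - box$lo, "*"), 2, box$lo, "+")
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)

  run_one <- function(th0, sgn, factr = 1e5) {
    obj <- function(th) {
      rss_nonlinear(model_id, if (fixed_sign) c(th, sgn) else th, y, t)
    }
    fit <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B", lower = box$lo, upper = box$hi,
            control = list(maxit = 200, factr = factr)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    # L-BFGS-B may land a few ulps outside the box
    fit$par <- pmin(pmax(fit$par, box$lo), box$hi)
    list(th = if (fixed_sign) c(fit$par, sgn) else fit$par, rss = fit$value,
         sgn = sgn,
         at_edge = any(abs(fit$par - box$lo) < 1e-7 * (1 + abs(box$lo))) ||
           any(abs(fit$par - box$hi) < 1e-7 * (1 + abs(box$hi))))
  }

  signs <- if (fixed_sign) c(1, -1) else NA
  best <- NULL
  for (sgn in signs) {
    # evaluate all starts cheaply, polish the best two
    vals <- apply(starts, 1, function(th0) {
      rss_nonlinear(model_id, if (fixed_sign) c(th0, sgn) else th0, y, t)
    })
    for (i in order(vals)[seq_len(min(2L, nrow(starts)))] ) {
      res <- run_one(starts[i, ], sgn)
      if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    }
  }
  if (!is.null(best)) {
    # tight final polish from the winning basin
    d_nl <- length(box$lo)
    res <- run_one(best$th[seq_len(d_nl)], best$sgn, factr = 10)
    if (!is.null(res) && res$rss <= best$rss) best <- res
    # derivative-free polish: gradient steps stall on the flat ridges of
    # weakly identified fits (e.g. hill with half-max beyond the top dose)
    box_obj <- function(th) {
      if (any(th < box$lo) || any(th > box$hi)) return(1e30)
      rss_nonlinear(model_id,
                    if (fixed_sign) c(th, best$sgn) else th, y, t)
    }
    nm <- tryCatch(
      if (d_nl == 1) {
        optimize(box_obj, lower = box$lo, upper = box$hi,
                 tol = 1e-10)[c("minimum", "objective")]
      } else {
        f <- optim(best$th[seq_len(d_nl)], box_obj, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-14))
        list(minimum = f$par, objective = f$value)
      },
      error = function(e) NULL
    )
    if (!is.null(nm) && nm$objective < best$rss) {
      th_nm <- pmin(pmax(nm$minimum, box$lo), box$hi)
      best$th <- if (fixed_sign) c(th_nm, best$sgn) else th_nm
      best$rss <- nm$objective
      best$at_edge <- any(abs(th_nm - box$lo) < 1e-7 * (1 + abs(box$lo))) ||
        any(abs(th_nm - box$hi) < 1e-7 * (1 + abs(box$hi)))
    }
  }
  best
}

# full fit of one model in scaled space; returns params list (scaled), rss,
# boundary flag, or NULL on failure
fit_scaled <- function(model_id, y, t, n_starts = 7L, warm = NULL) {
  n <- length(y)
  if (model_id == "linear") {
    f <- ls_fit(y, t)
    return(list(params = list(a = f$coef[1], b = f$coef[2]), rss = f$rss,
                boundary = FALSE))
  }
  if (model_id == "poly2") {
    f <- ls_fit(y, cbind(t, t^2))
    return(list(params = list(a = f$coef[1], b = f$coef[2], d = f$coef[3]),
                rss = f$rss, boundary = FALSE))
  }
  # nested fallbacks: seed exp3/exp5 from their 1-parameter-simpler parent
  # so the nested model can never lose likelihood, whoever the caller is
  if (model_id %in% c("exp3", "exp5")) {
    parent <- if (model_id == "exp3") "exp2" else "exp4"
    pf <- tryCatch(fit_scaled(parent, y, t, n_starts = n_starts),
                   error = function(e) NULL)
    if (!is.null(pf)) {
      warm <- rbind(warm, c(log(max(pf$params$b, 1e-6)), 1))
    }
  }
  if (model_id == "hill") {
    # data-driven half-max starts: scaled concentration where the response
    # first crosses half its observed range
    lev <- sort(unique(t))
    gm <- vapply(lev, function(l) mean(y[t == l]), numeric(1))
    dm <- gm - gm[1]
    half <- max(abs(dm)) / 2
    cross <- lev[which(abs(dm) >= half)[1]]
    if (is.finite(cross) && cross > 0) {
      warm <- rbind(warm, cbind(c(1, 2, 4), log(cross)))
    }
  }
  best <- optim_nl(model_id, y, t, n_starts, extra_starts = warm)
  if (is.null(best) || !is.finite(best$rss) || best$rss >= 1e29) return(NULL)
  th <- best$th
  params <- switch(model_id,
    power = {
      b <- ifelse(t == 0, 0, t^th[1])
      f <- ls_fit(y, b)
      list(a = f$coef[1], b = f$coef[2], p = th[1])
    },
    hill = {
      n_ <- th[1]; k <- exp(th[2])
      bas <- ifelse(t == 0, 0, t^n_ / (k^n_ + t^n_))
      f <- ls_fit(y, bas)
      list(a = f$coef[1], v = f$coef[2], n = n_, k = k)
    },
    exp2 = {
      b <- exp(th[1])
      h <- exp(th[2] * b * t)
      list(a = proj_fit(y, h)$a, b = b, s = th[2])
    },
    exp3 = {
      b <- exp(th[1])
      h <- exp(th[3] * ifelse(t == 0, 0, (b * t)^th[2]))
      list(a = proj_fit(y, h)$a, b = b, d = th[2], s = th[3])
    },
    exp4 = {
      b <- exp(th[1])
      pf <- exp45_profiled(y, exp(-b * t))
      list(a = pf$a, b = b, cc = pf$cc)
    },
    exp5 = {
      b <- exp(th[1])
      h <- exp(-ifelse(t == 0, 0, (b * t)^th[2]))
      pf <- exp45_profiled(y, h)
      list(a = pf$a, b = b, cc = pf$cc, d = th[2])
    }
  )
  if (any(!is.finite(unlist(params)))) return(NULL)
  list(params = params, rss = best$rss, boundary = best$at_edge)
}

# warm starts for nested models, given earlier fits in scaled space
nested_warm <- function(model_id, fits) {
  w <- NULL
  if (model_id == "exp3" && !is.null(fits$exp2)) {
    w <- rbind(w, c(log(max(fits$exp2$params_scaled$b, 1e-6)), 1))
  }
  if (model_id == "exp5" && !is.null(fits$exp4)) {
    w <- rbind(w, c(log(max(fits$exp4$params_scaled$b, 1e-6)), 1))
  }
  if (model_id == "power" && !is.null(fits$linear)) w <- rbind(w, 1)
  w
}

#' Fit one dose-response model to a gene's expression profile
#'
#' Bounded nonlinear least squares (equivalently, maximum likelihood under
#' homoscedastic Gaussian error) on the log2 scale, with multi-start
#' initialisation from a deterministic Latin-hypercube grid for the
#' nonlinear models. Fits internally use the scaled concentration
#' `c / max(conc)` so results are exactly equivariant under rescaling of the
#' concentration axis.
#'
#' @param values Per-sample log2 expression for one gene.
#' @param conc Matching concentrations (µM); must include 0 and a positive
#'   maximum.
#' @param model_id One of the eight model identifiers (see
#'   [evaluate_model()]).
#' @param n_starts Number of multi-start points (>= 5) for nonlinear models.
#' @return A `dr_fit` list: `model_id`, `params` (natural µM units),
#'   `npar`, `rss`, `loglik`, `aic` (`2k - 2 loglik`, `k = npar + 1` for the
#'   residual variance), `conc_max`, `status` (`"ok"` or `"boundary"`), or
#'   `NULL` when no start converges.
#' @export
fit_model <- function(values, conc, model_id, n_starts = 7L) {
  model_id <- match.arg(model_id, MODEL_IDS)
  stopifnot(length(values) == length(conc), max(conc) > 0, min(conc) >= 0)
  cmax <- max(conc)
  t <- conc / cmax
  f <- fit_scaled(model_id, values, t, n_starts)
  if (is.null(f)) return(NULL)
  finish_fit(model_id, f, length(values), cmax)
}

finish_fit <- function(model_id, f, n, cmax) {
  npar <- MODEL_NPAR[[model_id]]
  ll <- gauss_loglik(f$rss, n)
  k <- npar + 1 # + residual variance
  aic <- 2 * k - 2 * ll
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(
    list(model_id = model_id,
         params = params_to_natural(model_id, f$params, cmax),
         params_scaled = f$params,
         npar = npar, rss = f$rss, loglik = ll,
         aic = aic, aicc = aicc,
         sigma = sqrt(max(f$rss / n, SIGMA2_FLOOR)),
         conc_max = cmax, n = n,
         status = if (f$boundary) "boundary" else "ok"),
    class = "dr_fit"
  )
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit> ", x$model_id, "  AIC ", round(x$aic, 3), "  params: ",
      paste(names(x$params), signif(unlist(x$params), 4), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select the best model among converged fits
#'
#' Lowest information score wins; ties (within 1e-9) go to the model with
#' fewer parameters, then to the fixed suite order. The default score is
#' the small-sample corrected AICc, appropriate for the ~15 observations of
#' a 5-concentration, 3-replicate design; plain AIC is available.
#'
#' @param fits List of `dr_fit` objects (NULL entries allowed).
#' @param criterion `"aicc"` (default) or `"aic"`.
#' @return The winning `dr_fit`, or `NULL` if none converged.
#' @export
select_best <- function(fits, criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  fits <- purrr::compact(fits)
  if (!length(fits)) return(NULL)
  score <- round(vapply(fits, function(f) f[[criterion]], numeric(1)), 9)
  npar <- vapply(fits, function(f) f$npar, integer(1))
  ord <- match(vapply(fits, function(f) f$model_id, character(1)), MODEL_IDS)
  fits[[order(score, npar, ord)[1]]]
}
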