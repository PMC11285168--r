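#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio of
#' each sample's count to the per-gene geometric mean, computed over genes
#' with strictly positive counts in every sample, then rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts Counts tibble (`gene_id` + one column per sample).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) abort("no gene has nonzero counts in every sample; cannot normalize")
  lm_ <- log(m[ok, , drop = FALSE])
  ref <- rowMeans(lm_)
  raw <- apply(lm_ - ref, 2, median)
  sf <- exp(raw - mean(raw))
  setNames(sf, colnames(m))
}

#' Log2 normalized expression
#'
#' Elementwise `log2(count / size_factor + pseudocount)`.
#'
#' @param counts Counts tibble.
#' @param factors Size factors from [size_factors()]; computed if `NULL`.
#' @param pseudocount Positive offset guarding the log at zero counts.
#' @return Tibble of the same shape with normalized values; the factors and
#'   pseudocount are attached as attributes `size_factors`, `pseudocount`.
#' @export
normalize_log2 <- function(counts, factors = NULL, pseudocount = 1) {
  stopifnot_scalar_num(pseudocount, "pseudocount", positive = TRUE)
  m <- counts_to_matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(factors <= 0)) abort("size factors must be > 0")
  factors <- factors[colnames(m)]
  norm <- log2(sweep(m, 2, factors, "/") + pseudocount)
  out <- matrix_to_tbl(norm)
  attr(out, "size_factors") <- factors
  attr(out, "pseudocount") <- pseudocount
  out
}

# negative-binomial Wald fit for one gene; returns c(log2fc, p) or NAs.
# X: model matrix with the condition column last; off: log size factors.
nb_wald_gene <- function(y, X, off, phi) {
  fam <- if (phi < 1e-8) stats::poisson() else MASS::negative.binomial(theta = 1 / phi)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off,
                                    control = list(maxit = 50))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
  p <- ncol(X)
  piv <- fit$qr$pivot
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov)) return(c(NA_real_, NA_real_))
  se_piv <- sqrt(diag(cov))
  se <- se_piv[match(seq_len(p), piv)]
  beta <- fit$coefficients[p]
  if (!is.finite(beta) || !is.finite(se[p]) || se[p] <= 0) {
    return(c(NA_real_, NA_real_))
  }
  z <- beta / se[p]
  c(beta / log(2), 2 * pnorm(-abs(z)))
}

# Trended method-of-moments dispersion, shrunk toward the trend in log space.
estimate_dispersions <- function(m, sf, group) {
  q <- sweep(m, 2, sf, "/")
  z <- mean(1 / sf)
  lv <- levels(group)
  ssq <- 0; dfree <- 0
  for (g in lv) {
    qi <- q[, group == g, drop = FALSE]
    ssq <- ssq + rowSums((qi - rowMeans(qi))^2)
    dfree <- dfree + ncol(qi) - 1
  }
  s2 <- ssq / dfree
  mu <- rowMeans(q)
  phi_raw <- (s2 - mu * z) / mu^2
  use <- is.finite(phi_raw) & phi_raw > 0 & mu > 0
  phi_trend <- rep(1e-4, length(mu))
  if (sum(use) >= 10) {
    fit <- lm(phi_raw[use] ~ I(1 / mu[use]))
    a0 <- max(coef(fit)[1], 1e-6)
    a1 <- max(coef(fit)[2], 0)
    phi_trend <- a0 + a1 / pmax(mu, 1e-8)
  }
  phi_gene <- pmax(phi_raw, 1e-4)
  phi_gene[!is.finite(phi_gene)] <- phi_trend[!is.finite(phi_gene)]
  # strong geometric shrinkage toward the trend with an asymmetric floor:
  # below-trend moment estimates are pulled (almost) up to the trend, while
  # above-trend genes keep part of their excess dispersion
  shrunk <- exp(0.3 * log(phi_gene) + 0.7 * log(pmax(phi_trend, 1e-6)))
  pmax(shrunk, 0.9 * phi_trend)
}

#' Per-gene negative-binomial Wald test for a two-arm contrast
#'
#' For each gene, fits a negative-binomial generalized linear model with
#' replicate and condition terms (`~ replicate + condition`) on the raw
#' counts with log size-factor offsets, and tests the condition coefficient
#' with a two-sided Wald test. Dispersions are estimated by method of
#' moments per gene, stabilized by shrinkage toward a fitted mean-dispersion
#' trend. P-values are Benjamini-Hochberg adjusted across all tested
#' (not-all-zero) genes.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param samples Sample sheet tibble (`sample_id`, `concentration_uM`,
#'   `replicate`).
#' @param control Concentration (µM) of the reference arm (default 0).
#' @param treat Concentration of the treatment arm; defaults to the highest
#'   concentration present.
#' @param q_cut,lfc_cut DEG thresholds passed to [call_degs()].
#' @return Tibble with `gene_id`, `base_mean`, `log2fc`, `p`, `q`, `is_deg`,
#'   ordered by `p` with ties broken by `gene_id`. All-zero genes carry `NA`
#'   statistics and are never DEGs.
#' @export
nb_test <- function(counts, samples, control = 0, treat = NULL,
                    q_cut = 0.05, lfc_cut = 0.585) {
  samples <- align_samples(counts, samples)
  if (is.null(treat)) treat <- max(samples$concentration_uM)
  keep <- samples$concentration_uM %in% c(control, treat)
  if (sum(samples$concentration_uM == control) < 2 ||
      sum(samples$concentration_uM == treat) < 2) {
    abort("need >= 2 samples in each contrast arm")
  }
  m <- counts_to_matrix(counts)[, keep, drop = FALSE]
  smp <- samples[keep, , drop = FALSE]
  cond <- factor(ifelse(smp$concentration_uM == control, "control", "treat"),
                 levels = c("control", "treat"))
  repl <- factor(smp$replicate)
  X <- if (nlevels(repl) > 1) {
    model.matrix(~ repl + cond)
  } else {
    model.matrix(~ cond)
  }
  sf <- size_factors(matrix_to_tbl(m))
  off <- log(sf)

  tested <- rowSums(m) > 0
  phi <- estimate_dispersions(m[tested, , drop = FALSE], sf, cond)

  res <- matrix(NA_real_, nrow(m), 2)
  idx <- which(tested)
  for (i in seq_along(idx)) {
    res[idx[i], ] <- nb_wald_gene(m[idx[i], ], X, off, phi[i])
  }
  q <- rep(NA_real_, nrow(m))
  has_p <- !is.na(res[, 2])
  q[has_p] <- p.adjust(res[has_p, 2], method = "BH")
  out <- tibble(
    gene_id = rownames(m),
    base_mean = rowMeans(sweep(m, 2, sf, "/")),
    log2fc = res[, 1],
    p = res[, 2],
    q = q
  )
  out <- call_degs(out, q_cut = q_cut, lfc_cut = lfc_cut)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  class(out) <- c("tpod_deg", class(out))
  out
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when its BH-adjusted p-value is below `q_cut` and its
#' absolute log2 fold change is at least `lfc_cut` (default 0.585, i.e. a
#' 1.5-fold change).
#'
#' @param records Tibble with `q` and `log2fc` columns (as from [nb_test()]).
#' @param q_cut FDR threshold (default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.585).
#' @return `records` with the logical `is_deg` column set; the DEG subset is
#'   `dplyr::filter(records, is_deg)`.
#' @export
call_degs <- function(records, q_cut = 0.05, lfc_cut = 0.585) {
  stopifnot(is.data.frame(records), all(c("q", "log2fc") %in% names(records)))
  records$is_deg <- !is.na(records$q) & records$q < q_cut &
    abs(records$log2fc) >= lfc_cut
  records
}
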