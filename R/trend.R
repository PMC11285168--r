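#' Pool-adjacent-violators (weighted isotonic) regression
#'
#' Weighted least-squares monotone fit of group means, the amalgamation step
#' of Williams' trend procedure. Pooling preserves the overall weighted
#' mean.
#'
#' @param means Group means in dose order.
#' @param weights Positive group weights (sizes); equal by default.
#' @param direction `+1` for a non-decreasing fit, `-1` for non-increasing.
#' @return Numeric vector of amalgamated means, same length as `means`.
#' @examples
#' pava(c(1, 3, 2, 5)) # c(1, 2.5, 2.5, 5)
#' @export
pava <- function(means, weights = NULL, direction = 1) {
  stopifnot(length(means) >= 1, direction %in% c(-1, 1))
  if (is.null(weights)) weights <- rep(1, length(means))
  stopifnot(length(weights) == length(means), all(weights > 0))
  if (direction == -1) return(-pava(-means, weights, 1))
  # stack of (value, weight) blocks; merge while the tail violates order
  vals <- numeric(0); wts <- numeric(0); len <- integer(0)
  for (i in seq_along(means)) {
    v <- means[i]; w <- weights[i]; l <- 1L
    while (length(vals) && vals[length(vals)] > v) {
      j <- length(vals)
      v <- (vals[j] * wts[j] + v * w) / (wts[j] + w)
      w <- wts[j] + w
      l <- len[j] + l
      vals <- vals[-j]; wts <- wts[-j]; len <- len[-j]
    }
    vals <- c(vals, v); wts <- c(wts, w); len <- c(len, l)
  }
  rep(vals, len)
}

# Per-design constants reused across genes and permutations.
trend_layout <- function(conc) {
  lev <- sort(unique(conc))
  if (length(lev) < 2) abort("need >= 2 concentration groups")
  g <- match(conc, lev)
  n <- tabulate(g, nbins = length(lev))
  if (n[1] < 2 || n[length(lev)] < 2) {
    abort("need >= 2 replicates in control and top-dose groups")
  }
  W <- matrix(0, length(conc), length(lev))
  W[cbind(seq_along(conc), g)] <- 1 / n[g]
  list(levels = lev, group = g, n = n, k = length(lev), W = W)
}

# Amalgamated top-dose mean for direction +1 (max of weighted suffix means
# over dose groups) applied row-wise to a matrix of group means M (rows =
# cases, cols = groups incl. control first).
amalg_top <- function(M, n) {
  k <- ncol(M)
  dose <- M[, 2:k, drop = FALSE]
  w <- n[2:k]
  kd <- k - 1L
  U <- outer(seq_len(kd), seq_len(kd), ">=") * 1 # suffix-sum accumulator
  S <- sweep(dose, 2, w, "*") %*% U
  den <- rev(cumsum(rev(w)))
  suf <- sweep(S, 2, den, "/")
  do.call(pmax, lapply(seq_len(kd), function(j) suf[, j]))
}

williams_t_from_means <- function(M, n, s2, direction) {
  Md <- direction * M
  top <- amalg_top(Md, n)
  se <- sqrt(s2 * (1 / n[length(n)] + 1 / n[1]))
  num <- top - Md[, 1]
  ifelse(se > 0, num / se, ifelse(abs(num) < 1e-12, 0, Inf))
}

#' Williams trend statistic for one gene
#'
#' `t_bar = (amalgamated top-dose mean - control mean) / sqrt(s2 (1/n_k +
#' 1/n_0))`, where the top-dose mean is amalgamated by isotonic regression
#' over the dose groups and `s2` is the pooled within-group variance across
#' all groups. With `direction = NULL` both directions are evaluated and the
#' one with the larger statistic is returned (reported in the `direction`
#' attribute).
#'
#' @param values Per-sample expression values for one gene (log2 scale).
#' @param conc Per-sample concentrations (same length).
#' @param direction `+1` (increasing), `-1` (decreasing), or `NULL` to pick
#'   the better-fitting direction.
#' @return The statistic, with attribute `direction`.
#' @export
williams_stat <- function(values, conc, direction = NULL) {
  lay <- trend_layout(conc)
  M <- matrix(vapply(seq_len(lay$k),
                     function(j) mean(values[lay$group == j]), numeric(1)),
              nrow = 1)
  ss_within <- sum((values - M[1, lay$group])^2)
  s2 <- ss_within / (length(values) - lay$k)
  if (is.null(direction)) {
    tp <- williams_t_from_means(M, lay$n, s2, 1)
    tm <- williams_t_from_means(M, lay$n, s2, -1)
    if (tp >= tm) structure(tp, direction = 1) else structure(tm, direction = -1)
  } else {
    structure(williams_t_from_means(M, lay$n, s2, direction),
              direction = direction)
  }
}

#' Williams trend prefilter with permutation p-values
#'
#' For each gene, computes the Williams trend statistic in its
#' better-fitting direction and a permutation p-value (sample labels
#' permuted across concentration groups; the one-sided permutation p is
#' Bonferroni-doubled for the direction search). The largest linear-scale
#' fold change of any concentration's mean versus control gates the final
#' pass flag: `passes = (p < alpha) & (max_fc >= fc_cutoff)`.
#'
#' @param norm Normalized log2 expression tibble from [normalize_log2()].
#' @param samples Sample sheet tibble.
#' @param fc_cutoff Linear-scale fold-change gate (default 1.5).
#' @param alpha Permutation p-value threshold (default 0.05).
#' @param n_permutations Number of label permutations (>= 999; default
#'   10000). One shared set of permutations is used for all genes.
#' @param seed Integer seed for the permutation draw.
#' @return Tibble `gene_id`, `direction`, `stat`, `p`, `max_fc`, `passes`.
#' @export
williams_trend <- function(norm, samples, fc_cutoff = 1.5, alpha = 0.05,
                           n_permutations = 10000, seed = 1) {
  samples <- align_samples(norm, samples)
  if (n_permutations < 999) abort("`n_permutations` must be >= 999")
  m <- counts_to_matrix(norm)
  lay <- trend_layout(samples$concentration_uM)
  N <- ncol(m); B <- as.integer(n_permutations)

  n_distinct <- exp(lgamma(N + 1) - sum(lgamma(lay$n + 1)))
  if (n_distinct < B) {
    warn(sprintf(
      "only ~%.0f distinct group assignments exist; permutations sampled with replacement",
      n_distinct))
  }
  P <- with_seed(child_seed(seed, 777L), function() {
    matrix(replicate(B, sample.int(N)), nrow = B, byrow = TRUE)
  })

  one_gene <- function(x) {
    Mobs <- matrix(colSums(x * lay$W) / 1, nrow = 1) # W columns already 1/n
    ss_within_obs <- sum((x - Mobs[1, lay$group])^2)
    s2_obs <- ss_within_obs / (N - lay$k)
    tp <- williams_t_from_means(Mobs, lay$n, s2_obs, 1)
    tm <- williams_t_from_means(Mobs, lay$n, s2_obs, -1)
    dir <- if (tp >= tm) 1 else -1
    tobs <- max(tp, tm)

    xp <- matrix(x[P], nrow = B)
    Mp <- xp %*% lay$W
    sst <- sum((x - mean(x))^2)
    ssb <- Mp^2 %*% lay$n - N * mean(x)^2
    s2p <- pmax((sst - ssb) / (N - lay$k), 0)
    tperm <- williams_t_from_means(Mp, lay$n, s2p, dir)
    p1 <- (1 + sum(tperm >= tobs)) / (1 + B)
    pval <- min(1, 2 * p1)

    ratio <- 2^(Mobs[1, -1] - Mobs[1, 1])
    maxfc <- max(pmax(ratio, 1 / ratio))
    c(dir, tobs, pval, maxfc)
  }

  res <- t(apply(m, 1, one_gene))
  tibble(
    gene_id = rownames(m),
    direction = as.numeric(res[, 1]),
    stat = as.numeric(res[, 2]),
    p = as.numeric(res[, 3]),
    max_fc = as.numeric(res[, 4]),
    passes = as.numeric(res[, 3]) < alpha & as.numeric(res[, 4]) >= fc_cutoff
  )
}
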