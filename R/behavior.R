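# Larval locomotion metrics: distance per bin, dark-phase startle delta,
# and thigmotaxis (time in the inner zone of the well) with many-to-one
# group comparisons.

#' Well zone configuration
#'
#' A circular well split into a centred inner circle and the remaining
#' outer ring; time in the inner zone is the (anti)thigmotaxis readout.
#'
#' @param well_diameter_mm Well (arena) diameter (default 10 mm).
#' @param inner_diameter_mm Inner-zone diameter (default 6 mm, leaving a
#'   2 mm ring).
#' @return A `zone_config` list with diameters and ring width.
#' @export
zone_config <- function(well_diameter_mm = 10, inner_diameter_mm = 6) {
  stopifnot_scalar_num(well_diameter_mm, "well_diameter_mm", positive = TRUE)
  stopifnot_scalar_num(inner_diameter_mm, "inner_diameter_mm", positive = TRUE)
  if (inner_diameter_mm >= well_diameter_mm) {
    abort("inner zone must be smaller than the well")
  }
  structure(
    list(well_diameter_mm = well_diameter_mm,
         inner_diameter_mm = inner_diameter_mm,
         ring_mm = (well_diameter_mm - inner_diameter_mm) / 2),
    class = "zone_config"
  )
}

#' Inner-zone area fraction
#'
#' Fraction of the arena area covered by the inner zone:
#' `(inner_diameter / well_diameter)^2`. For the default 6 mm inner circle
#' in a 10 mm well this is 0.36 — the expected occupancy of a larva with
#' uniform positional density.
#'
#' @param cfg A [zone_config()].
#' @return Area fraction in `[0, 1)`.
#' @export
zone_fraction <- function(cfg) {
  stopifnot(inherits(cfg, "zone_config"))
  (cfg$inner_diameter_mm / cfg$well_diameter_mm)^2
}

#' Per-larva locomotion metrics
#'
#' From per-minute tracking bins (well-centred coordinates), computes for
#' each larva: total distance over the last 5 baseline-light minutes
#' (`baseline_distance`), the startle delta (total distance over the first
#' 5-min dark phase minus the preceding 5 light minutes), and the
#' cumulative-duration percentage of the first dark phase spent in the
#' inner zone (`inner_cd_pct`), with zone occupancy decided per bin from
#' the radial distance of the bin's mean position.
#'
#' @param tracks Tibble with columns `larva_id`, `treatment`, `bin_start_s`,
#'   `distance_mm`, `x_mm`, `y_mm`, `phase` (values `"baseline"`, `"dark"`,
#'   `"light"`; the recorded schedule is a baseline-light block followed by
#'   alternating 5-min dark/light cycles).
#' @param cfg A [zone_config()].
#' @return Tibble with one row per larva: `larva_id`, `treatment`,
#'   `baseline_distance`, `startle_delta`, `inner_cd_pct`. Larvae missing
#'   bins in a required phase are excluded; the `excluded` attribute lists
#'   them with reasons.
#' @export
phase_metrics <- function(tracks, cfg = zone_config()) {
  needed <- c("larva_id", "treatment", "bin_start_s", "distance_mm",
              "x_mm", "y_mm", "phase")
  stopifnot(is.data.frame(tracks), all(needed %in% names(tracks)))
  r_inner <- cfg$inner_diameter_mm / 2
  excluded <- list()
  per_larva <- function(d) {
    d <- d[order(d$bin_start_s), ]
    base <- d[d$phase == "baseline", ]
    dark_rows <- which(d$phase == "dark")
    if (nrow(base) < 5 || !length(dark_rows)) {
      return(list(row = NULL, reason = "missing baseline or dark phase"))
    }
    # first contiguous dark run
    first_dark_end <- dark_rows[c(which(diff(dark_rows) > 1), length(dark_rows))[1]]
    dark1 <- d[dark_rows[1]:first_dark_end, ]
    if (any(d$distance_mm < 0)) {
      return(list(row = NULL, reason = "negative distance"))
    }
    base5 <- tail(base, 5)
    r <- sqrt(dark1$x_mm^2 + dark1$y_mm^2)
    list(row = tibble(
      larva_id = d$larva_id[1],
      treatment = d$treatment[1],
      baseline_distance = sum(base5$distance_mm),
      startle_delta = sum(dark1$distance_mm) - sum(base5$distance_mm),
      inner_cd_pct = 100 * mean(r <= r_inner)
    ), reason = NULL)
  }
  out <- list()
  for (id in unique(tracks$larva_id)) {
    res <- per_larva(tracks[tracks$larva_id == id, , drop = FALSE])
    if (is.null(res$row)) {
      excluded[[length(excluded) + 1L]] <- tibble(larva_id = id,
                                                  reason = res$reason)
    } else {
      out[[length(out) + 1L]] <- res$row
    }
  }
  metrics <- dplyr::bind_rows(out)
  attr(metrics, "excluded") <- dplyr::bind_rows(excluded)
  metrics
}

#' Many-to-one group comparison (ANOVA + Monte-Carlo Dunnett)
#'
#' One-way ANOVA across treatment groups followed by Dunnett-style
#' comparisons of every treatment against the control, with the max-|t|
#' familywise null approximated by Monte-Carlo draws (group means from
#' independent normals, the pooled variance from a scaled chi-square). If a
#' group has zero variance while others do not, falls back to rank-based
#' comparisons (Kruskal-Wallis + pairwise Wilcoxon, Bonferroni) with a
#' warning.
#'
#' @param metrics Tibble with a `treatment` column and the metric in
#'   `value_col`.
#' @param value_col Name of the metric column.
#' @param control Control treatment label.
#' @param n_mc Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param seed Seed for the Monte-Carlo draw.
#' @return Tibble: one row per non-control treatment with `n`, `mean`,
#'   `effect` (mean difference vs control), `t`, `p` (unadjusted, two-sided)
#'   and `padj` (familywise). Attributes `f_statistic`, `p_overall`, `df`.
#' @export
group_compare <- function(metrics, value_col, control, n_mc = 1e5, seed = 1) {
  stopifnot(is.data.frame(metrics), "treatment" %in% names(metrics),
            value_col %in% names(metrics))
  y <- metrics[[value_col]]
  grp <- as.character(metrics$treatment)
  if (!control %in% grp) abort(sprintf("control group '%s' not found", control))
  lev <- c(control, sort(setdiff(unique(grp), control)))
  if (length(lev) < 2) abort("need >= 2 groups")
  g <- factor(grp, levels = lev)
  n_g <- table(g)
  if (any(n_g < 3)) abort("need >= 3 larvae per group")

  fit <- aov(y ~ g)
  an <- anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]

  vars <- tapply(y, g, var)
  if (any(vars == 0) && !all(vars == 0)) {
    warn("a group has zero variance; falling back to rank-based comparisons")
    kw <- stats::kruskal.test(y, g)
    rows <- purrr::map(lev[-1], function(l) {
      w <- stats::wilcox.test(y[g == l], y[g == control], exact = FALSE)
      tibble(treatment = l, n = as.integer(n_g[[l]]),
             mean = mean(y[g == l]),
             effect = mean(y[g == l]) - mean(y[g == control]),
             t = NA_real_, p = w$p.value,
             padj = min(1, w$p.value * (length(lev) - 1)))
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "f_statistic") <- unname(kw$statistic)
    attr(out, "p_overall") <- kw$p.value
    attr(out, "df") <- NA_real_
    return(out)
  }

  means <- tapply(y, g, mean)
  se <- sqrt(mse * (1 / n_g[-1] + 1 / n_g[[1]]))
  tstat <- (means[-1] - means[[1]]) / se
  p_un <- 2 * pt(-abs(tstat), df)

  k <- length(lev)
  maxT <- with_seed(child_seed(seed, 31L), function() {
    z <- matrix(rnorm(n_mc * k), n_mc, k)
    z <- sweep(z, 2, sqrt(as.numeric(n_g)), "/")
    s <- sqrt(rchisq(n_mc, df) / df)
    tmat <- (z[, -1, drop = FALSE] - z[, 1]) /
      outer(s, sqrt(as.numeric(1 / n_g[-1] + 1 / n_g[[1]])))
    apply(abs(tmat), 1, max)
  })
  padj <- vapply(abs(tstat), function(tt) mean(maxT >= tt), numeric(1))
  padj <- pmax(padj, p_un) # familywise p can never undercut the raw p

  out <- tibble(
    treatment = lev[-1],
    n = as.integer(n_g[-1]),
    mean = as.numeric(means[-1]),
    effect = as.numeric(means[-1] - means[[1]]),
    t = as.numeric(tstat),
    p = as.numeric(p_un),
    padj = as.numeric(padj)
  )
  attr(out, "f_statistic") <- an["g", "F value"]
  attr(out, "p_overall") <- an["g", "Pr(>F)"]
  attr(out, "df") <- df
  out
}

#' Simulate larval tracking tables
#'
#' Generates per-minute tracking bins for groups of larvae under the
#' recorded schedule (a baseline-light block followed by alternating 5-min
#' dark/light cycles). Positions are drawn uniformly over the well disc
#' unless a group's `inner_bias` shifts density toward the centre;
#' distances per bin are lognormal around `dark_gain` times the light-phase
#' mean during dark bins.
#'
#' @param groups Named integer vector: larvae per treatment group.
#' @param cfg A [zone_config()].
#' @param baseline_min Baseline light minutes (default 90, as recorded).
#' @param n_cycles Number of dark/light cycle pairs (default 2).
#' @param mean_distance Mean light-phase distance per minute (mm).
#' @param dark_gain Multiplier on distance during dark bins.
#' @param inner_bias Named numeric (per group): probability that a bin's
#'   position is resampled uniformly inside the inner zone instead of the
#'   whole well (0 = uniform over the well).
#' @param seed Integer seed.
#' @return Tracking tibble as required by [phase_metrics()].
#' @export
simulate_tracks <- function(groups, cfg = zone_config(), baseline_min = 90,
                            n_cycles = 2, mean_distance = 30, dark_gain = 2,
                            inner_bias = NULL, seed = 1) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  phases <- c(rep("baseline", baseline_min),
              rep(c(rep("dark", 5), rep("light", 5)), n_cycles))
  n_bins <- length(phases)
  R <- cfg$well_diameter_mm / 2
  r_in <- cfg$inner_diameter_mm / 2
  with_seed(child_seed(seed, 5150L), function() {
    rows <- list()
    idx <- 0L
    for (gname in names(groups)) {
      bias <- if (!is.null(inner_bias) && gname %in% names(inner_bias)) {
        inner_bias[[gname]]
      } else {
        0
      }
      for (i in seq_len(groups[[gname]])) {
        idx <- idx + 1L
        use_inner <- runif(n_bins) < bias
        rad_max <- ifelse(use_inner, r_in, R)
        r <- rad_max * sqrt(runif(n_bins))
        th <- runif(n_bins, 0, 2 * pi)
        gain <- ifelse(phases == "dark", dark_gain, 1)
        dist <- rlnorm(n_bins, log(mean_distance * gain), 0.25)
        rows[[idx]] <- tibble(
          larva_id = sprintf("%s_L%03d", gname, i),
          treatment = gname,
          bin_start_s = (seq_len(n_bins) - 1) * 60,
          distance_mm = dist,
          x_mm = r * cos(th),
          y_mm = r * sin(th),
          phase = phases
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
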