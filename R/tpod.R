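#' Postfilter gene-level BMDs
#'
#' Applies the three exclusion rules used before tPOD derivation: curves
#' with a confidence-bound ratio `bmdu / bmdl > 40`, a BMD above the
#' highest tested concentration, or a BMD more than 10-fold below the
#' lowest nonzero tested concentration are removed. Records with missing or
#' failed BMDs are dropped. The filter is idempotent.
#'
#' @param records `tpod_fits` tibble (or any tibble with `bmd`, `bmdl`,
#'   `bmdu`).
#' @param max_conc Highest tested concentration (µM); defaults to the
#'   `max_conc` attribute of `records`.
#' @param min_nonzero_conc Lowest nonzero tested concentration (µM);
#'   defaults to the corresponding attribute.
#' @param cap Largest tolerated `bmdu / bmdl` ratio (default 40).
#' @return The retained records, same columns.
#' @export
postfilter_bmds <- function(records, max_conc = NULL, min_nonzero_conc = NULL,
                            cap = 40) {
  stopifnot(is.data.frame(records),
            all(c("bmd", "bmdl", "bmdu") %in% names(records)))
  max_conc <- max_conc %||% attr(records, "max_conc")
  min_nonzero_conc <- min_nonzero_conc %||% attr(records, "min_nonzero_conc")
  if (is.null(max_conc) || is.null(min_nonzero_conc)) {
    abort("supply `max_conc` and `min_nonzero_conc` (or use a tpod_fits object)")
  }
  stopifnot(max_conc > min_nonzero_conc, min_nonzero_conc > 0)
  keep <- is.finite(records$bmd) & is.finite(records$bmdl) &
    is.finite(records$bmdu) & records$bmdl > 0 &
    (records$bmdu / records$bmdl <= cap) &
    (records$bmd <= max_conc) &
    (records$bmd >= min_nonzero_conc / 10)
  out <- records[keep, , drop = FALSE]
  attr(out, "max_conc") <- max_conc
  attr(out, "min_nonzero_conc") <- min_nonzero_conc
  out
}

#' Percentile tPOD
#'
#' Linear-interpolation (type 7) quantile of the postfiltered BMD values.
#'
#' @param bmds Retained BMD values (µM), at least one.
#' @param fraction Quantile fraction (default 0.10, the 10th percentile).
#' @return tPOD in µM.
#' @examples
#' tpod_percentile(1:10, 0.10) # 1.9
#' @export
tpod_percentile <- function(bmds, fraction = 0.10) {
  bmds <- bmds[is.finite(bmds)]
  if (!length(bmds)) abort("no retained BMDs; tPOD undefined")
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1]")
  unname(quantile(bmds, fraction, type = 7))
}

#' Modes and antimodes of the BMD distribution
#'
#' Gaussian kernel density of `log10(bmd)` on a 512-point grid spanning the
#' data range plus 3 bandwidths on each side. Modes are strict local maxima
#' of the grid density (maxima with density below 5% of the global maximum
#' are treated as grid noise and discarded); antimodes are the lowest
#' density points between consecutive retained modes.
#'
#' @param bmds Retained BMD values (µM); at least 5 for mode detection.
#' @param bandwidth `"silverman"` (rule-of-thumb on the log10 values) or a
#'   positive scalar bandwidth on the log10 axis.
#' @param min_rel_density Modes with density below this fraction of the
#'   maximum are discarded (default 0.05).
#' @param min_prominence Minimum relative dip separating two modes: the
#'   antimode between adjacent modes must fall below `1 - min_prominence`
#'   times the smaller mode's density (default 0.1), otherwise the smaller
#'   mode is treated as a shoulder of its neighbour and merged away.
#' @return List with `modes`, `antimodes` (ascending, log10 µM), `bw`, and
#'   `density` (tibble `x`, `y`). With fewer than 5 values, modes are `NULL`
#'   and a warning is raised.
#' @export
kde_modes <- function(bmds, bandwidth = "silverman", min_rel_density = 0.05,
                      min_prominence = 0.1) {
  bmds <- bmds[is.finite(bmds) & bmds > 0]
  if (length(bmds) < 5) {
    warn("fewer than 5 BMDs; mode detection skipped")
    return(list(modes = NULL, antimodes = NULL, bw = NA_real_, density = NULL))
  }
  x <- log10(bmds)
  bw <- if (identical(bandwidth, "silverman")) {
    stats::bw.nrd0(x)
  } else {
    stopifnot_scalar_num(bandwidth, "bandwidth", positive = TRUE)
    bandwidth
  }
  if (bw <= 0 || !is.finite(bw)) bw <- max(diff(range(x)) / 10, 1e-3)
  den <- density(x, bw = bw, n = 512, from = min(x) - 3 * bw,
                 to = max(x) + 3 * bw)
  y <- den$y
  g <- den$x
  n <- length(y)
  is_max <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]
  modes_i <- which(is_max) + 1L
  modes_i <- modes_i[y[modes_i] >= min_rel_density * max(y)]

  anti_between <- function(mi) {
    vapply(seq_len(length(mi) - 1), function(j) {
      seg <- mi[j]:mi[j + 1]
      seg[which.min(y[seg])]
    }, integer(1))
  }
  # prominence pruning: a mode separated from its neighbour by only a
  # shallow dip is a shoulder, not a separate cluster
  while (length(modes_i) > 1) {
    anti_i <- anti_between(modes_i)
    dip <- vapply(seq_along(anti_i), function(j) {
      y[anti_i[j]] / min(y[modes_i[j]], y[modes_i[j + 1]])
    }, numeric(1))
    worst <- which.max(dip)
    if (dip[worst] <= 1 - min_prominence) break
    drop <- if (y[modes_i[worst]] < y[modes_i[worst + 1]]) worst else worst + 1L
    modes_i <- modes_i[-drop]
  }
  antimodes <- if (length(modes_i) > 1) g[anti_between(modes_i)] else numeric(0)
  list(modes = g[modes_i], antimodes = antimodes, bw = bw,
       density = tibble(x = g, y = y))
}

#' Derive transcriptomic points of departure
#'
#' Postfilters the per-gene BMD records and assembles the two tPODs: the
#' 10th percentile of retained BMDs and the first (lowest-concentration)
#' mode of their kernel density on the log10 axis. The first-mode gene set
#' is every retained gene with `log10(bmd)` below the first antimode; for a
#' unimodal density it is all retained genes, flagged `unimodal`.
#'
#' @param records `tpod_fits` tibble.
#' @param max_conc,min_nonzero_conc Design range for [postfilter_bmds()];
#'   default to the attributes of `records`.
#' @param percentile Percentile fraction for the percentile tPOD.
#' @param bandwidth Passed to [kde_modes()].
#' @param cap BMDU/BMDL postfilter cap (default 40).
#' @return A `tpod_report` list: `n_input`, `n_retained`, `retained`
#'   (tibble), `tpod_10th`, `tpod_mode`, `modes_log10`, `antimodes_log10`,
#'   `bw`, `density`, `first_mode_genes`, `unimodal`.
#' @export
derive_tpods <- function(records, max_conc = NULL, min_nonzero_conc = NULL,
                         percentile = 0.10, bandwidth = "silverman",
                         cap = 40) {
  retained <- postfilter_bmds(records, max_conc, min_nonzero_conc, cap = cap)
  if (!nrow(retained)) abort("no BMD records pass the postfilter; tPOD undefined")
  tpod_p <- tpod_percentile(retained$bmd, percentile)
  km <- kde_modes(retained$bmd, bandwidth)
  unimodal <- is.null(km$modes) || length(km$modes) <= 1
  tpod_mode <- if (length(km$modes)) 10^km$modes[1] else NA_real_
  first_genes <- if (!unimodal) {
    retained$gene_id[log10(retained$bmd) < km$antimodes[1]]
  } else {
    retained$gene_id
  }
  structure(
    list(n_input = nrow(records), n_retained = nrow(retained),
         retained = retained, tpod_10th = tpod_p, tpod_mode = tpod_mode,
         modes_log10 = km$modes, antimodes_log10 = km$antimodes,
         bw = km$bw, density = km$density,
         first_mode_genes = first_genes, unimodal = unimodal),
    class = "tpod_report"
  )
}

#' @export
print.tpod_report <- function(x, ...) {
  cat("<tpod_report> ", x$n_retained, "/", x$n_input,
      " BMD records retained\n", sep = "")
  cat("  tPOD (10th): ", signif(x$tpod_10th, 4), " uM\n", sep = "")
  cat("  tPOD (mode): ", signif(x$tpod_mode, 4), " uM",
      if (x$unimodal) "  [unimodal]", "\n", sep = "")
  if (length(x$modes_log10)) {
    cat("  modes (log10 uM): ",
        paste(signif(x$modes_log10, 3), collapse = ", "), "\n", sep = "")
  }
  if (length(x$antimodes_log10)) {
    cat("  antimodes (log10 uM): ",
        paste(signif(x$antimodes_log10, 3), collapse = ", "), "\n", sep = "")
  }
  cat("  first-mode genes: ", length(x$first_mode_genes), "\n", sep = "")
  invisible(x)
}
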