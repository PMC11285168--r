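# ggplot2 figures for the main result types.

#' Plot the BMD density with modes, antimodes and tPODs
#'
#' Kernel density of the retained BMDs on the log10 µM axis with a rug of
#' gene-level BMDs, solid lines at modes, dashed lines at antimodes, and a
#' dotted line at the percentile tPOD.
#'
#' @param object A `tpod_report` from [derive_tpods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tpod_report <- function(object, ...) {
  stopifnot(!is.null(object$density))
  rug <- tibble(x = log10(object$retained$bmd))
  p <- ggplot2::ggplot(object$density, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = rug, ggplot2::aes(x = .data$x), inherit.aes = FALSE,
                      alpha = 0.4, length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "log10 BMD (uM)", y = "density",
                  title = sprintf("tPOD(10th) = %.3g uM, tPOD(mode) = %.3g uM",
                                  object$tpod_10th, object$tpod_mode)) +
    ggplot2::theme_minimal()
  if (length(object$modes_log10)) {
    p <- p + ggplot2::geom_vline(xintercept = object$modes_log10,
                                 linetype = "solid", colour = "steelblue")
  }
  if (length(object$antimodes_log10)) {
    p <- p + ggplot2::geom_vline(xintercept = object$antimodes_log10,
                                 linetype = "dashed", colour = "grey40")
  }
  p + ggplot2::geom_vline(xintercept = log10(object$tpod_10th),
                          linetype = "dotted", colour = "firebrick")
}

#' Histogram of gene-level BMDs from a fit table
#'
#' @param object A `tpod_fits` tibble from [fit_dose_response()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tpod_fits <- function(object, bins = 40, ...) {
  d <- object[is.finite(object$bmd), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$bmd))) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "log10 BMD (uM)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Dose-response fit figure for one gene
#'
#' Observed per-sample log2 expression against concentration with the
#' fitted curve and, when supplied, the BMD location.
#'
#' @param fit A `dr_fit` from [fit_model()].
#' @param values,conc The data the model was fitted to.
#' @param bmd Optional BMD (µM) to mark.
#' @return A ggplot object.
#' @export
plot_model_fit <- function(fit, values, conc, bmd = NULL) {
  stopifnot(inherits(fit, "dr_fit"))
  shift <- min(conc[conc > 0]) / 10 # plot 0 at a tenth of the lowest dose
  xx <- exp(seq(log(shift), log(max(conc)), length.out = 200))
  curve_d <- tibble(conc = xx,
                    y = evaluate_model(fit$model_id, fit$params,
                                       ifelse(xx <= shift, 0, xx)))
  obs <- tibble(conc = pmax(conc, shift), y = values)
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$conc, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_d, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "log2 expression",
                  title = fit$model_id) +
    ggplot2::theme_minimal()
  if (!is.null(bmd) && is.finite(bmd)) {
    p <- p + ggplot2::geom_vline(xintercept = bmd, linetype = "dotted",
                                 colour = "firebrick")
  }
  p
}

#' Volcano-style overview of a DEG table
#'
#' @param object A DEG tibble from [nb_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tpod_deg <- function(object, ...) {
  d <- object[!is.na(object$p), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                  colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "DEG") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
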