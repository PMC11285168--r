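# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted dose-response model
#'
#' @param x A `dr_fit` from [fit_model()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = as.numeric(unlist(x$params)))
}

#' One-row summary of a fitted dose-response model
#'
#' @param x A `dr_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `npar`, `loglik`, `aic`, `rss`, `sigma`,
#'   `status`.
#' @export
glance.dr_fit <- function(x, ...) {
  tibble(model = x$model_id, npar = x$npar, loglik = x$loglik,
         aic = x$aic, rss = x$rss, sigma = x$sigma, status = x$status)
}

#' Tidy a tPOD report
#'
#' @param x A `tpod_report` from [derive_tpods()].
#' @param ... Unused.
#' @return The retained per-gene records with a `first_mode` flag.
#' @export
tidy.tpod_report <- function(x, ...) {
  out <- as_tibble(x$retained)
  out$first_mode <- out$gene_id %in% x$first_mode_genes
  out
}

#' One-row summary of a tPOD report
#'
#' @param x A `tpod_report`.
#' @param ... Unused.
#' @return Tibble with the input/retained counts, both tPODs, the number of
#'   modes and antimodes, the bandwidth, and the unimodality flag.
#' @export
glance.tpod_report <- function(x, ...) {
  tibble(n_input = x$n_input, n_retained = x$n_retained,
         tpod_10th = x$tpod_10th, tpod_mode = x$tpod_mode,
         n_modes = length(x$modes_log10),
         n_antimodes = length(x$antimodes_log10),
         bandwidth = x$bw, unimodal = x$unimodal,
         n_first_mode = length(x$first_mode_genes))
}

#' One-row summary of a BMD fit table
#'
#' @param x A `tpod_fits` tibble from [fit_dose_response()].
#' @param ... Unused.
#' @return Tibble with fit counts by status and the finite-BMD count.
#' @export
glance.tpod_fits <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_ok = sum(x$fit_status == "ok"),
         n_boundary = sum(x$fit_status == "boundary"),
         n_failed = sum(x$fit_status == "failed"),
         n_finite_bmd = sum(is.finite(x$bmd)))
}
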