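#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> DE -> trend -> fit -> tPOD
#' (-> enrichment) chain with its default. Thresholds default to the
#' analysis conventions used throughout the package: FDR 0.05 with a
#' 1.5-fold (log2 0.585) change for DEG calling, a 1.5-fold Williams
#' prefilter at alpha 0.05, a BMDU/BMDL cap of 40 in the postfilter, the
#' 10th percentile and first density mode as tPODs.
#'
#' @param anchor_uM Top (EC20) concentration of the dilution series.
#' @param n_dilutions,dilution_factor,n_replicates Design layout.
#' @param n_genes,prop_responsive,library_size,truth_bmr Simulator settings
#'   (ignored when `counts_path` is given).
#' @param bmd_log10_mix Optional mixture spec for simulated true BMDs
#'   (passed to [make_truth()]).
#' @param counts_path,samples_path Optional existing input files; when
#'   `NULL` the pipeline simulates its input.
#' @param gmt_path Optional GMT collection for first-mode enrichment.
#' @param q_cut,lfc_cut DEG thresholds.
#' @param trend_fc,trend_alpha,n_permutations Williams prefilter settings.
#' @param bmr_factor,confidence,control_sd BMD settings.
#' @param cap BMDU/BMDL postfilter cap.
#' @param percentile Percentile tPOD fraction.
#' @param bandwidth KDE bandwidth rule or scalar.
#' @param max_term_size,fdr Enrichment settings.
#' @param seed Base seed for all stochastic stages.
#' @param out_dir Output directory for stage artifacts.
#' @return A `tpod_config` list.
#' @export
tpod_config <- function(anchor_uM = 48.3, n_dilutions = 3,
                        dilution_factor = 10, n_replicates = 3,
                        n_genes = 5000, prop_responsive = 0.10,
                        library_size = 5e5, truth_bmr = NULL,
                        bmd_log10_mix = NULL,
                        counts_path = NULL, samples_path = NULL,
                        gmt_path = NULL,
                        q_cut = 0.05, lfc_cut = 0.585,
                        trend_fc = 1.5, trend_alpha = 0.05,
                        n_permutations = 10000,
                        bmr_factor = 1, confidence = 0.90,
                        control_sd = "moderated", cap = 40,
                        percentile = 0.10, bandwidth = "silverman",
                        max_term_size = 1000, fdr = 0.05,
                        seed = 1, out_dir = tempfile("tpod_run_")) {
  cfg <- as.list(environment())
  stopifnot(cfg$q_cut > 0, cfg$q_cut < 1, cfg$lfc_cut >= 0,
            cfg$trend_fc >= 1, cfg$trend_alpha > 0, cfg$trend_alpha < 1,
            cfg$cap > 1, cfg$percentile >= 0, cfg$percentile <= 1,
            cfg$bmr_factor > 0, cfg$confidence > 0, cfg$confidence < 1,
            cfg$max_term_size >= 1, cfg$fdr > 0, cfg$fdr < 1)
  structure(cfg, class = "tpod_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [tpod_config()].
#' @param path YAML path.
#' @return `path` (writer) or `tpod_config` (reader). Configurations
#'   round-trip unchanged.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tpod_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(tpod_config, vals)
}

#' Run the full tPOD pipeline
#'
#' Executes simulate (or load) -> differential expression -> Williams trend
#' prefilter -> dose-response fitting -> postfilter and tPOD derivation ->
#' optional first-mode enrichment, writing each stage's table under
#' `config$out_dir` before the next stage starts, plus a manifest JSON with
#' versions, seeds, thresholds, input checksums, and per-stage gene counts.
#' Any stage failure halts with the stage name; completed artifacts remain
#' on disk.
#'
#' @param config A [tpod_config()].
#' @param quiet Suppress per-stage messages.
#' @return A `tpod_pipeline` list: `config`, `counts`, `samples`, `deg`,
#'   `trend`, `fits`, `report` (`tpod_report`), `enrichment` (or `NULL`),
#'   `manifest`, `paths`.
#' @export
run_pipeline <- function(config = tpod_config(), quiet = FALSE) {
  stopifnot(inherits(config, "tpod_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pth <- function(f) file.path(config$out_dir, f)
  paths <- list()
  counts_stage <- list(n = NA_integer_)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  truth <- NULL
  if (is.null(config$counts_path)) {
    sim <- stage("simulate", {
      design <- make_design(config$anchor_uM, config$n_dilutions,
                            config$dilution_factor, config$n_replicates)
      truth <- make_truth(design, n_genes = config$n_genes,
                          prop_responsive = config$prop_responsive,
                          bmr = config$truth_bmr,
                          bmd_log10_mix = config$bmd_log10_mix,
                          seed = child_seed(config$seed, 1L))
      simulate_counts(truth, design, library_size = config$library_size,
                      seed = child_seed(config$seed, 2L))
    })
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    paths$counts <- write_counts(counts, pth("counts.tsv"))
    paths$samples <- write_samples(samples, pth("samples.csv"))
    truth_out <- truth
    truth_out$curve <- lapply(truth_out$curve, unclass)
    paths$truth <- write_result_tsv(truth_out, pth("truth.tsv"))
  } else {
    counts <- stage("load", read_counts(config$counts_path))
    samples <- stage("load", read_samples(config$samples_path))
  }
  say("input: %d genes x %d samples", nrow(counts), nrow(samples))

  deg <- stage("deg", nb_test(counts, samples, q_cut = config$q_cut,
                              lfc_cut = config$lfc_cut))
  paths$deg <- write_result_tsv(deg, pth("deg_table.tsv"))
  say("deg: %d DEGs of %d tested", sum(deg$is_deg), sum(!is.na(deg$p)))

  norm <- stage("normalize", normalize_log2(counts))
  trend <- stage("trend", williams_trend(
    norm, samples, fc_cutoff = config$trend_fc, alpha = config$trend_alpha,
    n_permutations = config$n_permutations,
    seed = child_seed(config$seed, 3L)))
  paths$trend <- write_result_tsv(trend, pth("trend_table.tsv"))
  say("trend: %d of %d genes pass the prefilter",
      sum(trend$passes), nrow(trend))

  fits <- stage("fit", fit_dose_response(
    norm, samples, genes = trend$gene_id[trend$passes],
    bmr_factor = config$bmr_factor, control_sd = config$control_sd,
    confidence = config$confidence, seed = child_seed(config$seed, 4L)))
  paths$fits <- write_result_tsv(fits, pth("bmd_table.tsv"))
  say("fit: %d of %d fitted genes have a finite BMD",
      sum(is.finite(fits$bmd)), nrow(fits))

  report <- stage("pod", derive_tpods(
    fits, percentile = config$percentile, bandwidth = config$bandwidth,
    cap = config$cap))
  paths$report <- write_report_json(report, pth("tpod_report.json"))
  paths$retained <- write_result_tsv(report$retained, pth("retained_bmds.tsv"))
  if (!is.null(report$density)) {
    paths$density <- write_result_tsv(report$density, pth("density.tsv"))
  }
  say("pod: %d retained; tPOD(10th) %.4g uM, tPOD(mode) %.4g uM",
      report$n_retained, report$tpod_10th, report$tpod_mode)

  enrichment <- NULL
  if (!is.null(config$gmt_path)) {
    enrichment <- stage("enrich", {
      collection <- read_gmt(config$gmt_path)
      universe <- deg$gene_id[!is.na(deg$p)]
      query <- intersect(report$first_mode_genes, universe)
      ora(query, universe, collection,
          max_term_size = config$max_term_size, fdr = config$fdr)
    })
    paths$enrichment <- write_result_tsv(enrichment, pth("enrichment.tsv"))
  }

  manifest <- list(
    package = "tpodr",
    version = as.character(utils::packageVersion("tpodr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "out_dir")],
    input_checksums = as.list(tools::md5sum(unlist(
      paths[intersect(c("counts", "samples"), names(paths))]))),
    stage_counts = list(
      input_genes = nrow(counts),
      deg = sum(deg$is_deg),
      prefiltered = sum(trend$passes),
      fitted = sum(is.finite(fits$bmd)),
      postfiltered = report$n_retained,
      first_mode = length(report$first_mode_genes)
    )
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths$manifest <- pth("manifest.json")

  structure(
    list(config = config, counts = counts, samples = samples, truth = truth,
         deg = deg, trend = trend, fits = fits, report = report,
         enrichment = enrichment, manifest = manifest, paths = paths),
    class = "tpod_pipeline"
  )
}

#' @export
print.tpod_pipeline <- function(x, ...) {
  cat("<tpod_pipeline> out_dir: ", x$config$out_dir, "\n", sep = "")
  sc <- x$manifest$stage_counts
  cat(sprintf("  genes %d -> DEG %d -> prefiltered %d -> fitted %d -> retained %d\n",
              sc$input_genes, sc$deg, sc$prefiltered, sc$fitted,
              sc$postfiltered))
  print(x$report)
  invisible(x)
}
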