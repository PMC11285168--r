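# Readers and writers for the pipeline's plain-text formats: counts TSV /
# MatrixMarket, sample sheet CSV, truth/DEG/trend/BMD tables TSV, report
# JSON. Every writer's output is re-readable by the matching reader.

#' Write / read a counts table
#'
#' TSV with genes in rows (first column `gene_id`), or MatrixMarket
#' (`.mtx`) with sidecar `<path>.rownames` / `<path>.colnames` files.
#'
#' @param counts Counts tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = NULL) {
  format <- format %||% if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- counts_to_matrix(counts)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, quote = "")
    as_tibble(d)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(path, ".rownames"))
    colnames(m) <- readLines(paste0(path, ".colnames"))
    matrix_to_tbl(m)
  }
}

#' Write / read a sample sheet
#'
#' CSV with columns `sample_id`, `concentration_uM`, `replicate`.
#'
#' @param samples Sample sheet tibble.
#' @param path Output path.
#' @return `path` (writer) or tibble (reader).
#' @export
write_samples <- function(samples, path) {
  write.table(samples, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  as_tibble(read.delim(path, sep = ",", stringsAsFactors = FALSE, quote = ""))
}

# generic TSV writers; list-columns are serialized as JSON strings
serialize_list_col <- function(x) {
  vapply(x, function(e) {
    if (is.null(e)) "null" else as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA))
  }, character(1))
}

deserialize_list_col <- function(x) {
  lapply(x, function(e) {
    if (is.na(e) || e == "null") NULL else jsonlite::fromJSON(e, simplifyVector = TRUE)
  })
}

#' Write / read a pipeline result table
#'
#' Tab-separated with a header row; list-columns (model parameters,
#' overlap gene sets, truth curves) are serialized as JSON strings.
#'
#' @param tbl Result tibble (DEG, trend, BMD, truth, or enrichment table).
#' @param path Output path.
#' @return `path` (writer) or tibble (reader).
#' @export
write_result_tsv <- function(tbl, path) {
  out <- tbl
  for (nm in names(out)) {
    if (is.list(out[[nm]])) out[[nm]] <- serialize_list_col(out[[nm]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  d <- as_tibble(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, quote = ""))
  known <- c("params", "curve", "overlap_genes", "genes")
  for (nm in intersect(known, names(d))) {
    if (is.character(d[[nm]]) && any(grepl("^\\{|^\\[|^null$", d[[nm]]))) {
      d[[nm]] <- deserialize_list_col(d[[nm]])
    }
  }
  d
}

#' Write a tPOD report as JSON
#'
#' @param report A `tpod_report` from [derive_tpods()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "tpod_report"))
  obj <- list(
    tpod_10th_uM = report$tpod_10th,
    tpod_mode_uM = report$tpod_mode,
    modes_log10 = report$modes_log10,
    antimodes_log10 = report$antimodes_log10,
    kde_bandwidth = report$bw,
    n_input = report$n_input,
    n_retained = report$n_retained,
    unimodal = report$unimodal,
    first_mode_genes = report$first_mode_genes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
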