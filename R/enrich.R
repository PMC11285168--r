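#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: set name, description, then member ids. Duplicate
#' members within a set are deduplicated; empty sets and malformed lines
#' (fewer than 3 fields) are errors reporting the line number.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with `set_name`, `description`, `genes` (list-column),
#'   `size`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file")
  parsed <- purrr::imap(lines, function(l, i) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      abort(sprintf("malformed GMT line %d: empty gene set", i))
    }
    n_members <- length(genes)
    tibble(set_name = parts[1], description = parts[2], genes = list(genes),
           size = n_members)
  })
  out <- dplyr::bind_rows(parsed)
  if (anyDuplicated(out$set_name)) abort("duplicate set names in GMT")
  out
}

#' Write a GMT gene-set collection
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$set_name, collection$description, collection$genes),
    function(nm, de, gs) paste(c(nm, de, gs), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene list and each gene set (intersected with the universe), with
#' Benjamini-Hochberg adjustment across tested terms. Terms larger than
#' `max_term_size` (after intersection) are excluded, mirroring the practice
#' of not reporting very broad terms.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of background gene ids (e.g. all genes
#'   tested for differential expression).
#' @param collection Gene-set tibble from [read_gmt()].
#' @param max_term_size Largest term size tested (default 1000).
#' @param fdr BH-adjusted significance threshold stored in `significant`.
#' @return Tibble `set_name`, `description`, `term_size`, `overlap`, `p`,
#'   `padj`, `significant`, `overlap_genes` (list-column), sorted by `padj`
#'   then `p`.
#' @export
ora <- function(query, universe, collection, max_term_size = 1000, fdr = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    abort(paste0("query ids missing from universe: ",
                 paste(head(extra, 10), collapse = ", ")))
  }
  N <- length(universe)
  nq <- length(query)
  rows <- purrr::pmap(
    list(collection$set_name, collection$description, collection$genes),
    function(nm, de, gs) {
      term <- intersect(gs, universe)
      m <- length(term)
      if (m == 0 || m > max_term_size) return(NULL)
      hit <- intersect(term, query)
      x <- length(hit)
      # P(X >= x) for X ~ Hypergeometric(N, m, nq)
      p <- phyper(x - 1, m, N - m, nq, lower.tail = FALSE)
      tibble(set_name = nm, description = de, term_size = m, overlap = x,
             p = p, overlap_genes = list(sort(hit)))
    }
  )
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (!nrow(out)) {
    return(tibble(set_name = character(), description = character(),
                  term_size = integer(), overlap = integer(), p = numeric(),
                  padj = numeric(), significant = logical(),
                  overlap_genes = list()))
  }
  out$padj <- p.adjust(out$p, method = "BH")
  out$significant <- out$padj < fdr
  out <- out[order(out$padj, out$p, out$set_name), ]
  out[, c("set_name", "description", "term_size", "overlap", "p", "padj",
          "significant", "overlap_genes")]
}
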