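#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. Optionally rewrites known
#' aliases to their canonical symbol via a two-column synonym table
#' (columns `alias`, `symbol`). No identifier-mapping service is queried;
#' the synonym table is plain configuration so analyses stay reproducible
#' offline.
#'
#' @param x character vector of gene symbols.
#' @param synonyms optional data.frame with columns `alias` and `symbol`.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbols(c(" maoa", "Grin2b"))
normalize_symbols <- function(x, synonyms = NULL) {
  x <- toupper(trimws(as.character(x)))
  if (!is.null(synonyms)) {
    stopifnot(all(c("alias", "symbol") %in% names(synonyms)))
    hit <- match(x, toupper(trimws(synonyms$alias)))
    x[!is.na(hit)] <- toupper(trimws(synonyms$symbol))[hit[!is.na(hit)]]
  }
  x
}

#' Built-in gene synonym table
#'
#' Small static alias table shipped with the package (e.g. the truncated
#' token GRIN2 for GRIN2B seen in published pathway tables).
#'
#' @return data.frame with columns `alias`, `symbol`.
#' @export
default_synonyms <- function() {
  utils::read.delim(
    system.file("extdata", "gene_synonyms.tsv", package = "netpharm"),
    stringsAsFactors = FALSE
  )
}

# split a slash-separated gene field into normalized unique symbols
split_gene_field <- function(x, synonyms = NULL) {
  parts <- strsplit(as.character(x), "/", fixed = TRUE)
  lapply(parts, function(p) {
    p <- normalize_symbols(p, synonyms)
    unique(p[nzchar(p)])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
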