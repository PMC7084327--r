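#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member gene symbols,
#'   normalized internally).
#' @param names optional named character vector of human-readable set
#'   names (defaults to the set ids).
#' @param categories optional named character vector of category tags
#'   (e.g. "BP", "CC", "MF", "KEGG"); purely bookkeeping.
#' @param background explicit gene universe; defaults to the union of all
#'   set members. Members outside an explicit background are dropped.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL, categories = NULL,
                                background = NULL) {
  if (is.null(base::names(sets)) || any(!nzchar(base::names(sets)))) {
    stop_domain("sets must be a named list")
  }
  sets <- lapply(sets, function(g) unique(normalize_symbols(g)))
  if (any(lengths(sets) == 0)) stop_domain("empty gene set")
  ids <- base::names(sets)
  if (is.null(background)) {
    background <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    background <- sort(unique(normalize_symbols(background)))
    sets <- lapply(sets, intersect, background)
    if (any(lengths(sets) == 0)) {
      stop_domain("a set has no members inside the explicit background")
    }
  }
  nm <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(names)) nm[base::names(names)] <- names
  nm[is.na(nm)] <- ids[is.na(nm)]
  cat_ <- stats::setNames(rep("all", length(ids)), ids)
  if (!is.null(categories)) cat_[base::names(categories)] <- categories
  structure(list(sets = sets, names = nm, categories = cat_,
                 background = background),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set id, description, then member genes.
#' The description field is kept as the set name; if `category_from_desc`
#' is TRUE and the description is one of BP/CC/MF/KEGG it is also used as
#' the category tag.
#'
#' @param path GMT file path.
#' @param background optional explicit gene universe.
#' @param category_from_desc use the description column as category tag
#'   when it looks like one (default TRUE).
#' @return [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL, category_from_desc = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    stop_domain("malformed GMT: each line needs id, description, >=1 gene")
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  categories <- NULL
  if (category_from_desc) {
    tag <- toupper(desc)
    if (all(tag %in% c("BP", "CC", "MF", "KEGG"))) {
      categories <- stats::setNames(tag, ids)
      desc <- ids
    }
  }
  gene_set_collection(sets, names = stats::setNames(desc, ids),
                      categories = categories, background = background)
}

#' Write a gene-set collection as GMT
#'
#' @param collection [gene_set_collection()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' Exact upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: the chance of drawing at least `k`
#' annotated genes when `n` genes are drawn without replacement from a
#' universe of `N` genes of which `K` carry the annotation. Vectorized
#' over its arguments.
#'
#' @param k observed overlap; `0 <= k <= min(K, n)`.
#' @param K annotated-set size; `n` query size; `N` background size.
#' @return upper-tail p-value(s) in (0, 1].
#' @export
#' @examples
#' hypergeom_test(3, 4, 5, 10)  # 66/252
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stop_domain("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment `adj_i = min_{j >= i} (p_(j) m / j)`
#' capped at 1, with the input order restored. `m_total` lets a reported
#' subset of a larger test family be adjusted against the full family
#' size (e.g. ten published rows out of 146 tested sets).
#'
#' @param pvals raw p-values in (0, 1].
#' @param m_total family size; defaults to `length(pvals)` and must not
#'   be smaller.
#' @return adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(pvals, m_total = length(pvals)) {
  if (any(pvals <= 0 | pvals > 1)) stop_domain("p-values must lie in (0, 1]")
  if (m_total < length(pvals)) {
    stop_domain("m_total must be >= length(pvals)")
  }
  stats::p.adjust(pvals, method = "BH", n = m_total)
}

#' Over-representation analysis of a query gene set
#'
#' For every set in the collection computes the hypergeometric
#' upper-tail p-value of its overlap with the query, adjusts the whole
#' family by Benjamini-Hochberg, screens on raw p <= `p_cutoff`, sorts by
#' raw p ascending (ties: larger overlap, then set id) and truncates to
#' `top_n` sets per category. Query genes outside the background are
#' dropped with a warning.
#'
#' @param query character vector of gene symbols.
#' @param collection [gene_set_collection()].
#' @param p_cutoff screening cutoff on the raw p-value (default 0.05).
#' @param top_n maximum sets reported per category (default Inf).
#' @param m_total BH family size; defaults to the number of sets tested.
#' @return data.frame with set_id, name, category, k, K, n, N, p_raw,
#'   p_adjust and slash-separated hit_genes.
#' @export
enrich <- function(query, collection, p_cutoff = 0.05, top_n = Inf,
                   m_total = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(normalize_symbols(query))
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop_domain("query empty after background intersection")
  N <- length(collection$background)
  n <- length(query)
  ids <- names(collection$sets)
  hits <- lapply(collection$sets, intersect, query)
  k <- lengths(hits)
  K <- lengths(collection$sets)
  p_raw <- hypergeom_test(k, K, n, N)
  m <- m_total %||% length(ids)
  res <- data.frame(
    set_id = ids,
    name = unname(collection$names[ids]),
    category = unname(collection$categories[ids]),
    k = as.integer(k), K = as.integer(K), n = n, N = N,
    p_raw = unname(p_raw),
    p_adjust = unname(bh_adjust(p_raw, m_total = m)),
    hit_genes = vapply(hits, function(g) paste(sort(g), collapse = "/"),
                       character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- res[res$p_raw <= p_cutoff, , drop = FALSE]
  res <- res[order(res$p_raw, -res$k, res$set_id), , drop = FALSE]
  if (is.finite(top_n) && nrow(res)) {
    res <- do.call(rbind, lapply(split(res, res$category), utils::head, top_n))
    res <- res[order(res$p_raw, -res$k, res$set_id), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}
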