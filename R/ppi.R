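#' Load and filter a protein-protein interaction edge table
#'
#' Reads a STRING-dialect TSV (`node1`, `node2`, `combined_score`),
#' normalizes the score dialect, keeps edges with confidence >=
#' `min_confidence`, drops self-loops and duplicate undirected edges, and
#' removes nodes left isolated by the filter. Score dialects: values in
#' [0, 1] are used as-is; any value > 1 switches the whole table to the
#' 0-1000 STRING convention (divided by 1000). A table mixing values > 1
#' with fractional values in (0, 1) is rejected as ambiguous.
#'
#' @param edges TSV path or a data.frame with the three columns.
#' @param min_confidence confidence cutoff on the 0-1 scale (default 0.7,
#'   i.e. STRING combined score 700); comparison is inclusive.
#' @param synonyms optional synonym table for [normalize_symbols()].
#' @return undirected igraph with edge attribute `score` and node
#'   attribute `type = "protein"`.
#' @export
load_ppi <- function(edges, min_confidence = 0.7, synonyms = NULL) {
  df <- if (is.character(edges)) {
    utils::read.delim(edges, stringsAsFactors = FALSE)
  } else {
    as.data.frame(edges, stringsAsFactors = FALSE)
  }
  required <- c("node1", "node2", "combined_score")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_domain("PPI table is missing columns: ",
                paste(missing, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(!is.finite(score) | !nzchar(trimws(df$node1)) |
                 !nzchar(trimws(df$node2)))
  if (length(bad)) {
    stop_domain("malformed PPI row(s) at line(s): ",
                paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  score <- normalize_ppi_scores(score)
  u <- normalize_symbols(df$node1, synonyms)
  v <- normalize_symbols(df$node2, synonyms)
  keep <- score >= min_confidence & u != v
  u <- u[keep]; v <- v[keep]; score <- score[keep]
  # canonical undirected key, first occurrence wins
  lo <- pmin(u, v); hi <- pmax(u, v)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  ed <- data.frame(from = lo[!dup], to = hi[!dup], score = score[!dup],
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  if (igraph::vcount(g)) igraph::V(g)$type <- "protein"
  g
}

normalize_ppi_scores <- function(score) {
  if (!length(score)) return(score)
  if (any(score < 0) || any(score > 1000)) {
    stop_domain("PPI scores outside both the 0-1 and 0-1000 dialects")
  }
  if (any(score > 1)) {
    frac <- score > 0 & score < 1
    if (any(frac)) {
      stop_domain("mixed PPI score dialects: values both in (0,1) and > 1")
    }
    score <- score / 1000
  }
  score
}

#' Rank network nodes by degree
#'
#' Descending degree, ties broken lexicographically by node name so the
#' ranking is deterministic.
#'
#' @param net igraph.
#' @param k number of top nodes to return.
#' @return data.frame with columns `node` and `degree`.
#' @export
degree_ranking <- function(net, k = 10) {
  if (igraph::vcount(net) == 0) stop_domain("empty network")
  if (k <= 0) stop_domain("k must be positive")
  d <- igraph::degree(net)
  ord <- order(-d, names(d))
  utils::head(
    data.frame(node = names(d)[ord], degree = as.integer(d[ord]),
               row.names = NULL, stringsAsFactors = FALSE),
    k
  )
}

#' Intersect herb and disease targets and induce the PPI subnetwork
#'
#' Computes the overlap of two symbol sets (e.g. herb component targets
#' and disease-associated genes) and induces the subgraph of `ppi` on the
#' overlap: nodes are overlap genes present in the PPI, edges are PPI
#' edges with both endpoints in the overlap. An empty overlap yields an
#' empty network.
#'
#' @param herb_targets,disease_targets character vectors of gene symbols
#'   (normalized internally).
#' @param ppi igraph from [load_ppi()].
#' @return list with `network` (igraph) and `venn`, the named counts
#'   `a_only`, `b_only`, `both`.
#' @export
intersect_subnetwork <- function(herb_targets, disease_targets, ppi) {
  a <- unique(normalize_symbols(herb_targets))
  b <- unique(normalize_symbols(disease_targets))
  both <- intersect(a, b)
  nodes <- intersect(both, igraph::V(ppi)$name)
  sub <- igraph::induced_subgraph(ppi, nodes)
  list(network = sub,
       venn = c(a_only = length(setdiff(a, b)),
                b_only = length(setdiff(b, a)),
                both = length(both)))
}
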