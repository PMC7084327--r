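#' Read a component-target association table
#'
#' TSV with columns `component_id`, `target`, `source` and optionally
#' `score`. Sources are `identified` (experimentally curated) or the
#' prediction tools `hitpick` (score = precision) and `sea`
#' (score = MaxTc, the maximum Tanimoto similarity to a known ligand).
#' Target symbols are normalized (uppercased, trimmed).
#'
#' @param path TSV path.
#' @param synonyms optional synonym table for [normalize_symbols()].
#' @return data.frame of associations.
#' @export
read_associations <- function(path, synonyms = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("component_id", "target", "source")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_domain("association table is missing columns: ",
                paste(missing, collapse = ", "))
  }
  if (!"score" %in% names(df)) df$score <- NA_real_
  df$target <- normalize_symbols(df$target, synonyms)
  df$source <- tolower(trimws(df$source))
  if (any(!nzchar(df$target))) stop_domain("empty target symbol")
  bad <- is.finite(df$score) & (df$score < 0 | df$score > 1)
  if (any(bad)) stop_domain("association scores must lie in [0, 1]")
  df
}

#' Filter predicted associations by score
#'
#' Curated (`identified`) rows always pass. Predicted rows are kept when
#' their score meets the tool's threshold: precision >= `min_precision`
#' for hitpick, MaxTc >= `min_maxtc` for sea. Predicted rows with a
#' missing score are dropped with a warning by default.
#'
#' @param assocs association data.frame (see [read_associations()]).
#' @param min_precision HitPick precision cutoff (default 0.5).
#' @param min_maxtc SEA maximum-Tanimoto cutoff (default 0.5).
#' @param missing_score one of "drop" (default, warns), "keep", "error".
#' @return filtered data.frame.
#' @export
filter_predictions <- function(assocs, min_precision = 0.5, min_maxtc = 0.5,
                               missing_score = c("drop", "keep", "error")) {
  missing_score <- match.arg(missing_score)
  src <- tolower(assocs$source)
  predicted <- src %in% c("hitpick", "sea")
  nos <- predicted & !is.finite(assocs$score)
  if (any(nos)) {
    msg <- paste0(sum(nos), " predicted association(s) lack a score")
    if (missing_score == "error") stop_domain(msg)
    if (missing_score == "drop") warning(msg, "; dropped", call. = FALSE)
  }
  keep <- !predicted |
    (src == "hitpick" & is.finite(assocs$score) & assocs$score >= min_precision) |
    (src == "sea" & is.finite(assocs$score) & assocs$score >= min_maxtc)
  if (missing_score == "keep") keep <- keep | nos
  assocs[keep, , drop = FALSE]
}

#' Deduplicate associations into unique edges and targets
#'
#' Union semantics: the same (component, target) pair reported by several
#' sources collapses to one edge; the unique target set is the union over
#' all components and sources. Idempotent and independent of row order.
#'
#' @param assocs association data.frame.
#' @return list with `edges` (data.frame component_id, target) and
#'   `targets` (sorted character vector).
#' @export
dedup_union <- function(assocs) {
  if (nrow(assocs) == 0) {
    return(list(edges = data.frame(component_id = character(),
                                   target = character(),
                                   stringsAsFactors = FALSE),
                targets = character()))
  }
  e <- unique(assocs[c("component_id", "target")])
  e <- e[order(e$component_id, e$target), , drop = FALSE]
  rownames(e) <- NULL
  list(edges = e, targets = sort(unique(e$target)))
}

#' Component-target network summary statistics
#'
#' Two headline ratios of a bipartite component-target network: the
#' average number of targets per component (`n_targets / n_components`)
#' and the mean number of components hitting each target
#' (`n_edges / n_targets`). Full precision is retained; `round()` the
#' fields for display.
#'
#' @param n_components,n_targets,n_edges non-negative counts;
#'   `n_components` and `n_targets` must be positive.
#' @return list of class `ct_stats`.
#' @export
#' @examples
#' s <- ct_stats(11, 267, 509)
#' round(s$targets_per_component, 1)  # 24.3
ct_stats <- function(n_components, n_targets, n_edges) {
  if (n_components <= 0 || n_targets <= 0) {
    stop_domain("n_components and n_targets must be positive")
  }
  if (n_edges < 0) stop_domain("n_edges must be non-negative")
  structure(
    list(n_components = n_components, n_targets = n_targets,
         n_edges = n_edges,
         targets_per_component = n_targets / n_components,
         mean_component_degree_per_target = n_edges / n_targets),
    class = "ct_stats"
  )
}

#' @export
print.ct_stats <- function(x, ...) {
  cat(sprintf(
    "C-T network: %d components, %d targets, %d edges\n", x$n_components,
    x$n_targets, x$n_edges))
  cat(sprintf("  targets per component: %.1f\n", x$targets_per_component))
  cat(sprintf("  mean component degree per target: %.1f\n",
              x$mean_component_degree_per_target))
  invisible(x)
}

#' Build the bipartite component-target network
#'
#' Deduplicates the associations and assembles an undirected igraph with
#' node attribute `type` set to "component" or "target".
#'
#' @param assocs association data.frame (already filtered).
#' @return list with `network` (igraph) and `stats` ([ct_stats()]).
#' @export
build_ct_network <- function(assocs) {
  dd <- dedup_union(assocs)
  comps <- sort(unique(dd$edges$component_id))
  if (length(intersect(comps, dd$targets))) {
    stop_domain("component ids collide with target symbols")
  }
  g <- igraph::graph_from_data_frame(
    dd$edges, directed = FALSE,
    vertices = data.frame(
      name = c(comps, dd$targets),
      type = rep(c("component", "target"), c(length(comps), length(dd$targets))),
      stringsAsFactors = FALSE
    )
  )
  list(network = g,
       stats = ct_stats(length(comps), length(dd$targets), nrow(dd$edges)))
}
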