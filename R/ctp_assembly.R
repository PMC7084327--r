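#' Read a pathway-enrichment table
#'
#' Tab-separated table in the published dialect: columns `ID`, `Pathway`,
#' `p`, `p.adjust`, `Count` and a slash-separated `GeneIDs` field.
#' Gene tokens are trimmed, uppercased and passed through the synonym
#' table (truncated aliases such as GRIN2 resolve to GRIN2B); the reader
#' reports when that normalization changes the unique-target union so
#' both readings of the published counts stay visible.
#'
#' @param path TSV path.
#' @param synonyms synonym data.frame (default [default_synonyms()]);
#'   `NULL` disables alias resolution.
#' @return data.frame with a `genes` list-column of normalized symbols.
#' @export
read_pathway_table <- function(path, synonyms = default_synonyms()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  gene_col <- intersect(c("GeneIDs", "Gene IDs", "genes"), names(df))[1]
  if (is.na(gene_col)) stop_domain("no gene-list column found")
  if (!"ID" %in% names(df)) stop_domain("pathway table needs an ID column")
  raw <- split_gene_field(df[[gene_col]], synonyms = NULL)
  df$genes <- split_gene_field(df[[gene_col]], synonyms = synonyms)
  n_raw <- length(unique(unlist(raw)))
  n_norm <- length(unique(unlist(df$genes)))
  if (n_raw != n_norm) {
    message("synonym normalization merged targets: ", n_raw, " -> ", n_norm,
            " unique symbols")
  }
  empty <- lengths(df$genes) == 0
  if (any(empty)) {
    warning("pathway row(s) with empty gene list: ",
            paste(df$ID[empty], collapse = ", "), call. = FALSE)
  }
  df
}

#' Build the target-pathway bipartite network
#'
#' One node per pathway and per unique target gene; one edge per
#' (pathway, member gene) pair after symbol normalization, duplicates
#' within a row counted once.
#'
#' @param pathway_table data.frame from [read_pathway_table()] (or any
#'   data.frame with `ID` and a `genes` list-column).
#' @return list with `network` (igraph, node attribute
#'   `type` in pathway/target) and `stats` (n_pathways, n_targets,
#'   n_nodes, n_edges).
#' @export
build_tp_network <- function(pathway_table) {
  stopifnot(is.data.frame(pathway_table), "genes" %in% names(pathway_table))
  ids <- as.character(pathway_table$ID)
  edges <- do.call(rbind, lapply(seq_along(ids), function(i) {
    g <- unique(pathway_table$genes[[i]])
    if (!length(g)) return(NULL)
    data.frame(from = ids[i], to = g, stringsAsFactors = FALSE)
  }))
  targets <- sort(unique(edges$to))
  if (length(intersect(ids, targets))) {
    stop_domain("pathway ids collide with target symbols")
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(
      name = c(ids, targets),
      type = rep(c("pathway", "target"), c(length(ids), length(targets))),
      stringsAsFactors = FALSE
    )
  )
  list(network = g,
       stats = list(n_pathways = length(ids), n_targets = length(targets),
                    n_nodes = length(ids) + length(targets),
                    n_edges = igraph::ecount(g)))
}

#' Merge component-target and target-pathway layers
#'
#' Union of the two bipartite networks into one tripartite
#' component-target-pathway graph. Targets appearing in both layers fuse
#' into single nodes; node types are preserved. A name shared between a
#' component (or pathway) and a gene symbol would silently fuse unrelated
#' nodes, so namespace collisions across types are an error.
#'
#' @param ct_net component-target igraph (types component/target).
#' @param tp_net target-pathway igraph (types pathway/target).
#' @return list with `network` and `summary` (per-type node counts and
#'   per-layer edge counts).
#' @export
build_ctp_network <- function(ct_net, tp_net) {
  type_of <- function(g) stats::setNames(igraph::V(g)$type,
                                         igraph::V(g)$name)
  t1 <- type_of(ct_net); t2 <- type_of(tp_net)
  shared <- intersect(names(t1), names(t2))
  clash <- shared[t1[shared] != t2[shared]]
  if (length(clash)) {
    stop_domain("node name(s) used with conflicting types: ",
                paste(utils::head(clash, 5), collapse = ", "))
  }
  e1 <- igraph::as_data_frame(ct_net, what = "edges")[1:2]
  e2 <- igraph::as_data_frame(tp_net, what = "edges")[1:2]
  e1$layer <- "component-target"; e2$layer <- "target-pathway"
  types <- c(t1, t2[setdiff(names(t2), names(t1))])
  g <- igraph::graph_from_data_frame(
    rbind(e1, e2), directed = FALSE,
    vertices = data.frame(name = names(types), type = unname(types),
                          stringsAsFactors = FALSE)
  )
  list(network = g,
       summary = list(
         n_nodes_by_type = as.list(table(igraph::V(g)$type)),
         n_edges_by_layer = as.list(table(igraph::E(g)$layer)),
         n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)))
}

#' Export a network
#'
#' Formats: `"graphml"` (full attribute round-trip), `"sif"` (simple
#' interaction format: one `node relation node` line per edge, isolated
#' nodes as bare lines; node attributes are not representable), and
#' `"tsv"` (an edge table `from    to  layer/score...` plus a companion
#' `<path>.nodes.tsv` with node types).
#'
#' @param net igraph.
#' @param path output file path.
#' @param format one of "graphml", "sif", "tsv".
#' @param relation SIF interaction label (default "pp").
#' @return invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "tsv"),
                           relation = "pp") {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else if (format == "sif") {
    e <- igraph::as_data_frame(net, what = "edges")
    lines <- if (nrow(e)) paste(e$from, relation, e$to, sep = "\t") else character()
    iso <- igraph::V(net)$name[igraph::degree(net) == 0]
    writeLines(c(lines, iso), path)
  } else {
    e <- igraph::as_data_frame(net, what = "edges")
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    v <- igraph::as_data_frame(net, what = "vertices")
    utils::write.table(v, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path file path.
#' @param format one of "graphml", "sif", "tsv".
#' @return igraph.
#' @export
import_network <- function(path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
    iso <- vapply(parts, length, integer(1)) == 1
    edges <- do.call(rbind, lapply(parts[!iso], function(p) {
      data.frame(from = p[1], to = p[3], stringsAsFactors = FALSE)
    }))
    g <- igraph::graph_from_data_frame(
      edges %||% data.frame(from = character(), to = character()),
      directed = FALSE)
    if (any(iso)) {
      g <- igraph::add_vertices(
        g, sum(iso), name = vapply(parts[iso], `[[`, character(1), 1))
    }
    return(g)
  }
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes_path <- paste0(path, ".nodes.tsv")
  v <- if (file.exists(nodes_path)) {
    utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  } else NULL
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}
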