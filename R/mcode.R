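# MCODE-style molecular complex detection: k-core vertex weighting,
# seed-and-grow cluster prediction, haircut/fluff post-processing and the
# density x size cluster score. Implemented directly on igraph objects;
# all tie-breaks are lexicographic on node name so results are
# deterministic across runs and input orderings.

#' k-core decomposition
#'
#' Core number of every vertex: the largest k such that the vertex belongs
#' to a subgraph in which every vertex has degree >= k. Computed by
#' iterative minimum-degree peeling (ties broken by node name).
#'
#' @param net simple undirected igraph.
#' @return named integer vector of core numbers.
#' @export
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("A", "B", "C")
#' core_number(g)  # all 2
core_number <- function(net) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  core <- stats::setNames(integer(n), nm)
  if (n == 0) return(core)
  deg <- as.integer(igraph::degree(net, loops = FALSE))
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  alive <- rep(TRUE, n)
  ord_name <- order(nm)          # positional rank for lexicographic ties
  name_rank <- integer(n); name_rank[ord_name] <- seq_len(n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[order(deg[cand], name_rank[cand])][1]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  core
}

# loopless density 2E / (N (N-1)); 0 for N < 2
graph_density2 <- function(n_nodes, n_edges) {
  if (n_nodes < 2) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' MCODE vertex weighting
#'
#' Weight of a vertex = k_max x density of the highest k-core of the
#' subgraph induced on its closed neighborhood, where k_max is that
#' subgraph's maximum core number and density is the loopless
#' 2E/(N(N-1)). Dense, highly interconnected neighborhoods give high
#' weights; isolated vertices weigh 0.
#'
#' @param net simple undirected igraph.
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(igraph::vcount(net)))
    igraph::V(net)$name <- nm
  }
  adj <- igraph::as_adj_list(net, mode = "all")
  w <- stats::setNames(numeric(igraph::vcount(net)), nm)
  for (i in seq_along(w)) {
    nb <- unique(c(i, as.integer(adj[[i]])))
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(net, nb)
    cores <- core_number(sub)
    kmax <- max(cores)
    if (kmax == 0) next
    kc <- igraph::induced_subgraph(sub, names(cores)[cores >= kmax])
    w[i] <- kmax * graph_density2(igraph::vcount(kc), igraph::ecount(kc))
  }
  w
}

#' MCODE parameter set
#'
#' @param k_core minimum core a reported cluster must contain (>= 2);
#'   typical values are 2 for small direct-interaction networks and 5 for
#'   large disease PPI networks.
#' @param vwp vertex weight percentage in [0, 1): during growth a
#'   neighbor joins the cluster when its weight is at least
#'   `(1 - vwp) * seed_weight`.
#' @param haircut drop weakly attached (degree < 2) members after growth.
#' @param fluff add boundary neighbors whose closed-neighborhood density
#'   exceeds `fluff_density_threshold` (off by default; fluffed clusters
#'   may overlap).
#' @param fluff_density_threshold density cutoff for fluff.
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(k_core = 2, vwp = 0.2, haircut = TRUE,
                         fluff = FALSE, fluff_density_threshold = 0.5) {
  if (k_core < 2) stop_domain("k_core must be >= 2")
  if (vwp < 0 || vwp >= 1) stop_domain("vwp must lie in [0, 1)")
  structure(list(k_core = as.integer(k_core), vwp = vwp, haircut = haircut,
                 fluff = fluff,
                 fluff_density_threshold = fluff_density_threshold),
            class = "mcode_params")
}

#' Cluster score: density times size
#'
#' `score = (2E / (N (N-1))) * N = 2E / (N-1)`, the loopless internal
#' density of the cluster multiplied by its node count. A clique of size N
#' scores exactly N.
#'
#' @param n_nodes,n_edges cluster node and edge counts (vectorized).
#' @return numeric score(s).
#' @export
#' @examples
#' cluster_score(63, 1042)  # 33.613...
cluster_score <- function(n_nodes, n_edges) {
  if (any(n_nodes < 2)) stop_domain("cluster_score requires n_nodes >= 2")
  if (any(n_edges < 0)) stop_domain("n_edges must be non-negative")
  2 * n_edges / (n_nodes - 1)
}

#' Detect dense clusters (MCODE-style)
#'
#' Seed-and-grow molecular complex detection. Vertices are weighted by
#' [vertex_weights()]; clusters are grown greedily from the
#' highest-weight unvisited seed, admitting unvisited neighbors whose
#' weight is at least `(1 - vwp) * seed_weight` (breadth-first, so
#' clusters are node-disjoint unless fluff is enabled). Post-processing:
#' optional fluff, optional haircut (iterative removal of degree < 2
#' members), then clusters lacking an internal k-core of order
#' `params$k_core` are discarded — raising `k_core` therefore never
#' increases the number of clusters. Output is sorted by score
#' descending, ties by size then by lexicographically smallest member,
#' and each cluster records its growth seed.
#'
#' @param net simple undirected igraph (loops/multi-edges are removed).
#' @param params [mcode_params()].
#' @return object of class `mcode_clusters`: list of clusters, each with
#'   `members`, `n_nodes`, `n_edges`, `score`, `seed`, `rank`. Coerce
#'   with [as.data.frame()] for a Table-style summary.
#' @export
find_clusters <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  net <- igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(net)$name)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  }
  nm <- igraph::V(net)$name
  w <- vertex_weights(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  seen <- stats::setNames(rep(FALSE, length(nm)), nm)
  raw <- list()
  for (s in order(-w, nm)) {
    if (seen[s]) next
    thr <- (1 - params$vwp) * w[s]
    members <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (u in as.integer(adj[[v]])) {
        if (!seen[u] && w[u] >= thr) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    raw[[length(raw) + 1]] <- list(members = nm[members], seed = nm[s])
  }
  clusters <- list()
  for (cl in raw) {
    members <- cl$members
    if (params$fluff) {
      members <- fluff_members(net, members, w,
                               params$fluff_density_threshold)
    }
    sub <- igraph::induced_subgraph(net, members)
    if (params$haircut) sub <- haircut(sub)
    if (igraph::vcount(sub) < 2) next
    if (max(core_number(sub)) < params$k_core) next
    nn <- igraph::vcount(sub); ne <- igraph::ecount(sub)
    clusters[[length(clusters) + 1]] <- list(
      members = sort(igraph::V(sub)$name), n_nodes = nn, n_edges = ne,
      score = cluster_score(nn, ne), seed = cl$seed
    )
  }
  if (length(clusters)) {
    first <- vapply(clusters, function(x) x$members[1], character(1))
    ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
                 -vapply(clusters, `[[`, numeric(1), "n_nodes"),
                 first)
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) clusters[[i]]$rank <- i
  }
  structure(clusters, class = "mcode_clusters")
}

# iterative removal of degree < 2 vertices (2-core of the cluster)
haircut <- function(sub) {
  repeat {
    d <- igraph::degree(sub)
    drop <- names(d)[d < 2]
    if (!length(drop) || igraph::vcount(sub) <= length(drop)) {
      if (length(drop)) sub <- igraph::induced_subgraph(sub, character(0))
      return(sub)
    }
    sub <- igraph::induced_subgraph(sub, setdiff(names(d), drop))
  }
}

fluff_members <- function(net, members, w, dens_thr) {
  boundary <- setdiff(
    unique(unlist(lapply(igraph::adjacent_vertices(net, members),
                         igraph::as_ids))),
    members
  )
  add <- character(0)
  for (u in boundary) {
    nb <- unique(c(u, names(igraph::neighbors(net, u))))
    sub <- igraph::induced_subgraph(net, nb)
    if (graph_density2(igraph::vcount(sub), igraph::ecount(sub)) > dens_thr) {
      add <- c(add, u)
    }
  }
  c(members, add)
}

#' @export
as.data.frame.mcode_clusters <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(rank = integer(), score = numeric(),
                      nodes = integer(), edges = integer(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rank = vapply(x, `[[`, numeric(1), "rank"),
    score = vapply(x, `[[`, numeric(1), "score"),
    nodes = vapply(x, `[[`, numeric(1), "n_nodes"),
    edges = vapply(x, `[[`, numeric(1), "n_edges"),
    seed = vapply(x, `[[`, character(1), "seed"),
    members = vapply(x, function(cl) paste(cl$members, collapse = "/"),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mcode_clusters <- function(x, ...) {
  cat(length(x), "cluster(s)\n")
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}
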