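# Independent brute-force oracles and fixture loaders used across tests.
# Oracles never call the implementation paths they check.

extdata <- function(f) system.file("extdata", f, package = "netpharm")

load_cluster_table <- function(f) {
  utils::read.delim(extdata(f), stringsAsFactors = FALSE)
}

# exhaustive enumeration of all C(N, n) draws; overlap tail P(X >= k)
brute_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  ov <- colSums(matrix(draws <= K, nrow = n))
  mean(ov >= k)
}

# k-core membership by iterative pruning of degree < k vertices
brute_kcore_members <- function(g, k) {
  nodes <- igraph::V(g)$name
  repeat {
    sub <- igraph::induced_subgraph(g, nodes)
    d <- igraph::degree(sub)
    drop <- names(d)[d < k]
    if (!length(drop)) return(sort(nodes))
    nodes <- setdiff(nodes, drop)
    if (!length(nodes)) return(character(0))
  }
}

# core number per vertex: largest k whose k-core contains it
brute_core_number <- function(g) {
  nm <- igraph::V(g)$name
  core <- stats::setNames(rep(0L, length(nm)), nm)
  k <- 1L
  repeat {
    members <- brute_kcore_members(g, k)
    if (!length(members)) return(core)
    core[members] <- k
    k <- k + 1L
  }
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

named_clique <- function(n, prefix = "V") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}
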