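test_that("core numbers match iterative-pruning oracle on canonical graphs", {
  tri <- named_clique(3, "T")
  expect_equal(unname(core_number(tri)), rep(2L, 3))
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("S", 1:6)
  expect_equal(unname(core_number(star)), rep(1L, 6))
  # K5 plus a pendant vertex
  g <- named_clique(5, "K")
  g <- igraph::add_vertices(g, 1, name = "PEND")
  g <- igraph::add_edges(g, c("K01", "PEND"))
  cn <- core_number(g)
  expect_equal(unname(cn[paste0("K0", 1:5)]), rep(4L, 5))
  expect_equal(unname(cn["PEND"]), 1L)
  expect_equal(cn, brute_core_number(g))
})

test_that("core numbers agree with pruning oracle and igraph on random graphs", {
  for (seed in 1:5) {
    g <- random_named_gnp(25, 0.15, seed = seed)
    cn <- core_number(g)
    expect_equal(cn, brute_core_number(g))
    expect_equal(unname(cn), unname(igraph::coreness(g)))
  }
})

test_that("vertex weights: closed-neighborhood core density", {
  # isolated edge: each endpoint sees K2 -> core 1, density 1 -> weight 1
  e <- igraph::graph_from_edgelist(rbind(c("u", "v")), directed = FALSE)
  expect_equal(unname(vertex_weights(e)), c(1, 1))
  # any clique K_n: every vertex weight n - 1
  for (n in 3:6) {
    expect_equal(unname(vertex_weights(named_clique(n))), rep(n - 1, n))
  }
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- c("a", "b", "c")
  expect_equal(unname(vertex_weights(empty)), rep(0, 3))
})

test_that("cluster score reproduces every published (nodes, edges, score)", {
  for (f in c("dd_clusters.tsv", "hrdd_clusters.tsv")) {
    tab <- load_cluster_table(f)
    expect_equal(round(cluster_score(tab$nodes, tab$edges), 3),
                 round(tab$score, 3))
  }
  # a single edge is a 2-clique: density 1, score = N = 2
  expect_equal(cluster_score(2, 1), 2)
  expect_error(cluster_score(1, 0), "n_nodes")
})

test_that("planted cliques are recovered exactly on a sparse background", {
  pg <- gen_planted_graph(40, 0.03, c(6, 6), seed = 1)
  cl <- find_clusters(pg$graph, mcode_params(k_core = 5))
  expect_length(cl, 2L)
  got <- lapply(cl, `[[`, "members")
  expect_setequal(got, lapply(pg$modules, sort))
  expect_equal(vapply(cl, `[[`, numeric(1), "score"), c(6, 6))
  expect_true(all(vapply(cl, `[[`, character(1), "seed") %in%
                    unlist(pg$modules)))
})

test_that("k-core filter and haircut behave on a bare K4", {
  k4 <- named_clique(4, "Q")
  expect_length(find_clusters(k4, mcode_params(k_core = 5)), 0L)
  cl <- find_clusters(k4, mcode_params(k_core = 2, haircut = TRUE))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, sprintf("Q%02d", 1:4))
  expect_equal(cl[[1]]$score, 4)
  expect_equal(cl[[1]]$n_edges, 6L)
})

test_that("haircut prunes weakly attached members", {
  g <- named_clique(5, "C")
  g <- igraph::add_vertices(g, 1, name = "TAIL")
  g <- igraph::add_edges(g, c("C01", "TAIL"))
  # wide vwp so the low-weight tail joins during growth
  cl <- find_clusters(g, mcode_params(k_core = 2, vwp = 0.8, haircut = TRUE))
  expect_length(cl, 1L)
  expect_false("TAIL" %in% cl[[1]]$members)
  no_hc <- find_clusters(g, mcode_params(k_core = 2, vwp = 0.8,
                                         haircut = FALSE))
  expect_true("TAIL" %in% no_hc[[1]]$members)
})

test_that("clusters are node-disjoint and each contains its k-core", {
  g <- random_named_gnp(60, 0.12, seed = 4)
  cl <- find_clusters(g, mcode_params(k_core = 2))
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  for (c_i in cl) {
    sub <- igraph::induced_subgraph(g, c_i$members)
    expect_gte(max(core_number(sub)), 2)
    expect_equal(c_i$score, cluster_score(c_i$n_nodes, c_i$n_edges))
  }
})

test_that("raising k_core never increases the cluster count", {
  g <- random_named_gnp(50, 0.15, seed = 6)
  counts <- vapply(2:6, function(k) {
    length(find_clusters(g, mcode_params(k_core = k)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is deterministic and invariant to vertex order", {
  pg <- gen_planted_graph(30, 0.08, c(5, 4), seed = 9)
  p <- mcode_params(k_core = 2)
  a <- find_clusters(pg$graph, p)
  b <- find_clusters(pg$graph, p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  set.seed(1)
  g_perm <- igraph::permute(pg$graph,
                            sample(igraph::vcount(pg$graph)))
  c_perm <- find_clusters(g_perm, p)
  expect_identical(as.data.frame(a), as.data.frame(c_perm))
})

test_that("fluff may only add boundary nodes in dense neighborhoods", {
  g <- named_clique(5, "F")
  g <- igraph::add_vertices(g, 2, name = c("X", "Y"))
  g <- igraph::add_edges(g, c("F01", "X", "F02", "X", "X", "Y", "F03", "Y"))
  base <- find_clusters(g, mcode_params(k_core = 2, haircut = FALSE))
  fl <- find_clusters(g, mcode_params(k_core = 2, haircut = FALSE,
                                      fluff = TRUE,
                                      fluff_density_threshold = 0.5))
  expect_true(all(base[[1]]$members %in% fl[[1]]$members))
})
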