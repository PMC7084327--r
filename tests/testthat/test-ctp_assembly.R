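test_that("pathway-table reader normalizes slash-separated gene fields", {
  expect_message(
    ptab <- read_pathway_table(extdata("kegg_pathways.tsv")),
    "merged targets: 24 -> 23")
  expect_equal(nrow(ptab), 10L)
  expect_true("GRIN2B" %in% ptab$genes[[2]])
  expect_false("GRIN2" %in% unlist(ptab$genes))
  # without synonyms the truncated token survives
  raw <- suppressMessages(
    read_pathway_table(extdata("kegg_pathways.tsv"), synonyms = NULL))
  expect_true("GRIN2" %in% unlist(raw$genes))
})

test_that("target-pathway network matches the published fixture counts", {
  ptab <- suppressMessages(read_pathway_table(extdata("kegg_pathways.tsv")))
  tp <- build_tp_network(ptab)
  expect_equal(tp$stats$n_pathways, 10L)
  expect_equal(tp$stats$n_targets, 23L)
  expect_equal(tp$stats$n_nodes, 33L)
  expect_equal(tp$stats$n_edges, 71)
  # edge count = sum of per-pathway unique gene counts = printed Counts
  expect_equal(sum(lengths(lapply(ptab$genes, unique))), 71L)
  expect_equal(sum(ptab$Count), 71L)
})

test_that("target-pathway toy cases use set semantics", {
  one <- data.frame(ID = "P1", stringsAsFactors = FALSE)
  one$genes <- list(c("A", "B"))
  tp <- build_tp_network(one)
  expect_equal(tp$stats$n_nodes, 3L)
  expect_equal(tp$stats$n_edges, 2)
  dup <- data.frame(ID = "P1", stringsAsFactors = FALSE)
  dup$genes <- list(c("A", "A", "B"))
  expect_equal(build_tp_network(dup)$stats$n_edges, 2)
})

test_that("tripartite merge fuses shared targets and keeps types", {
  ct <- igraph::graph_from_data_frame(
    data.frame(from = "c1", to = "T1"), directed = FALSE,
    vertices = data.frame(name = c("c1", "T1"),
                          type = c("component", "target")))
  tp <- igraph::graph_from_data_frame(
    data.frame(from = "P1", to = "T1"), directed = FALSE,
    vertices = data.frame(name = c("P1", "T1"),
                          type = c("pathway", "target")))
  ctp <- build_ctp_network(ct, tp)
  expect_equal(ctp$summary$n_nodes, 3L)
  expect_equal(ctp$summary$n_edges, 2L)
  expect_equal(sort(unlist(ctp$summary$n_nodes_by_type)),
               c(component = 1L, pathway = 1L, target = 1L))
  # disjoint target sets are additive
  tp2 <- igraph::graph_from_data_frame(
    data.frame(from = "P1", to = "T2"), directed = FALSE,
    vertices = data.frame(name = c("P1", "T2"),
                          type = c("pathway", "target")))
  expect_equal(build_ctp_network(ct, tp2)$summary$n_nodes, 4L)
  # namespace collision across types is an error
  bad <- igraph::graph_from_data_frame(
    data.frame(from = "P1", to = "c1"), directed = FALSE,
    vertices = data.frame(name = c("P1", "c1"),
                          type = c("pathway", "target")))
  expect_error(build_ctp_network(ct, bad), "conflicting types")
})

test_that("component-target-pathway union equals brute-force counts", {
  ptab <- suppressMessages(read_pathway_table(extdata("kegg_pathways.tsv")))
  tp <- build_tp_network(ptab)
  targets <- igraph::V(tp$network)$name[
    igraph::V(tp$network)$type == "target"]
  set.seed(14)
  assoc <- data.frame(
    component_id = sample(paste0("HR0", 1:3), 18, replace = TRUE),
    target = sample(targets, 18, replace = TRUE),
    source = "identified", score = NA_real_)
  ct <- build_ct_network(assoc)
  ctp <- build_ctp_network(ct$network, tp$network)
  ct_edges <- unique(assoc[1:2])
  expect_equal(ctp$summary$n_edges, nrow(ct_edges) + 71L)
  expect_equal(
    ctp$summary$n_nodes,
    3L + 10L + length(union(unique(ct_edges$target), targets)))
})

test_that("exports round-trip nodes, edges and type attributes", {
  ptab <- suppressMessages(read_pathway_table(extdata("kegg_pathways.tsv")))
  tp <- build_tp_network(ptab)$network
  dir <- withr::local_tempdir()
  # GraphML keeps the type attribute
  gml <- file.path(dir, "tp.graphml")
  export_network(tp, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(tp)$name)
  expect_equal(
    stats::setNames(igraph::V(back)$type, igraph::V(back)$name)[
      igraph::V(tp)$name],
    stats::setNames(igraph::V(tp)$type, igraph::V(tp)$name))
  expect_equal(igraph::ecount(back), igraph::ecount(tp))
  # SIF: K3 gives three interaction lines
  sif <- file.path(dir, "k3.sif")
  export_network(named_clique(3, "S"), sif, "sif")
  expect_length(readLines(sif), 3L)
  sif_back <- import_network(sif, "sif")
  expect_equal(igraph::ecount(sif_back), 3L)
  # TSV pair on a random graph: edge sets equal by node ids
  g <- random_named_gnp(100, 0.05, seed = 31)
  igraph::V(g)$type <- "protein"
  tsv <- file.path(dir, "g.tsv")
  export_network(g, tsv, "tsv")
  g_back <- import_network(tsv, "tsv")
  key <- function(x) {
    el <- igraph::as_edgelist(x)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(key(g_back), key(g))
  expect_setequal(igraph::V(g_back)$name, igraph::V(g)$name)
  expect_error(export_network(g, file.path(dir, "x"), "xml"))
})
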