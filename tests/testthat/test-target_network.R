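toy_assoc <- function() {
  data.frame(
    component_id = c("C1", "C1", "C2", "C2", "C3", "C3"),
    target = c("T1", "T2", "T3", "T4", "T5", "T6"),
    source = c("identified", "hitpick", "hitpick", "sea", "sea", "identified"),
    score = c(NA, 0.6, 0.4, 0.6, 0.4, NA),
    stringsAsFactors = FALSE
  )
}

test_that("prediction filtering applies per-source inclusive thresholds", {
  kept <- filter_predictions(toy_assoc())
  expect_equal(nrow(kept), 4L)
  expect_setequal(kept$target, c("T1", "T2", "T4", "T6"))
  # boundary forced by >=
  b <- data.frame(component_id = "C", target = c("A", "B"),
                  source = "hitpick", score = c(0.50, 0.49))
  expect_equal(filter_predictions(b)$target, "A")
  # identified rows never need a score
  ident <- data.frame(component_id = "C", target = "A",
                      source = "identified", score = NA_real_)
  expect_equal(nrow(filter_predictions(ident)), 1L)
  # missing predicted scores: drop+warn / keep / error
  nos <- data.frame(component_id = "C", target = "A", source = "sea",
                    score = NA_real_)
  expect_warning(out <- filter_predictions(nos), "lack a score")
  expect_equal(nrow(out), 0L)
  expect_equal(nrow(filter_predictions(nos, missing_score = "keep")), 1L)
  expect_error(filter_predictions(nos, missing_score = "error"))
})

test_that("dedup_union collapses multi-source pairs to set semantics", {
  a <- data.frame(component_id = c("c1", "c1", "c2"),
                  target = c("T1", "T1", "T1"),
                  source = c("identified", "sea", "identified"))
  dd <- dedup_union(a)
  expect_equal(nrow(dd$edges), 2L)
  expect_equal(dd$targets, "T1")
  empty <- dedup_union(a[0, ])
  expect_equal(nrow(empty$edges), 0L)
  expect_length(empty$targets, 0L)
})

test_that("dedup_union matches brute-force sets, idempotent, order-invariant", {
  set.seed(5)
  rows <- data.frame(
    component_id = sample(paste0("C", 1:4), 30, replace = TRUE),
    target = sample(paste0("T", 1:8), 30, replace = TRUE),
    source = sample(c("identified", "sea"), 30, replace = TRUE),
    stringsAsFactors = FALSE
  )
  dd <- dedup_union(rows)
  # brute-force oracle over the row list
  keys <- unique(paste(rows$component_id, rows$target))
  expect_equal(nrow(dd$edges), length(keys))
  expect_setequal(paste(dd$edges$component_id, dd$edges$target), keys)
  expect_setequal(dd$targets, unique(rows$target))
  # idempotence and permutation invariance
  again <- dedup_union(cbind(dd$edges, source = "identified"))
  expect_equal(again$edges, dd$edges)
  perm <- dedup_union(rows[sample(nrow(rows)), ])
  expect_equal(perm, dd)
})

test_that("C-T statistics reproduce the published ratios and simple cases", {
  s <- ct_stats(11, 267, 509)
  expect_equal(round(s$targets_per_component, 1), 24.3)
  expect_equal(round(s$mean_component_degree_per_target, 1), 1.9)
  s2 <- ct_stats(1, 1, 1)
  expect_equal(s2$targets_per_component, 1)
  expect_equal(s2$mean_component_degree_per_target, 1)
  s3 <- ct_stats(3, 12, 20)
  expect_equal(s3$targets_per_component, 4)
  expect_equal(s3$mean_component_degree_per_target, 20 / 12)
  expect_error(ct_stats(0, 10, 5), "positive")
})

test_that("bipartite C-T network degrees sum to the edge count on both sides", {
  assoc <- gen_associations(paste0("HR", 1:5), n_targets = 30, seed = 3)
  ct <- build_ct_network(assoc)
  g <- ct$network
  type <- igraph::V(g)$type
  d <- igraph::degree(g)
  expect_equal(sum(d[type == "component"]), ct$stats$n_edges)
  expect_equal(sum(d[type == "target"]), ct$stats$n_edges)
  expect_equal(igraph::ecount(g), ct$stats$n_edges)
  expect_true(igraph::bipartite_mapping(g)$res)
})

test_that("association reader normalizes symbols and validates scores", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("component_id\ttarget\tsource\tscore",
               "C1\t maoa \tIdentified\t",
               "C1\tGrin2b\tSEA\t0.8"), path)
  df <- read_associations(path)
  expect_equal(df$target, c("MAOA", "GRIN2B"))
  expect_equal(df$source, c("identified", "sea"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("component_id\ttarget\tsource\tscore", "C1\tA\tsea\t1.4"), bad)
  expect_error(read_associations(bad), "\\[0, 1\\]")
})
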