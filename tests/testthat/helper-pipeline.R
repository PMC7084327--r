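# Builds a coherent set of pipeline inputs in `dir`: the shipped component
# table plus synthetic associations, PPI, disease list and GMT that share
# one target namespace (TG...).
make_pipeline_inputs <- function(dir, seed = 11) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp_csv <- extdata("hr_components.csv")
  wl_txt <- extdata("hr_whitelist.txt")
  hr_ids <- sprintf("HR%02d", 1:11)

  pg <- gen_planted_graph(60, 0.05, c(6, 5), seed = seed)
  old <- igraph::V(pg$graph)$name
  map <- stats::setNames(sprintf("TG%03d", seq_along(old)), old)
  ppi <- data.frame(node1 = map[pg$edges$node1], node2 = map[pg$edges$node2],
                    combined_score = 900, stringsAsFactors = FALSE)
  ppi_tsv <- file.path(dir, "ppi.tsv")
  utils::write.table(ppi, ppi_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  assoc <- gen_associations(hr_ids, n_targets = length(old),
                            mean_targets = 12, seed = seed + 1)
  assoc_tsv <- file.path(dir, "assoc.tsv")
  utils::write.table(assoc, assoc_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dt_txt <- file.path(dir, "disease_targets.txt")
  writeLines(unname(map), dt_txt)

  set.seed(seed + 2)
  pool <- unname(map)
  sets <- lapply(1:20, function(i) sample(pool, sample(8:15, 1)))
  names(sets) <- sprintf("PW%03d", 1:20)
  gmt <- file.path(dir, "sets.gmt")
  write_gmt(gene_set_collection(sets, background = pool), gmt)

  list(inputs = list(components = comp_csv, whitelist = wl_txt,
                     associations = assoc_tsv, disease_targets = dt_txt,
                     ppi_edges = ppi_tsv, genesets = gmt))
}
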