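#' Default pipeline parameters
#'
#' The screening and network thresholds the pipeline runs with unless a
#' config overrides them: OB >= 30, Caco-2 > -0.4, DL >= 0.18, GI High,
#' Lipinski <= 1 violation, prediction cutoffs precision >= 0.5 and
#' MaxTc >= 0.5, PPI confidence >= 0.7, MCODE k-core 5 for the disease
#' network and 2 for the herb-disease intersection network, enrichment
#' raw-p cutoff 0.05 with the top 10 sets per category.
#'
#' @return named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(ob = 30, caco2 = -0.4, dl = 0.18, gi = "High",
       max_lipinski_violations = 1,
       min_precision = 0.5, min_maxtc = 0.5,
       ppi_confidence = 0.7,
       k_core_disease = 5, k_core_intersection = 2,
       vwp = 0.2, haircut = TRUE,
       p_cutoff = 0.05, top_n = 10, m_total = NULL,
       seed = 1)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  list(inputs = config$inputs %||% list(), params = params,
       out_dir = config$out_dir %||% NULL)
}

require_input <- function(inputs, field, stage) {
  path <- inputs[[field]]
  if (is.null(path) || !file.exists(path)) {
    stop_domain("stage '", stage, "': missing input '", field, "'",
                if (!is.null(path)) paste0(" (", path, ")"))
  }
  path
}

#' Run the full network-pharmacology pipeline
#'
#' Chains the six analysis stages — ADME screening, component-target
#' network, disease PPI with dense-module clustering, herb-disease
#' target intersection with its own clustering, pathway
#' over-representation, and component-target-pathway assembly — from a
#' config (YAML/JSON path or list) into a deterministic directory layout
#' (`report/`, `networks/`, `clusters/`, `enrichment/`, `manifest.json`).
#'
#' Config `inputs`: `components` (CSV), `whitelist` (one id per line,
#' optional), `associations` (TSV), `disease_targets` (one symbol per
#' line), `ppi_edges` (STRING-dialect TSV), `genesets` (GMT). Config
#' `params` override [default_pipeline_params()].
#'
#' @param config path to a YAML/JSON config, or an equivalent list.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  p <- cfg$params
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop_domain("no output directory configured")
  for (d in c("report", "networks", "clusters", "enrichment")) {
    dir.create(file.path(out_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  }
  set.seed(p$seed)
  stages <- character()
  log_stage <- function(name) {
    message("[netpharm] stage: ", name)
    stages <<- c(stages, name)
  }

  # 1. ADME screening
  log_stage("screen")
  comp <- read_components(require_input(cfg$inputs, "components", "screen"))
  whitelist <- if (!is.null(cfg$inputs$whitelist)) {
    readLines(cfg$inputs$whitelist)
  } else character()
  thr <- adme_thresholds(p$ob, p$caco2, p$dl, p$gi,
                         p$max_lipinski_violations)
  report <- adme_screen(comp, thr, whitelist = trimws(whitelist))
  write_screen_report(report, file.path(out_dir, "report"))
  retained <- report$id[report$retained]

  # 2. component-target network
  log_stage("ct_network")
  assoc <- read_associations(
    require_input(cfg$inputs, "associations", "ct_network"))
  assoc <- assoc[assoc$component_id %in% retained, , drop = FALSE]
  assoc <- suppressWarnings(
    filter_predictions(assoc, p$min_precision, p$min_maxtc))
  ct <- build_ct_network(assoc)
  export_network(ct$network, file.path(out_dir, "networks", "ct.tsv"),
                 format = "tsv")
  jsonlite::write_json(unclass(ct$stats),
                       file.path(out_dir, "report", "ct_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  herb_targets <- igraph::V(ct$network)$name[
    igraph::V(ct$network)$type == "target"]

  # 3. disease PPI network + clustering
  log_stage("disease_ppi")
  ppi <- load_ppi(require_input(cfg$inputs, "ppi_edges", "disease_ppi"),
                  min_confidence = p$ppi_confidence)
  hubs <- degree_ranking(ppi, k = 10)
  utils::write.table(hubs, file.path(out_dir, "report", "dd_hubs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dd_clusters <- find_clusters(
    ppi, mcode_params(k_core = p$k_core_disease, vwp = p$vwp,
                      haircut = p$haircut))
  utils::write.table(as.data.frame(dd_clusters),
                     file.path(out_dir, "clusters", "dd_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 4. herb-disease intersection
  log_stage("intersect")
  disease_targets <- readLines(
    require_input(cfg$inputs, "disease_targets", "intersect"))
  inter <- intersect_subnetwork(herb_targets, disease_targets, ppi)
  export_network(inter$network,
                 file.path(out_dir, "networks", "hrdd.tsv"), format = "tsv")
  hrdd_clusters <- find_clusters(
    inter$network,
    mcode_params(k_core = p$k_core_intersection, vwp = p$vwp,
                 haircut = p$haircut))
  utils::write.table(as.data.frame(hrdd_clusters),
                     file.path(out_dir, "clusters", "hrdd_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  overlap_genes <- intersect(normalize_symbols(herb_targets),
                             normalize_symbols(disease_targets))

  # 5. enrichment
  log_stage("enrich")
  collection <- read_gmt(require_input(cfg$inputs, "genesets", "enrich"))
  enr <- suppressWarnings(
    enrich(overlap_genes, collection, p_cutoff = p$p_cutoff,
           top_n = p$top_n, m_total = p$m_total))
  utils::write.table(enr, file.path(out_dir, "enrichment", "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # 6. component-target-pathway assembly
  log_stage("ctp")
  if (nrow(enr)) {
    ptab <- data.frame(ID = enr$set_id, stringsAsFactors = FALSE)
    ptab$genes <- strsplit(enr$hit_genes, "/", fixed = TRUE)
    ptab <- ptab[lengths(ptab$genes) > 0, , drop = FALSE]
    tp <- build_tp_network(ptab)
    ctp <- build_ctp_network(ct$network, tp$network)
    export_network(ctp$network,
                   file.path(out_dir, "networks", "ctp.graphml"),
                   format = "graphml")
    ctp_summary <- ctp$summary
  } else {
    ctp_summary <- list(note = "no enriched sets; CTP layer skipped")
  }

  manifest <- list(
    package = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = p$seed,
    parameters = p[setdiff(names(p), "seed")],
    inputs = lapply(cfg$inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    stages = stages,
    results = list(
      n_retained_components = length(retained),
      ct = unclass(ct$stats),
      ppi = list(nodes = igraph::vcount(ppi), edges = igraph::ecount(ppi)),
      venn = as.list(inter$venn),
      n_dd_clusters = length(dd_clusters),
      n_hrdd_clusters = length(hrdd_clusters),
      n_enriched_sets = nrow(enr),
      ctp = ctp_summary
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
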