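# Seeded generators for every pipeline input, with known ground truth.
# All generators are pure functions of (parameters, seed): they use R's
# default Mersenne-Twister stream, seeded locally and restored on exit,
# so outputs are identical across runs and platforms.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a component property table with known screening labels
#'
#' Draws descriptors uniformly from ranges spanning a realistic herbal
#' component table (MW 150-500 Da, AlogP -1 to 7, OB 10-90 percent,
#' Caco-2 -1.5 to 1, DL 0-0.8, GI in High/Low). A `pass_fraction` subset
#' is constructed to satisfy all five strict ADME criteria; each
#' remaining row has one randomly chosen criterion forced into its
#' failing range (for the Lipinski case, two rule violations), so the
#' true strict-pass labels are known exactly.
#'
#' @param n number of components.
#' @param pass_fraction fraction (rounded to a count) of strict passes.
#' @param seed integer seed.
#' @return list with `components` (data.frame in [read_components()]
#'   layout) and logical `labels` named by component id.
#' @export
gen_components <- function(n, pass_fraction = 0.5, seed = 1) {
  stopifnot(n >= 1, pass_fraction >= 0, pass_fraction <= 1)
  with_local_seed(seed, {
    n_pass <- round(pass_fraction * n)
    label <- sample(rep(c(TRUE, FALSE), c(n_pass, n - n_pass)))
    id <- sprintf("SC%03d", seq_len(n))
    df <- data.frame(
      id = id, name = paste0("synthetic-", id),
      MW = round(stats::runif(n, 150, 500), 2),
      AlogP = round(stats::runif(n, -1, 4.8), 2),
      nHdon = sample(0:5, n, replace = TRUE),
      nHacc = sample(0:10, n, replace = TRUE),
      TPSA = round(stats::runif(n, 20, 160), 2),
      RBN = sample(0:10, n, replace = TRUE),
      OB = round(stats::runif(n, 30, 90), 2),
      Caco2 = round(stats::runif(n, -0.35, 1), 2),
      DL = round(stats::runif(n, 0.18, 0.8), 2),
      GI = "High",
      stringsAsFactors = FALSE
    )
    breakable <- c("OB", "Caco2", "DL", "GI", "Lipinski")
    for (i in which(!label)) {
      switch(sample(breakable, 1),
        OB = df$OB[i] <- round(stats::runif(1, 10, 29.5), 2),
        Caco2 = df$Caco2[i] <- round(stats::runif(1, -1.5, -0.45), 2),
        DL = df$DL[i] <- round(stats::runif(1, 0, 0.17), 2),
        GI = df$GI[i] <- "Low",
        Lipinski = {
          df$MW[i] <- round(stats::runif(1, 505, 700), 2)
          df$AlogP[i] <- round(stats::runif(1, 5.2, 7), 2)
        }
      )
    }
    list(components = df, labels = stats::setNames(label, id))
  })
}

#' Generate a sparse background graph with planted cliques
#'
#' Erdos-Renyi background `G(n_background, p_background)` plus
#' vertex-disjoint cliques on fresh nodes — the unambiguous ground truth
#' for dense-module detection (a planted clique has density 1, the
#' maximum of the density x size score).
#'
#' @param n_background number of background nodes.
#' @param p_background background edge probability.
#' @param module_sizes integer vector of planted clique sizes (each >= 3).
#' @param seed integer seed.
#' @return list with `edges` (data.frame node1, node2, combined_score = 1,
#'   parseable by [load_ppi()]), `modules` (list of member vectors) and
#'   `graph` (igraph).
#' @export
gen_planted_graph <- function(n_background, p_background, module_sizes,
                              seed = 1) {
  stopifnot(n_background >= 2, p_background >= 0, p_background <= 1,
            all(module_sizes >= 3))
  with_local_seed(seed, {
    bg <- sprintf("B%03d", seq_len(n_background))
    pairs <- utils::combn(bg, 2)
    keep <- stats::runif(ncol(pairs)) < p_background
    edges <- data.frame(node1 = pairs[1, keep], node2 = pairs[2, keep],
                        stringsAsFactors = FALSE)
    modules <- lapply(seq_along(module_sizes), function(m) {
      sprintf("M%d_%02d", m, seq_len(module_sizes[m]))
    })
    for (mod in modules) {
      mp <- utils::combn(mod, 2)
      edges <- rbind(edges, data.frame(node1 = mp[1, ], node2 = mp[2, ],
                                       stringsAsFactors = FALSE))
    }
    edges$combined_score <- 1
    g <- igraph::graph_from_data_frame(
      edges[1:2], directed = FALSE,
      vertices = data.frame(name = c(bg, unlist(modules)),
                            stringsAsFactors = FALSE))
    list(edges = edges, modules = modules, graph = g)
  })
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Samples a background universe, a query gene set, and `n_sets` gene
#' sets of which one (the planted set) shares exactly `planted_overlap`
#' genes with the query while decoys are drawn uniformly from the
#' background (null overlap).
#'
#' @param n_sets number of gene sets.
#' @param set_size_range length-2 integer range of set sizes.
#' @param background_size universe size.
#' @param query_size query size.
#' @param planted_overlap genes shared between query and the planted set;
#'   must not exceed `min(query_size, max(set_size_range))`.
#' @param seed integer seed.
#' @return list with `collection` ([gene_set_collection()] whose
#'   background is the full universe), `query` and `planted_id`.
#' @export
gen_genesets <- function(n_sets, set_size_range = c(20, 40),
                         background_size = 1000, query_size = 50,
                         planted_overlap = 15, seed = 1) {
  if (planted_overlap > min(query_size, max(set_size_range))) {
    stop_domain("planted_overlap exceeds query or maximum set size")
  }
  stopifnot(n_sets >= 1, background_size >= query_size)
  with_local_seed(seed, {
    bg <- sprintf("G%05d", seq_len(background_size))
    query <- sort(sample(bg, query_size))
    ids <- sprintf("GS%03d", seq_len(n_sets))
    planted_id <- sample(ids, 1)
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sizes[ids == planted_id] <- max(sizes[ids == planted_id],
                                    planted_overlap)
    sets <- lapply(seq_len(n_sets), function(i) {
      if (ids[i] == planted_id) {
        sort(c(sample(query, planted_overlap),
               sample(setdiff(bg, query), sizes[i] - planted_overlap)))
      } else {
        sort(sample(bg, sizes[i]))
      }
    })
    names(sets) <- ids
    list(collection = gene_set_collection(sets, background = bg),
         query = query, planted_id = planted_id)
  })
}

#' Generate a component-target association table
#'
#' Random associations over a synthetic target pool, mixing curated
#' (`identified`) rows with scored `hitpick` and `sea` predictions, and
#' re-reporting a fraction of pairs under a second source so that
#' cross-source deduplication is exercised.
#'
#' @param component_ids character vector of component ids.
#' @param n_targets size of the target symbol pool.
#' @param mean_targets mean targets drawn per component.
#' @param dup_fraction fraction of pairs duplicated under another source.
#' @param seed integer seed.
#' @return data.frame in the [read_associations()] layout.
#' @export
gen_associations <- function(component_ids, n_targets = 60,
                             mean_targets = 10, dup_fraction = 0.2,
                             seed = 1) {
  stopifnot(length(component_ids) >= 1, n_targets >= 1)
  with_local_seed(seed, {
    pool <- sprintf("TG%03d", seq_len(n_targets))
    rows <- do.call(rbind, lapply(component_ids, function(cid) {
      nt <- max(1, stats::rpois(1, mean_targets))
      tg <- sample(pool, min(nt, n_targets))
      src <- sample(c("identified", "hitpick", "sea"), length(tg),
                    replace = TRUE)
      data.frame(component_id = cid, target = tg, source = src,
                 score = ifelse(src == "identified", NA_real_,
                                round(stats::runif(length(tg)), 3)),
                 stringsAsFactors = FALSE)
    }))
    ndup <- round(dup_fraction * nrow(rows))
    if (ndup > 0) {
      dup <- rows[sample(nrow(rows), ndup), , drop = FALSE]
      other <- c(identified = "sea", hitpick = "identified",
                 sea = "identified")
      dup$source <- unname(other[dup$source])
      dup$score <- ifelse(dup$source == "identified", NA_real_,
                          round(stats::runif(nrow(dup)), 3))
      rows <- rbind(rows, dup)
    }
    rownames(rows) <- NULL
    rows
  })
}
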