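#' Simulation configuration
#'
#' Parameters of the seeded generators that emulate every pipeline input
#' with planted ground truth. Defaults describe a desk-scale study: a few
#' dozen compounds whose OB/DL values straddle the activity thresholds,
#' a scale-free interactome of a few hundred genes grown by preferential
#' attachment, a handful of planted hub genes wired with extra
#' degree-biased edges, one planted near-clique module of 6 genes at
#' density 14/15 (the density whose 6-node cluster score is 5.60), and an
#' annotation collection with one planted enriched term.
#'
#' @param seed Integer master seed; every sub-generator derives its own
#'   stream from it, so partial re-runs are stable.
#' @param n_compounds Number of simulated compounds.
#' @param ob_mean,ob_sd Oral bioavailability distribution (percent);
#'   normal truncated at 0, centred near the 30 percent threshold so the
#'   activity screen has both outcomes.
#' @param dl_alpha,dl_beta Beta-distribution shape parameters for
#'   drug-likeness in \[0, 1\].
#' @param n_genes Genes in the interactome backbone.
#' @param attach_m Edges added per node during preferential attachment.
#' @param n_hubs Number of planted hub genes.
#' @param hub_extra_degree Extra edges wired onto each hub; partners are
#'   drawn half uniformly and half with probability proportional to
#'   current degree, so hubs embed in the connected part of the network
#'   (acquiring the triangles that real hub proteins have) without
#'   welding the top of the degree distribution into a single dense
#'   cluster.
#' @param module_size Nodes in the planted dense module (>= 3).
#' @param module_density Edge density of the planted module, in (0, 1].
#' @param n_terms Terms in the simulated annotation collection.
#' @param planted_term_size Size of the planted enriched term.
#' @param n_disease Size of the simulated disease gene list.
#' @param disease_overlap Fraction of the disease list drawn from the
#'   compound-target pool (the "shared target" signal).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_compounds = 30L,
                              ob_mean = 35, ob_sd = 12,
                              dl_alpha = 2, dl_beta = 5,
                              n_genes = 250L,
                              attach_m = 3L,
                              n_hubs = 5L,
                              hub_extra_degree = 30L,
                              module_size = 6L,
                              module_density = 14 / 15,
                              n_terms = 50L,
                              planted_term_size = 15L,
                              n_disease = 60L,
                              disease_overlap = 0.3) {
  cfg <- list(seed = as.integer(seed),
              n_compounds = as.integer(n_compounds),
              ob_mean = ob_mean, ob_sd = ob_sd,
              dl_alpha = dl_alpha, dl_beta = dl_beta,
              n_genes = as.integer(n_genes),
              attach_m = as.integer(attach_m),
              n_hubs = as.integer(n_hubs),
              hub_extra_degree = as.integer(hub_extra_degree),
              module_size = as.integer(module_size),
              module_density = module_density,
              n_terms = as.integer(n_terms),
              planted_term_size = as.integer(planted_term_size),
              n_disease = as.integer(n_disease),
              disease_overlap = disease_overlap)
  stopifnot(cfg$n_compounds >= 0, cfg$n_genes >= 10,
            cfg$attach_m >= 1, cfg$n_hubs >= 0,
            cfg$hub_extra_degree >= 0,
            cfg$module_size >= 3,
            cfg$module_density > 0, cfg$module_density <= 1,
            cfg$n_terms >= 1, cfg$planted_term_size >= 1,
            cfg$n_disease >= 1,
            cfg$disease_overlap > 0, cfg$disease_overlap <= 1,
            cfg$ob_sd > 0, cfg$dl_alpha > 0, cfg$dl_beta > 0)
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic per-stream seed derived from the master seed; keeps every
# sub-generator independent of how many draws the previous one consumed
stream_seed <- function(cfg, stream) {
  (cfg$seed %% 1000003L) * 1009L + stream * 101L
}

#' Simulate a compound table with known active set
#'
#' OB is drawn from a normal distribution truncated at zero and DL from a
#' beta distribution; both straddle the default activity thresholds, so a
#' screen on the output exercises all four outcomes. The ground-truth
#' active set is computed analytically from the drawn values.
#'
#' @param cfg A [simulation_config()].
#' @param thresholds The [adme_thresholds()] defining ground truth.
#' @return List with `records` (compound data.frame) and `truth`
#'   (character vector of mol_ids satisfying the thresholds).
#' @export
simulate_compounds <- function(cfg, thresholds = adme_thresholds()) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_compounds
  if (n == 0) {
    rec <- data.frame(mol_id = character(0), name = character(0),
                      ob = numeric(0), dl = numeric(0),
                      is_active = logical(0), stringsAsFactors = FALSE)
    return(list(records = rec, truth = character(0)))
  }
  set.seed(stream_seed(cfg, 1L))
  ob <- pmax(stats::rnorm(n, cfg$ob_mean, cfg$ob_sd), 0)
  dl <- stats::rbeta(n, cfg$dl_alpha, cfg$dl_beta)
  records <- data.frame(
    mol_id = sprintf("SIM%05d", seq_len(n)),
    name = sprintf("compound_%d", seq_len(n)),
    ob = ob, dl = dl, is_active = FALSE,
    stringsAsFactors = FALSE
  )
  cmp <- if (thresholds$inclusive) `>=` else `>`
  truth <- records$mol_id[cmp(ob, thresholds$ob_min) &
                            cmp(dl, thresholds$dl_min)]
  list(records = records, truth = truth)
}

#' Simulate a scale-free interactome with planted hubs and module
#'
#' The backbone is grown by preferential attachment (`attach_m` edges per
#' incoming node), giving the heavy-tailed degree distribution of real
#' protein-interaction networks. `n_hubs` backbone genes then receive
#' `hub_extra_degree` additional edges each, with partners drawn with
#' probability proportional to current degree; `module_size` fresh genes
#' are wired among themselves to `module_density` and each attached to
#' the backbone by at most one edge.
#'
#' @param cfg A [simulation_config()].
#' @return List with `graph` (an `interaction_graph`), `hubs` and
#'   `module_nodes` (character vectors of planted ids).
#' @export
simulate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_pairs <- choose(cfg$module_size, 2)
  n_mod_edges <- round(cfg$module_density * n_pairs)
  if (n_mod_edges < cfg$module_size - 1) {
    stop("module_density too low for module_size: planted module could ",
         "not even be connected", call. = FALSE)
  }
  set.seed(stream_seed(cfg, 2L))
  base_names <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  ig <- igraph::sample_pa(cfg$n_genes, m = cfg$attach_m, directed = FALSE)
  igraph::V(ig)$name <- base_names
  edges <- igraph::as_edgelist(ig, names = TRUE)
  edge_seen <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(edges))) {
    key <- paste(sort(edges[r, ]), collapse = "|")
    assign(key, TRUE, envir = edge_seen)
  }
  deg <- stats::setNames(as.numeric(igraph::degree(ig)), base_names)
  # plant hubs: extra edges with degree-proportional partner choice
  hubs <- sort(sample(base_names, cfg$n_hubs))
  new_edges <- list()
  for (h in hubs) {
    added <- 0L
    guard <- 0L
    while (added < cfg$hub_extra_degree && guard < 50L * cfg$hub_extra_degree) {
      guard <- guard + 1L
      # partners: half uniform, half degree-proportional, so hubs touch
      # both the connected core (giving them triangles) and the periphery
      # (without welding the core into a super-dense cluster)
      cand <- if (stats::runif(1) < 0.5) {
        sample(base_names, 1L, prob = deg + 1)
      } else {
        sample(base_names, 1L)
      }
      if (cand == h) next
      key <- paste(sort(c(h, cand)), collapse = "|")
      if (exists(key, envir = edge_seen, inherits = FALSE)) next
      assign(key, TRUE, envir = edge_seen)
      new_edges[[length(new_edges) + 1L]] <- c(h, cand)
      deg[h] <- deg[h] + 1
      deg[cand] <- deg[cand] + 1
      added <- added + 1L
    }
  }
  # plant the dense module on fresh gene ids
  module_nodes <- sprintf("GENE%04d", cfg$n_genes + seq_len(cfg$module_size))
  pairs <- t(utils::combn(module_nodes, 2))
  keep <- sample(nrow(pairs), n_mod_edges)
  mod_edges <- pairs[keep, , drop = FALSE]
  anchor <- lapply(module_nodes, function(mn) {
    if (stats::runif(1) < 0.5) c(mn, sample(base_names, 1L)) else NULL
  })
  anchor <- do.call(rbind, anchor[!vapply(anchor, is.null, TRUE)])
  all_edges <- rbind(edges,
                     do.call(rbind, new_edges),
                     mod_edges,
                     anchor)
  g <- interaction_graph(nodes = c(base_names, module_nodes),
                         edges = all_edges)
  list(graph = g, hubs = hubs, module_nodes = module_nodes)
}

#' Simulate an annotation collection with one planted enriched term
#'
#' The planted term contains all of `key_genes` padded with random genes
#' up to `planted_term_size`; the other `n_terms - 1` terms are drawn
#' uniformly from the universe with sizes between 10 and 40 genes.
#'
#' @param cfg A [simulation_config()].
#' @param key_genes Genes the planted term must contain.
#' @param universe Character vector: the gene namespace to draw from.
#' @return List with `annotations` (an `annotation_collection` whose
#'   `universe` is set to `universe`) and `planted_term` (the term id).
#' @export
simulate_annotations <- function(cfg, key_genes, universe) {
  stopifnot(inherits(cfg, "simulation_config"))
  key_genes <- unique(as.character(key_genes))
  universe <- unique(as.character(universe))
  if (!all(key_genes %in% universe)) {
    stop("key_genes must lie inside the universe", call. = FALSE)
  }
  if (cfg$planted_term_size < length(key_genes)) {
    stop("planted_term_size smaller than |key_genes|", call. = FALSE)
  }
  set.seed(stream_seed(cfg, 3L))
  pad_pool <- setdiff(universe, key_genes)
  n_pad <- min(cfg$planted_term_size - length(key_genes), length(pad_pool))
  planted_genes <- sort(c(key_genes, sample(pad_pool, n_pad)))
  ids <- sprintf("TERM%04d", seq_len(cfg$n_terms))
  planted_id <- ids[sample(cfg$n_terms, 1L)]
  terms <- lapply(ids, function(id) {
    if (id == planted_id) return(planted_genes)
    size <- sample(10:40, 1L)
    sort(sample(universe, min(size, length(universe))))
  })
  names(terms) <- ids
  descriptions <- stats::setNames(
    ifelse(ids == planted_id, "planted synthetic term",
           "random synthetic term"),
    ids
  )
  annotations <- structure(
    list(terms = terms, descriptions = descriptions, universe = universe),
    class = "annotation_collection"
  )
  list(annotations = annotations, planted_term = planted_id)
}

#' Simulate a complete study bundle
#'
#' Generates every input of the pipeline with a single master seed and,
#' optionally, writes them to disk in the formats the readers consume:
#' `compounds.tsv`, `assoc.tsv`, `disease_genes.txt`, `ppi.tsv`,
#' `terms.gmt` and `truth.json`. Compound-target counts follow a
#' truncated Pareto law and targets are drawn with degree-proportional
#' probability (well-connected proteins are the usually reported
#' targets); the disease gene list contains the planted module and hub
#' genes plus a `disease_overlap` share of compound targets.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return List with the in-memory objects (`compounds`, `associations`,
#'   `disease_genes`, `interactome`, `annotations`) and `truth` (planted
#'   active compounds, hubs, module nodes and enriched term id); when
#'   `dir` is given, also `paths`.
#' @export
simulate_study <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  comp <- simulate_compounds(cfg)
  net <- simulate_interactome(cfg)
  genes <- net$graph$nodes
  deg <- graph_degree(net$graph)

  set.seed(stream_seed(cfg, 4L))
  active_ids <- comp$truth
  assoc <- NULL
  if (length(active_ids) > 0) {
    # truncated Pareto target counts: few promiscuous, many specific
    k <- pmin(40L, ceiling(stats::runif(length(active_ids))^(-1 / 1.5)))
    assoc <- do.call(rbind, lapply(seq_along(active_ids), function(i) {
      tg <- sample(genes, min(k[i], length(genes)), prob = deg + 1)
      cbind(active_ids[i], tg)
    }))
  }
  associations <- data.frame(
    mol_id = if (is.null(assoc)) character(0) else assoc[, 1],
    gene = if (is.null(assoc)) character(0) else assoc[, 2],
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  compound_targets <- unique(associations$gene)

  # disease list: planted structure + overlap with compound targets + noise
  n_from_ct <- round(cfg$disease_overlap * cfg$n_disease)
  from_ct <- sample(compound_targets,
                    min(n_from_ct, length(compound_targets)))
  core <- unique(c(net$module_nodes, net$hubs, from_ct))
  pool <- setdiff(genes, core)
  n_rest <- max(cfg$n_disease - length(core), 0L)
  disease_genes <- sort(unique(c(core, sample(pool, min(n_rest,
                                                        length(pool))))))

  key_genes <- unique(c(net$hubs, net$module_nodes))
  ann <- simulate_annotations(cfg, key_genes, universe = genes)

  truth <- list(active_compounds = comp$truth,
                hubs = net$hubs,
                module_nodes = net$module_nodes,
                planted_term = ann$planted_term)
  out <- list(compounds = comp$records,
              associations = associations,
              disease_genes = disease_genes,
              interactome = net$graph,
              annotations = ann$annotations,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      compounds = file.path(dir, "compounds.tsv"),
      associations = file.path(dir, "assoc.tsv"),
      disease_genes = file.path(dir, "disease_genes.txt"),
      background_ppi = file.path(dir, "ppi.tsv"),
      annotations = file.path(dir, "terms.gmt"),
      truth = file.path(dir, "truth.json")
    )
    utils::write.table(
      comp$records[c("mol_id", "name", "ob", "dl")],
      paths$compounds, sep = "\t", quote = FALSE, row.names = FALSE
    )
    writeLines(paste(associations$mol_id, associations$gene,
                     associations$source, sep = "\t"),
               paths$associations)
    writeLines(paste(disease_genes, "synthetic", sep = "\t"),
               paths$disease_genes)
    write_graph(net$graph, paths$background_ppi, format = "edge-list")
    write_gmt(ann$annotations, paths$annotations)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}
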