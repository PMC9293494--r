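#' Validate a pipeline configuration
#'
#' Checks a YAML configuration file (see [run_pipeline()] for the schema)
#' without running anything: required sections, input paths, threshold
#' ranges, parameter invariants.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  cfg <- load_config(config)
  problems <- character(0)
  say <- function(...) problems <<- c(problems, paste0(...))

  if (is.null(cfg$output_dir)) say("missing output_dir")
  has_sim <- !is.null(cfg$simulation)
  has_inputs <- !is.null(cfg$inputs)
  if (!has_sim && !has_inputs) say("need an `inputs` or `simulation` section")
  if (has_inputs) {
    required <- c("compounds", "associations", "disease_genes",
                  "background_ppi", "gmt_go")
    for (key in required) {
      p <- cfg$inputs[[key]]
      if (is.null(p)) {
        say("inputs: missing ", key)
      } else if (!file.exists(p)) {
        say("inputs: ", key, " file not found: ", p)
      }
    }
    if (!is.null(cfg$inputs$gmt_kegg) && !file.exists(cfg$inputs$gmt_kegg)) {
      say("inputs: gmt_kegg file not found: ", cfg$inputs$gmt_kegg)
    }
  }
  adme <- cfg$adme
  if (!is.null(adme$ob_min) && (!is.numeric(adme$ob_min) || adme$ob_min < 0)) {
    say("adme: ob_min out of range (must be >= 0)")
  }
  if (!is.null(adme$dl_min) &&
      (!is.numeric(adme$dl_min) || adme$dl_min < 0 || adme$dl_min > 1)) {
    say("adme: dl_min out of range (must lie in [0, 1])")
  }
  mc <- cfg$mcode
  if (!is.null(mc$vwp) && (!is.numeric(mc$vwp) || mc$vwp < 0 || mc$vwp >= 1)) {
    say("mcode: vwp out of range (must lie in [0, 1))")
  }
  if (!is.null(mc$min_size) && (!is.numeric(mc$min_size) || mc$min_size < 2)) {
    say("mcode: min_size out of range (must be >= 2)")
  }
  en <- cfg$enrichment
  if (!is.null(en$alpha) &&
      (!is.numeric(en$alpha) || en$alpha <= 0 || en$alpha > 1)) {
    say("enrichment: alpha out of range (must lie in (0, 1])")
  }
  if (has_sim) {
    ok <- tryCatch({
      do.call(simulation_config,
              c(list(seed = cfg$seed %||% 1L),
                cfg$simulation[setdiff(names(cfg$simulation), "seed")]))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) say("simulation: ", conditionMessage(ok))
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a path or a list", call. = FALSE)
  }
}

#' Run the full network-pharmacology pipeline
#'
#' Orchestrates the whole analysis from one configuration: ADME activity
#' filter, compound-target bipartite network, disease PPI subnetwork,
#' merged compound/disease PPI network, six-measure key-target screen,
#' MCODE module detection on the disease PPI, and over-representation
#' analysis of the key targets against one or two GMT collections
#' (conventionally GO terms reported top-10 and pathways top-20).
#'
#' The YAML schema (all thresholds shown at their defaults):
#' ```yaml
#' output_dir: out
#' seed: 42                     # only used by the simulation block
#' inputs:                      # either this section...
#'   compounds: compounds.tsv
#'   associations: assoc.tsv
#'   disease_genes: disease_genes.txt
#'   background_ppi: ppi.tsv
#'   gmt_go: go.gmt
#'   gmt_kegg: kegg.gmt         # optional
#' simulation: {}               # ...or this one (simulation_config fields)
#' adme: {ob_min: 30, dl_min: 0.18, inclusive: true}
#' screen: {strict: true}
#' mcode: {vwp: 0.2, haircut: true, fluff: false, min_size: 3}
#' enrichment: {alpha: 0.05, top_go: 10, top_kegg: 20, ease: false,
#'              adjust: none}
#' ```
#'
#' @param config Path to a YAML configuration (or an equivalent list).
#' @param seed Optional integer overriding the config's `seed`.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, the report list also written to
#'   `output_dir/report.json`. Identical config and seed produce a
#'   byte-identical report.
#' @export
run_pipeline <- function(config, seed = NULL, quiet = FALSE) {
  cfg <- load_config(config)
  problems <- validate_config(cfg)
  if (length(problems) > 0) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  note <- function(...) if (!quiet) message(...)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  seed_used <- cfg$seed %||% NA_integer_

  if (!is.null(cfg$simulation)) {
    note("simulating study inputs (seed ", seed_used, ")")
    sim_cfg <- do.call(
      simulation_config,
      c(list(seed = seed_used %||% 1L),
        cfg$simulation[setdiff(names(cfg$simulation), "seed")])
    )
    sim <- simulate_study(sim_cfg, dir = file.path(out_dir, "simulated"))
    cfg$inputs <- list(compounds = sim$paths$compounds,
                       associations = sim$paths$associations,
                       disease_genes = sim$paths$disease_genes,
                       background_ppi = sim$paths$background_ppi,
                       gmt_go = sim$paths$annotations)
  }

  adme <- cfg$adme
  thresholds <- adme_thresholds(ob_min = adme$ob_min %||% 30,
                                dl_min = adme$dl_min %||% 0.18,
                                inclusive = adme$inclusive %||% TRUE)
  mc <- cfg$mcode
  params <- mcode_params(vwp = mc$vwp %||% 0.2,
                         haircut = mc$haircut %||% TRUE,
                         fluff = mc$fluff %||% FALSE,
                         fluff_density = mc$fluff_density %||% 0.1,
                         min_size = mc$min_size %||% 3L)
  en <- cfg$enrichment
  alpha <- en$alpha %||% 0.05
  top_go <- en$top_go %||% 10L
  top_kegg <- en$top_kegg %||% 20L
  strict <- cfg$screen$strict %||% TRUE

  # --- stage 1: ADME screen -------------------------------------------
  note("stage 1/6: ADME activity screen")
  compounds <- read_compound_table(cfg$inputs$compounds)
  screen <- filter_active_compounds(compounds, thresholds)
  utils::write.table(screen$active, file.path(out_dir,
                                              "active_compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 2: compound-target network -------------------------------
  note("stage 2/6: compound-target network")
  assoc <- read_associations(cfg$inputs$associations)
  ct <- build_compound_target_network(screen$active, assoc)
  write_graph(ct$graph, file.path(out_dir, "compound_target.sif"), "sif")
  compound_targets <- ct$graph$nodes[ct$graph$node_kind == "gene"]

  # --- stage 3: disease PPI + modules ---------------------------------
  note("stage 3/6: disease PPI network and module detection")
  background <- read_edge_list(cfg$inputs$background_ppi)
  disease <- read_gene_list(cfg$inputs$disease_genes, label = "disease")
  disease_ppi <- induced_ppi_subgraph(background, disease$genes,
                                      drop_isolated = TRUE)
  write_graph(disease_ppi$graph, file.path(out_dir, "disease_ppi.sif"),
              "sif")
  modules <- mcode_find_modules(disease_ppi$graph, params)
  write_modules_json(modules, file.path(out_dir, "modules.json"))

  # --- stage 4: merged network ----------------------------------------
  note("stage 4/6: merged compound/disease PPI network")
  merged <- merge_target_networks(compound_targets, disease$genes,
                                  background)
  write_graph(merged$graph, file.path(out_dir, "merged_ppi.sif"), "sif")
  shared <- shared_targets(compound_targets, disease$genes)

  # --- stage 5: centrality screen -------------------------------------
  note("stage 5/6: six-measure centrality screen")
  if (graph_size(merged$graph) > 0) {
    ctab <- centrality_table(merged$graph)
    scr <- screen_key_nodes(ctab, merged$graph, strict = strict)
    tab_out <- ctab
    tab_out$passes_all <- ctab$node %in% scr$key_nodes
    utils::write.table(format(tab_out, digits = 10),
                       file.path(out_dir, "centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(scr$key_nodes, file.path(out_dir, "key_targets.txt"))
    write_graph(scr$central, file.path(out_dir, "central.sif"), "sif")
    key_nodes <- scr$key_nodes
    central_edges <- graph_size(scr$central)
  } else {
    note("  merged network has no edges; skipping the screen")
    writeLines(character(0), file.path(out_dir, "key_targets.txt"))
    key_nodes <- character(0)
    central_edges <- 0L
  }

  # --- stage 6: enrichment --------------------------------------------
  note("stage 6/6: over-representation analysis of key targets")
  enr_counts <- list()
  run_enrichment <- function(gmt_path, top_k, out_name) {
    empty <- data.frame(term_id = character(0), description = character(0),
                        k = integer(0), n = integer(0), K = integer(0),
                        M = integer(0), enrichment_ratio = numeric(0),
                        p_raw = numeric(0), p_adj = numeric(0))
    res <- if (length(key_nodes) == 0) empty else {
      tryCatch(
        enrich_gene_set(key_nodes, read_gmt(gmt_path),
                        ease = en$ease %||% FALSE,
                        adjust = en$adjust %||% "none"),
        error = function(e) empty
      )
    }
    top <- select_top_terms(res, alpha = alpha, top_k = top_k)
    utils::write.table(top, file.path(out_dir, out_name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(n_tested = nrow(res), n_significant = sum(res$p_raw < alpha),
         n_reported = nrow(top))
  }
  enr_counts$go <- run_enrichment(cfg$inputs$gmt_go, top_go,
                                  "enrichment_go.tsv")
  if (!is.null(cfg$inputs$gmt_kegg)) {
    enr_counts$kegg <- run_enrichment(cfg$inputs$gmt_kegg, top_kegg,
                                      "enrichment_kegg.tsv")
  }

  report <- list(
    tool = "herbnetpharm",
    version = as.character(utils::packageVersion("herbnetpharm")),
    seed = seed_used,
    thresholds = list(ob_min = thresholds$ob_min,
                      dl_min = thresholds$dl_min,
                      inclusive = thresholds$inclusive,
                      alpha = alpha, strict_screen = strict,
                      mcode_vwp = params$vwp),
    adme = as.list(screen_summary(screen$report)),
    compound_target_network = list(
      n_nodes = graph_order(ct$graph),
      n_compounds = sum(ct$graph$node_kind == "compound"),
      n_targets = length(compound_targets),
      n_edges = graph_size(ct$graph),
      compounds_without_targets = ct$compounds_without_targets
    ),
    disease = list(n_genes = length(disease$genes),
                   ppi_nodes = graph_order(disease_ppi$graph),
                   ppi_edges = graph_size(disease_ppi$graph)),
    modules = list(n_modules = length(modules),
                   top_score = if (length(modules) > 0)
                     modules[[1]]$score else NA_real_,
                   top_size = if (length(modules) > 0)
                     modules[[1]]$n else NA_integer_),
    merged_network = list(n_nodes = graph_order(merged$graph),
                          n_edges = graph_size(merged$graph)),
    shared_targets = shared,
    screen = list(n_key_targets = length(key_nodes),
                  central_edges = central_edges,
                  key_targets = key_nodes),
    enrichment = enr_counts
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("done: ", out_dir, "/report.json")
  invisible(report)
}
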