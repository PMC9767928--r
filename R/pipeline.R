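#' Run the full footprint pipeline from one configuration
#'
#' Chains the stages in dependency order: obtain a network (read from disk
#' or simulate), filter accessory metabolites, export the SIF edge list,
#' build the shortest-path forest, compute signed dissipation weights
#' (species-level and base-name collapsed), run the metabolomics statistics
#' (QC RSD filter, TIC normalization, log2, optional batch regression,
#' moderated t with BH correction), and score footprints. All outputs are
#' written with stable ordering, so identical configuration and inputs give
#' byte-identical files; a manifest with input/output checksums, the
#' parameters and the package version closes the run.
#'
#' @param config A configuration list or the path to a YAML file with it.
#'   Recognised top-level keys (unknown keys are rejected): `out`,
#'   `simulate` (a block of [fixture_spec()] arguments), `network` (dir),
#'   `cofactors` (file), `abundance`, `design`, `mapping` (files),
#'   `filter` (`min_atoms`, `max_promiscuity`, `explicit_removals`),
#'   `penalty`, `qc_rsd`, `contrast` (two group labels), `footprint`
#'   (`root`, optional `seed_product`, `seed_reactant`).
#' @param out Output directory; overrides `config$out`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "metafoot_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("out", "simulate", "network", "cofactors", "abundance", "design",
             "mapping", "filter", "penalty", "qc_rsd", "contrast", "footprint")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "metafoot_config_error")
  }
  out <- out %||% config$out
  if (is.null(out)) {
    abort("an output directory is required ('out')",
          class = "metafoot_config_error")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  penalty <- config$penalty %||% 0.8
  qc_rsd <- config$qc_rsd %||% 0.30
  filter_cfg <- config$filter %||% list()
  inputs <- character()

  # --- network + abundance inputs ------------------------------------------
  if (!is.null(config$simulate)) {
    spec <- do.call(fixture_spec, config$simulate)
    network <- make_network(spec)
    sim <- make_abundances(spec, network)
    sim_dir <- file.path(out, "simulated")
    write_reaction_network(network, sim_dir)
    readr::write_csv(sim$abundance, file.path(sim_dir, "abundance.csv"))
    readr::write_csv(sim$design, file.path(sim_dir, "design.csv"))
    readr::write_csv(sim$mapping, file.path(sim_dir, "mapping.csv"))
    abundance <- sim$abundance
    design <- sim$design
    mapping <- sim$mapping
  } else {
    if (is.null(config$network)) {
      abort("either 'network' or 'simulate' must be configured",
            class = "metafoot_config_error")
    }
    network <- read_reaction_network(config$network)
    inputs <- c(inputs, file.path(config$network, c("reactions.csv",
                                                    "metabolites.csv")))
    abundance <- design <- mapping <- NULL
    if (!is.null(config$abundance)) {
      for (p in c(config$abundance, config$design)) {
        if (is.null(p) || !file.exists(p)) {
          abort(sprintf("required stats input not found: %s",
                        p %||% "(design missing)"),
                class = "metafoot_io_error")
        }
      }
      abundance <- readr::read_csv(config$abundance,
                                   col_types = readr::cols(sample = "c",
                                                           .default = "d"))
      design <- readr::read_csv(config$design,
                                col_types = readr::cols(is_qc = "l",
                                                        .default = "c"))
      inputs <- c(inputs, config$abundance, config$design)
      if (!is.null(config$mapping)) {
        mapping <- read_name_mapping(config$mapping)
        inputs <- c(inputs, config$mapping)
      }
    }
  }
  cofactors <- character()
  if (!is.null(config$cofactors)) {
    cofactors <- read_cofactor_list(config$cofactors)
    inputs <- c(inputs, config$cofactors)
  }

  # --- network stages -------------------------------------------------------
  filtered <- filter_network(
    network,
    cofactors = cofactors,
    explicit_removals = filter_cfg$explicit_removals %||%
      c("CO2", "ITP", "IDP", "NADH"),
    min_atoms = filter_cfg$min_atoms %||% 4,
    max_promiscuity = filter_cfg$max_promiscuity %||% 100
  )
  write_reaction_network(filtered, file.path(out, "network_filtered"))
  readr::write_csv(removal_report(filtered),
                   file.path(out, "removal_report.csv"))
  graph <- build_instance_graph(filtered)
  write_sif(sif_edges(graph), file.path(out, "network.sif"))
  forest <- build_forest(graph)
  write_forest_json(forest, file.path(out, "forest.json"))
  weights <- signed_weights(forest, penalty = penalty)
  write_weight_table(weights, file.path(out, "weights.csv"))
  weights_base <- collapse_to_base_names(weights, filtered)
  readr::write_csv(as_tibble(weights_base), file.path(out, "weights_base.csv"),
                   na = "")

  # --- statistics + scoring -------------------------------------------------
  stats_table <- scatter <- imbalance <- NULL
  if (!is.null(abundance)) {
    contrast <- config$contrast %||% c("CASE", "CTRL")
    prepped <- abundance |>
      qc_rsd_filter(design, threshold = qc_rsd) |>
      tic_normalize() |>
      log2_transform()
    n_batches <- length(unique(design$batch[!design$is_qc]))
    if (n_batches > 1) prepped <- remove_batch_effect(prepped, design)
    stats_table <- moderated_t(prepped, design, contrast)
    readr::write_csv(stats_table, file.path(out, "stats.csv"))
    imbalance <- imbalance_score(weights_base, stats_table, mapping = mapping)
    readr::write_csv(imbalance, file.path(out, "imbalance.csv"))
    fp <- config$footprint
    if (!is.null(fp$root)) {
      wmap <- weights_base
      if (!is.null(fp$seed_product) || !is.null(fp$seed_reactant)) {
        root_id <- resolve_roots(weights_base, fp$root)[1]
        cf <- channel_forest(graph, root_id,
                             seed_product = fp$seed_product,
                             seed_reactant = fp$seed_reactant)
        wmap <- collapse_to_base_names(signed_weights(cf, penalty), filtered)
      }
      scatter <- footprint_scatter(wmap, stats_table, root = fp$root,
                                   mapping = mapping)
      readr::write_csv(as_tibble(scatter), file.path(out, "scatter.csv"))
    }
  }

  # --- manifest -------------------------------------------------------------
  outputs <- radix_sort(setdiff(list.files(out, recursive = TRUE),
                                "manifest.json"))
  manifest <- list(
    tool = "metafoot",
    version = as.character(packageVersion("metafoot")),
    parameters = list(
      penalty = penalty, qc_rsd = qc_rsd,
      min_atoms = filter_cfg$min_atoms %||% 4,
      max_promiscuity = filter_cfg$max_promiscuity %||% 100,
      contrast = config$contrast %||% c("CASE", "CTRL"),
      simulate = config$simulate
    ),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(setNames(unname(tools::md5sum(file.path(out, outputs))),
                               outputs))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(
    network = filtered, graph = graph, forest = forest, weights = weights,
    weights_base = weights_base, stats = stats_table, scatter = scatter,
    imbalance = imbalance, out = out
  ))
}
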