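#' Compute the enzyme-rooted shortest-path forest
#'
#' For every enzyme instance (or a chosen subset) the bipartite graph is
#' traversed breadth-first twice: along edge direction to reach direct and
#' indirect products (`down_distance`) and against it to reach direct and
#' indirect reactants (`up_distance`). Distances count reactions traversed,
#' the root included, so a direct product or reactant sits at distance 1
#' and each further reaction adds 1. On the bipartite graph this is
#' `(edge_count + 1) / 2`. Unreachable species are absent on that side; in
#' cyclic networks a species can carry both distances.
#'
#' @param graph An [build_instance_graph()] result.
#' @param roots Optional character vector of instance ids (default: all).
#' @return A `footprint_forest` tibble with `root_id`, `species_id`,
#'   `down_distance`, `up_distance` (NA when unreachable on that side);
#'   rows where both sides are unreachable are omitted.
#' @export
#' @examples
#' net <- make_network(fixture_spec("chain", n_species = 3))
#' build_forest(build_instance_graph(net))
build_forest <- function(graph, roots = NULL) {
  stopifnot(inherits(graph, "instance_graph"))
  enzymes <- graph$nodes$node_id[graph$nodes$node_type == "enzyme"]
  mets <- graph$nodes$node_id[graph$nodes$node_type == "metabolite"]
  if (is.null(roots)) {
    roots <- enzymes
  } else {
    unknown <- setdiff(roots, enzymes)
    if (length(unknown) > 0) {
      abort(sprintf("unknown root instance(s): %s",
                    paste(unknown, collapse = ", ")),
            class = "metafoot_lookup_error")
    }
  }
  empty <- tibble(root_id = character(), species_id = character(),
                  down_distance = integer(), up_distance = integer())
  if (length(roots) == 0 || length(mets) == 0) {
    return(structure(empty, class = c("footprint_forest", class(empty))))
  }
  ig <- as_igraph(graph)
  d_down <- igraph::distances(ig, v = roots, to = mets, mode = "out",
                              weights = NA)
  d_up <- igraph::distances(ig, v = roots, to = mets, mode = "in",
                            weights = NA)
  to_steps <- function(d) {
    s <- (d + 1) / 2
    s[!is.finite(s)] <- NA
    s
  }
  down <- to_steps(d_down)
  up <- to_steps(d_up)
  out <- tibble(
    root_id = rep(roots, times = length(mets)),
    species_id = rep(mets, each = length(roots)),
    down_distance = as.integer(as.vector(down)),
    up_distance = as.integer(as.vector(up))
  )
  out <- out[!(is.na(out$down_distance) & is.na(out$up_distance)), ]
  out <- out[radix_order(out$root_id, out$species_id), ]
  structure(out, class = c("footprint_forest", class(empty)))
}

#' Channel-restricted footprint of one enzyme instance
#'
#' A multi-substrate reaction carries several conversion channels (for a
#' transaminase: amino acid -> keto acid and 2-oxoglutarate -> glutamate).
#' This restricts a root's footprint to one channel by seeding the
#' downstream traversal at a chosen direct product and/or the upstream
#' traversal at a chosen direct reactant; the unseeded side keeps the full
#' root footprint.
#'
#' @param graph An [build_instance_graph()] result.
#' @param root One enzyme instance id.
#' @param seed_product Optional species id; must be a direct product of
#'   `root`. Downstream distances then follow that branch only.
#' @param seed_reactant Optional species id; must be a direct reactant of
#'   `root`. Upstream distances then follow that branch only.
#' @return A `footprint_forest` tibble for the single root.
#' @export
channel_forest <- function(graph, root, seed_product = NULL,
                           seed_reactant = NULL) {
  stopifnot(inherits(graph, "instance_graph"))
  base <- build_forest(graph, roots = root)
  if (is.null(seed_product) && is.null(seed_reactant)) return(base)
  ig <- as_igraph(graph)
  mets <- graph$nodes$node_id[graph$nodes$node_type == "metabolite"]

  seeded_side <- function(seed, mode, role) {
    direct <- if (role == "product") {
      graph$edges$to[graph$edges$from == root]
    } else {
      graph$edges$from[graph$edges$to == root]
    }
    if (!seed %in% direct) {
      abort(sprintf("'%s' is not a direct %s of root '%s'", seed, role, root),
            class = "metafoot_lookup_error")
    }
    d <- igraph::distances(ig, v = seed, to = mets, mode = mode, weights = NA)
    s <- d / 2 + 1  # seed itself: 0 edges -> distance 1 from the root
    s[!is.finite(s)] <- NA
    setNames(as.integer(s), mets)
  }

  down <- setNames(base$down_distance, base$species_id)
  up <- setNames(base$up_distance, base$species_id)
  all_sp <- radix_sort(unique(mets))
  down <- down[match(all_sp, names(down))]
  up <- up[match(all_sp, names(up))]
  if (!is.null(seed_product)) {
    down <- seeded_side(seed_product, "out", "product")[all_sp]
  }
  if (!is.null(seed_reactant)) {
    up <- seeded_side(seed_reactant, "in", "reactant")[all_sp]
  }
  out <- tibble(root_id = root, species_id = all_sp,
                down_distance = as.integer(down), up_distance = as.integer(up))
  out <- out[!(is.na(out$down_distance) & is.na(out$up_distance)), ]
  structure(out, class = c("footprint_forest", class(tibble())))
}

#' Serialize a footprint forest as JSON
#'
#' Layout `{root_id: {species_id: {"down": int|null, "up": int|null}}}`,
#' keys sorted, so reruns are byte-identical.
#'
#' @param forest A [build_forest()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  by_root <- split(forest, forest$root_id)
  payload <- map(by_root, function(rows) {
    entries <- map2(rows$down_distance, rows$up_distance, function(d, u) {
      list(down = if (is.na(d)) NULL else d, up = if (is.na(u)) NULL else u)
    })
    setNames(entries, rows$species_id)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a footprint forest from JSON
#'
#' @param path File written by [write_forest_json()].
#' @return A `footprint_forest` tibble.
#' @export
read_forest_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "metafoot_io_error")
  }
  payload <- jsonlite::read_json(path)
  rows <- imap(payload, function(species, root) {
    tibble(
      root_id = root,
      species_id = names(species),
      down_distance = unname(map_int(species, function(e) {
        if (is.null(e$down)) NA_integer_ else as.integer(e$down)
      })),
      up_distance = unname(map_int(species, function(e) {
        if (is.null(e$up)) NA_integer_ else as.integer(e$up)
      }))
    )
  })
  out <- bind_rows(rows)
  out <- out[radix_order(out$root_id, out$species_id), ]
  structure(out, class = c("footprint_forest", class(tibble())))
}
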