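#' Build the bipartite enzyme-metabolite instance graph
#'
#' Nodes are metabolite species plus enzyme instances; directed edges run
#' reactant -> instance (the enzyme needs the reactant) and instance ->
#' product (the product depends on the enzyme). Because compartments live
#' inside species ids and no cross-compartment edge is ever created beyond
#' explicit transport reactions, paths conserve compartment information by
#' construction. Instances flagged `swapped` (backward flux or the `@bwd`
#' half of a reversible reaction) take the declared products as their
#' reactants and vice versa.
#'
#' @param network A [reaction_network()], typically after
#'   [filter_network()].
#' @return An `instance_graph`: list with `$nodes` (node_id, node_type),
#'   `$edges` (from, to) and `$instances` (the [enzyme_instances()] table).
#' @export
build_instance_graph <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  instances <- enzyme_instances(network)
  rxns <- network$reactions
  side_of <- function(rid, declared) {
    i <- match(rid, rxns$reaction_id)
    rxns[[declared]][[i]]$species_id
  }
  edge_rows <- pmap(list(instances$instance_id, instances$reaction_id,
                         instances$swapped),
                    function(iid, rid, swapped) {
    ins <- side_of(rid, if (swapped) "products" else "reactants")
    outs <- side_of(rid, if (swapped) "reactants" else "products")
    bind_rows(
      tibble(from = ins, to = rep(iid, length(ins))),
      tibble(from = rep(iid, length(outs)), to = outs)
    )
  })
  edges <- bind_rows(edge_rows)
  if (nrow(edges) == 0) edges <- tibble(from = character(), to = character())
  edges <- distinct(edges)
  edges <- edges[radix_order(edges$from, edges$to), ]

  nodes <- bind_rows(
    tibble(node_id = network$metabolites$species_id, node_type = "metabolite"),
    tibble(node_id = instances$instance_id, node_type = "enzyme")
  )
  nodes <- nodes[radix_order(nodes$node_id), ]

  g <- structure(list(nodes = nodes, edges = edges, instances = instances),
                 class = "instance_graph")
  validate_instance_graph(g)
  g
}

validate_instance_graph <- function(g) {
  type_of <- setNames(g$nodes$node_type, g$nodes$node_id)
  if (nrow(g$edges) > 0) {
    missing <- setdiff(c(g$edges$from, g$edges$to), g$nodes$node_id)
    if (length(missing) > 0) {
      abort(sprintf("edge endpoint(s) missing from node table: %s",
                    paste(missing, collapse = ", ")),
            class = "metafoot_integrity_error")
    }
    same <- type_of[g$edges$from] == type_of[g$edges$to]
    if (any(same)) {
      abort("instance graph is not bipartite: edge joins two nodes of the same type",
            class = "metafoot_integrity_error")
    }
  }
  invisible(g)
}

#' @export
print.instance_graph <- function(x, ...) {
  cat(sprintf("<instance_graph> %d metabolites, %d enzyme instances, %d edges\n",
              sum(x$nodes$node_type == "metabolite"),
              sum(x$nodes$node_type == "enzyme"),
              nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes$node_id)
}

#' Export an instance graph as SIF edges
#'
#' @param graph An [build_instance_graph()] result.
#' @return Tibble with `source`, `relation` (constant `"1"`), `target` —
#'   ready for [write_sif()].
#' @export
sif_edges <- function(graph) {
  stopifnot(inherits(graph, "instance_graph"))
  tibble(source = graph$edges$from, relation = "1", target = graph$edges$to)
}
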