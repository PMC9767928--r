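#' Collapse a weight map to compartment-free base names
#'
#' Footprint reports and plots use compartment-free metabolite names, while
#' the graph keeps compartment-tagged species. For each (root, base name)
#' the minimal distance across the compartment duplicates is kept per
#' direction, before signing and averaging, and the signed weight is then
#' recomputed at the collapsed distances. Ties are broken lexicographically
#' on species id; the winning species per direction is recorded for
#' provenance.
#'
#' @param weights A [signed_weights()] result (species-level).
#' @param network The [reaction_network()] the weights came from (supplies
#'   the species -> base name mapping).
#' @param penalty Dissipation parameter; defaults to the penalty recorded
#'   on `weights`.
#' @return A `weight_map` tibble keyed by (`root_id`, `base_name`) with the
#'   collapsed distances, the recomputed `weight`, and provenance columns
#'   `down_species` / `up_species`.
#' @export
collapse_to_base_names <- function(weights, network,
                                   penalty = attr(weights, "penalty")) {
  stopifnot(is.data.frame(weights), inherits(network, "reaction_network"))
  if (is.null(penalty)) {
    abort("penalty is not recorded on the weight map; pass it explicitly",
          class = "metafoot_config_error")
  }
  w <- as_tibble(weights) |>
    left_join(select(network$metabolites, "species_id", "base_name"),
              by = "species_id")
  if (any(is.na(w$base_name))) {
    abort("weight map references species absent from the network",
          class = "metafoot_integrity_error")
  }
  min_side <- function(dist, species) {
    ok <- !is.na(dist)
    if (!any(ok)) return(list(distance = NA_integer_, species = NA_character_))
    best <- min(dist[ok])
    winners <- radix_sort(species[ok][dist[ok] == best])
    list(distance = as.integer(best), species = winners[1])
  }
  out <- w |>
    group_by(.data$root_id, .data$base_name) |>
    summarise(
      down = list(min_side(.data$down_distance, .data$species_id)),
      up = list(min_side(.data$up_distance, .data$species_id)),
      .groups = "drop"
    ) |>
    mutate(
      down_distance = map_int(.data$down, "distance"),
      up_distance = map_int(.data$up, "distance"),
      down_species = map_chr(.data$down, "species"),
      up_species = map_chr(.data$up, "species")
    ) |>
    select("root_id", "base_name", "down_distance", "up_distance",
           "down_species", "up_species")
  down_w <- ifelse(is.na(out$down_distance), NA_real_,
                   weight_from_distance(out$down_distance, penalty))
  up_w <- ifelse(is.na(out$up_distance), NA_real_,
                 weight_from_distance(out$up_distance, penalty))
  out$weight <- dplyr::case_when(
    !is.na(down_w) & !is.na(up_w) ~ (down_w - up_w) / 2,
    !is.na(down_w) ~ down_w,
    !is.na(up_w) ~ -up_w
  )
  out <- out[radix_order(out$root_id, out$base_name), ]
  structure(out, penalty = penalty, class = c("weight_map", class(tibble())))
}

resolve_roots <- function(weights, selector) {
  roots <- unique(weights$root_id)
  catalyst <- sub("@.*$", "", roots)
  members <- map(strsplit(catalyst, "+", fixed = TRUE), identity)
  hit <- roots == selector | catalyst == selector |
    map_lgl(members, function(m) selector %in% m)
  matched <- roots[hit]
  if (length(matched) == 0) {
    abort(sprintf("no enzyme instance matches selector '%s'", selector),
          class = "metafoot_lookup_error")
  }
  matched
}

map_stats_to_bases <- function(stats, mapping) {
  if (is.null(mapping)) {
    mapping <- tibble(measured_name = stats$metabolite,
                      base_name = stats$metabolite)
  }
  mapping <- as_tibble(mapping)
  if (anyDuplicated(paste(mapping$measured_name, mapping$base_name))) {
    mapping <- distinct(mapping)
  }
  if (any(is.na(mapping$base_name) | mapping$base_name == "")) {
    abort("mapping targets must be non-empty", class = "metafoot_format_error")
  }
  inner_join(stats, mapping, by = c(metabolite = "measured_name"),
             relationship = "many-to-many")
}

#' Per-enzyme footprint scatter table
#'
#' Joins a base-name weight map with a differential table to reproduce the
#' footprint scatter for one enzyme: x is the signed weighted distance
#' index (the dissipation weight), y the metabolite's t-value, and the dot
#' size their absolute product, so metabolites that are both strongly
#' deregulated and close to the enzyme dominate the plot. A measured name
#' mapped to several network species resolves to the minimum-distance one.
#'
#' @param weights A base-name `weight_map` (see [collapse_to_base_names()]).
#' @param stats Differential tibble with `metabolite` and `t_value` columns
#'   (from [moderated_t()]).
#' @param root Selector for the footprint root: an instance id, a catalyst
#'   label, or a single gene (matches every instance whose complex contains
#'   it).
#' @param mapping Optional tibble `measured_name` -> `base_name`; default
#'   identity.
#' @return A `footprint_scatter` tibble with `root_id`, `metabolite`
#'   (measured name), `weight`, `t_value`, `dot_size`, `side`
#'   (upstream/downstream/both), sorted by decreasing dot size. The count
#'   of measured metabolites without a weight for the root is reported via
#'   a message and attribute `"n_unmapped"`.
#' @export
footprint_scatter <- function(weights, stats, root, mapping = NULL) {
  stopifnot(is.data.frame(weights), is.data.frame(stats))
  if (!"base_name" %in% names(weights)) {
    abort("footprint_scatter expects a base-name weight map; run collapse_to_base_names() first",
          class = "metafoot_format_error")
  }
  roots <- resolve_roots(weights, root)
  mapped <- map_stats_to_bases(as_tibble(stats), mapping)
  rows <- weights[weights$root_id %in% roots, ]
  joined <- inner_join(mapped, rows, by = "base_name",
                       relationship = "many-to-many") |>
    mutate(min_distance = pmin(.data$down_distance, .data$up_distance,
                               na.rm = TRUE)) |>
    group_by(.data$root_id, .data$metabolite) |>
    arrange(.data$min_distance, .data$base_name, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  n_unmapped <- length(setdiff(unique(as_tibble(stats)$metabolite),
                               unique(joined$metabolite)))
  if (n_unmapped > 0) {
    inform(sprintf("footprint_scatter: %d measured metabolite(s) have no weight for this root",
                   n_unmapped))
  }
  out <- joined |>
    mutate(
      dot_size = abs(.data$t_value * .data$weight),
      side = dplyr::case_when(
        !is.na(.data$down_distance) & !is.na(.data$up_distance) ~ "both",
        !is.na(.data$down_distance) ~ "downstream",
        TRUE ~ "upstream"
      )
    ) |>
    select("root_id", "metabolite", "base_name", "weight", "t_value",
           "dot_size", "side")
  out <- out[radix_order(-out$dot_size, out$root_id, out$metabolite), ]
  structure(out, n_unmapped = n_unmapped,
            class = c("footprint_scatter", class(tibble())))
}

#' Upstream/downstream imbalance score per enzyme
#'
#' A weighted-mean summary of a footprint: for each root,
#' sum(weight * t) / sum(|weight|) over the mapped metabolites. Positive
#' scores mean accumulation downstream relative to upstream (products up,
#' substrates down), the signature of the enzyme's own deregulation. This
#' summary is an extension of the footprint scatter, provided for ranking;
#' the scatter is the primary output.
#'
#' @param weights A base-name `weight_map`.
#' @param stats Differential tibble with `metabolite` and `t_value`.
#' @param roots Optional selector(s) (as in [footprint_scatter()]) or
#'   `NULL` for every root in the map.
#' @param mapping Optional measured-name mapping.
#' @return Tibble `root_id`, `score`, `n_metabolites`, sorted by decreasing
#'   `|score|`. Roots whose footprint meets no measured metabolite score 0.
#' @export
imbalance_score <- function(weights, stats, roots = NULL, mapping = NULL) {
  stopifnot(is.data.frame(weights), is.data.frame(stats))
  if (!"base_name" %in% names(weights)) {
    abort("imbalance_score expects a base-name weight map",
          class = "metafoot_format_error")
  }
  root_ids <- if (is.null(roots)) {
    unique(weights$root_id)
  } else {
    unique(unlist(map(roots, function(r) resolve_roots(weights, r))))
  }
  mapped <- map_stats_to_bases(as_tibble(stats), mapping)
  joined <- weights[weights$root_id %in% root_ids, ] |>
    inner_join(mapped, by = "base_name", relationship = "many-to-many")
  scored <- joined |>
    group_by(.data$root_id) |>
    summarise(
      score = {
        denom <- sum(abs(.data$weight))
        if (denom == 0) 0 else sum(.data$weight * .data$t_value) / denom
      },
      n_metabolites = dplyr::n(),
      .groups = "drop"
    )
  out <- tibble(root_id = root_ids) |>
    left_join(scored, by = "root_id") |>
    mutate(score = replace_na(.data$score, 0),
           n_metabolites = as.integer(replace_na(.data$n_metabolites, 0L)))
  out[radix_order(-abs(out$score), out$root_id), ]
}

#' Read a measured-name mapping CSV
#'
#' @param path CSV with columns `measured_name`, `base_name`.
#' @return The mapping tibble.
#' @export
read_name_mapping <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "metafoot_io_error")
  }
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- setdiff(c("measured_name", "base_name"), names(out))
  if (length(need) > 0) {
    abort(sprintf("mapping file is missing column(s): %s",
                  paste(need, collapse = ", ")),
          class = "metafoot_format_error")
  }
  out
}

#' Plot a footprint scatter
#'
#' Signed weighted distance index on x (upstream negative, downstream
#' positive), differential t-value on y, dot area proportional to
#' |t x weight|; the most prominent metabolites are labelled.
#'
#' @param object A [footprint_scatter()] result.
#' @param n_labels Number of top dots to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.footprint_scatter <- function(object, n_labels = 8, ...) {
  df <- as_tibble(object)
  lab <- head(df[radix_order(-df$dot_size), ], n_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$t_value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$dot_size,
                                     colour = .data$side), alpha = 0.8) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$metabolite),
                       vjust = -1, size = 3) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(
      x = "weighted distance index (upstream < 0 < downstream)",
      y = "t-value", size = "|t x weight|", colour = NULL,
      title = unique(df$root_id)[1]
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.footprint_scatter
#' @param scatter A [footprint_scatter()] result.
#' @export
plot_footprint <- function(scatter, n_labels = 8) {
  autoplot.footprint_scatter(scatter, n_labels = n_labels)
}
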