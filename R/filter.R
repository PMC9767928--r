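#' Reactant degree of network species
#'
#' Number of distinct reactions that list a species among their declared
#' reactants (appearances as product do not count; a reversible reaction
#' counts once). Species consumed by very many reactions are currency
#' metabolites (ATP, water, protons ...) whose paths short-circuit the
#' network, so the filter removes reactant degrees above a promiscuity
#' threshold.
#'
#' @param network A [reaction_network()].
#' @param species Optional character vector of species ids to restrict to;
#'   unknown ids raise an error.
#' @return A tibble with `species_id` and `reactant_degree` covering every
#'   requested species (0 when never a reactant).
#' @export
reactant_degree <- function(network, species = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  used <- tibble(
    reaction_id = rep(network$reactions$reaction_id,
                      map_int(network$reactions$reactants, nrow)),
    species_id = unlist(map(network$reactions$reactants,
                            function(s) s$species_id))
  )
  deg <- used |>
    distinct(.data$reaction_id, .data$species_id) |>
    count(.data$species_id, name = "reactant_degree")
  out <- network$metabolites |>
    select("species_id") |>
    left_join(deg, by = "species_id") |>
    mutate(reactant_degree = as.integer(replace_na(.data$reactant_degree, 0L)))
  if (!is.null(species)) {
    unknown <- setdiff(species, out$species_id)
    if (length(unknown) > 0) {
      abort(sprintf("unknown species: %s", paste(unknown, collapse = ", ")),
            class = "metafoot_lookup_error")
    }
    out <- out[match(species, out$species_id), ]
  }
  out
}

#' Remove accessory metabolites before graph construction
#'
#' Applies, in a single pass over the input network, the four accessory-
#' metabolite rules: (a) membership in a supplied cofactor/nucleotide class
#' list, (b) an explicit base-name removal list (default CO2, ITP, IDP,
#' NADH), (c) fewer than `min_atoms` atoms (species without a parseable
#' formula are conservatively kept), and (d) reactant degree above
#' `max_promiscuity`, computed on the input network. Removed species are
#' dropped from every reaction side; a reaction that loses all species on
#' both sides is dropped, but a reaction keeping only one side is retained
#' so its enzyme still anchors the surviving species.
#'
#' @param network A [reaction_network()].
#' @param cofactors Character vector of cofactor/nucleotide identifiers;
#'   matched against `species_id` or `base_name` (class lists in the wild
#'   mix the two).
#' @param explicit_removals Base names always removed.
#' @param min_atoms Species with a known atom count below this are removed.
#' @param max_promiscuity Species used as reactant by more than this many
#'   reactions are removed.
#' @return The filtered `reaction_network`, carrying the removal report as
#'   attribute `"removal_report"` (see [removal_report()]): one row per
#'   (species, rule) pair that fired.
#' @export
#' @examples
#' net <- make_network(fixture_spec("hub_cofactor", n_species = 10))
#' filtered <- filter_network(net)
#' removal_report(filtered)
filter_network <- function(network,
                           cofactors = character(),
                           explicit_removals = c("CO2", "ITP", "IDP", "NADH"),
                           min_atoms = 4,
                           max_promiscuity = 100) {
  stopifnot(inherits(network, "reaction_network"))
  if (min_atoms <= 0 || max_promiscuity <= 0) {
    abort("filter thresholds must be positive", class = "metafoot_config_error")
  }
  mets <- network$metabolites
  deg <- reactant_degree(network)

  fired <- list(
    cofactor_class = mets$species_id %in% cofactors |
      mets$base_name %in% cofactors,
    explicit_removal = mets$base_name %in% explicit_removals,
    min_atoms = !is.na(mets$atom_count) & mets$atom_count < min_atoms,
    promiscuity = deg$reactant_degree[match(mets$species_id, deg$species_id)] >
      max_promiscuity
  )
  report <- imap(fired, function(hit, rule) {
    tibble(species_id = mets$species_id[hit],
           base_name = mets$base_name[hit],
           rule = rule)
  }) |>
    bind_rows()
  report <- report[radix_order(report$species_id, report$rule), ]
  removed <- unique(report$species_id)

  keep_mets <- mets[!mets$species_id %in% removed, ]
  strip <- function(side) side[!side$species_id %in% removed, , drop = FALSE]
  rxns <- network$reactions
  rxns$reactants <- map(rxns$reactants, strip)
  rxns$products <- map(rxns$products, strip)
  keep_rxn <- map_int(rxns$reactants, nrow) + map_int(rxns$products, nrow) > 0
  rxns <- rxns[keep_rxn, ]

  out <- reaction_network(keep_mets, rxns)
  attr(out, "removal_report") <- report
  out
}

#' Removal report of a filtered network
#'
#' @param network A network returned by [filter_network()].
#' @return Tibble with `species_id`, `base_name`, `rule` — one row per rule
#'   that fired for each removed species (a species can appear under
#'   several rules).
#' @export
removal_report <- function(network) {
  rep <- attr(network, "removal_report")
  if (is.null(rep)) {
    rep <- tibble(species_id = character(), base_name = character(),
                  rule = character())
  }
  rep
}

#' Read a cofactor/nucleotide class list
#'
#' One identifier per line (species_id or base_name); blank lines and
#' `#` comments ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers.
#' @export
read_cofactor_list <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "metafoot_io_error")
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[lines != ""]
}
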