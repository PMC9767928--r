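#' Construct a metabolic reaction network
#'
#' Bundles a metabolite sheet and a reaction sheet into a validated
#' `reaction_network` object, the container every downstream stage consumes.
#' Metabolite species are compartment-tagged: `species_id` is unique per
#' (base name, compartment) and carries the compartment as a suffix by
#' convention (`"glc_c"`, `"glc_m"`), while `base_name` is the
#' compartment-free label used when footprints are collapsed for reporting.
#'
#' @param metabolites A data frame with columns `species_id`, `base_name`,
#'   `compartment` and optionally `formula` (elemental formula string, may be
#'   `NA`). An `atom_count` column is derived from `formula` when absent;
#'   species whose formula does not parse keep an `NA` atom count and a
#'   warning is raised (they are never removed by the size filter).
#' @param reactions A data frame with columns `reaction_id`, `direction`
#'   (one of `"forward"`, `"backward"`, `"reversible"`), `gpr` (boolean
#'   gene-reaction rule over AND/OR, may be empty) and list-columns
#'   `reactants` and `products`, each element a data frame with `species_id`
#'   and positive `coef`.
#'
#' @return A `reaction_network`: a list with tibbles `$metabolites` and
#'   `$reactions`, validated for referential integrity, unique identifiers,
#'   disjoint reactant/product sets and positive stoichiometry.
#' @export
#' @examples
#' net <- reaction_network(
#'   metabolites = tibble::tibble(
#'     species_id = c("A_c", "B_c"), base_name = c("A", "B"),
#'     compartment = "c", formula = c("C3H6O3", NA)
#'   ),
#'   reactions = tibble::tibble(
#'     reaction_id = "r1", direction = "forward", gpr = "g1",
#'     reactants = list(tibble::tibble(species_id = "A_c", coef = 1)),
#'     products = list(tibble::tibble(species_id = "B_c", coef = 1))
#'   )
#' )
#' net
reaction_network <- function(metabolites, reactions) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)

  need_met <- c("species_id", "base_name", "compartment")
  missing_cols <- setdiff(need_met, names(metabolites))
  if (length(missing_cols) > 0) {
    abort(sprintf("metabolite sheet is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "metafoot_format_error")
  }
  need_rxn <- c("reaction_id", "direction", "gpr", "reactants", "products")
  missing_cols <- setdiff(need_rxn, names(reactions))
  if (length(missing_cols) > 0) {
    abort(sprintf("reaction sheet is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "metafoot_format_error")
  }
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if ("atom_count" %in% names(metabolites)) {
    metabolites$atom_count <- as.integer(metabolites$atom_count)
  } else {
    metabolites$atom_count <- atom_count_safe(metabolites$formula)
  }
  metabolites <- metabolites[, c("species_id", "base_name", "compartment",
                                 "formula", "atom_count")]
  metabolites <- metabolites[radix_order(metabolites$species_id), ]
  reactions <- reactions[, need_rxn]
  reactions$reactants <- map(reactions$reactants, canonical_side)
  reactions$products <- map(reactions$products, canonical_side)
  reactions <- reactions[radix_order(reactions$reaction_id), ]

  net <- structure(list(metabolites = metabolites, reactions = reactions),
                   class = "reaction_network")
  validate_network(net)
  net
}

canonical_side <- function(side) {
  side <- as_tibble(side)
  if (nrow(side) == 0) return(tibble(species_id = character(), coef = numeric()))
  side <- side[, c("species_id", "coef")]
  side$coef <- as.numeric(side$coef)
  side[radix_order(side$species_id), ]
}

validate_network <- function(net) {
  mets <- net$metabolites
  rxns <- net$reactions
  if (anyDuplicated(mets$species_id)) {
    abort(sprintf("duplicate species_id: %s",
                  paste(unique(mets$species_id[duplicated(mets$species_id)]),
                        collapse = ", ")),
          class = "metafoot_integrity_error")
  }
  if (any(is.na(mets$compartment) | mets$compartment == "")) {
    abort("every metabolite needs a non-empty compartment",
          class = "metafoot_integrity_error")
  }
  known <- !is.na(mets$atom_count) & !is.na(mets$formula)
  if (any(known)) {
    recomputed <- atom_count_safe(mets$formula[known])
    bad <- which(!is.na(recomputed) & recomputed != mets$atom_count[known])
    if (length(bad) > 0) {
      abort(sprintf("atom_count disagrees with formula for: %s",
                    paste(mets$species_id[known][bad], collapse = ", ")),
            class = "metafoot_integrity_error")
    }
  }
  if (anyDuplicated(rxns$reaction_id)) {
    abort(sprintf("duplicate reaction_id: %s",
                  paste(unique(rxns$reaction_id[duplicated(rxns$reaction_id)]),
                        collapse = ", ")),
          class = "metafoot_integrity_error")
  }
  ok_dir <- rxns$direction %in% c("forward", "backward", "reversible")
  if (!all(ok_dir)) {
    abort(sprintf("invalid direction for reaction(s): %s",
                  paste(rxns$reaction_id[!ok_dir], collapse = ", ")),
          class = "metafoot_format_error")
  }
  for (i in seq_len(nrow(rxns))) {
    r <- rxns$reactants[[i]]
    p <- rxns$products[[i]]
    if (any(c(r$coef, p$coef) <= 0)) {
      abort(sprintf("non-positive stoichiometric coefficient in reaction %s",
                    rxns$reaction_id[i]),
            class = "metafoot_integrity_error")
    }
    overlap <- intersect(r$species_id, p$species_id)
    if (length(overlap) > 0) {
      abort(sprintf("reaction %s lists %s as both reactant and product",
                    rxns$reaction_id[i], paste(overlap, collapse = ", ")),
            class = "metafoot_integrity_error")
    }
  }
  referenced <- unique(unlist(map(c(rxns$reactants, rxns$products),
                                  function(s) s$species_id)))
  dangling <- setdiff(referenced, mets$species_id)
  if (length(dangling) > 0) {
    abort(sprintf("reaction(s) reference undefined species: %s",
                  paste(radix_sort(dangling), collapse = ", ")),
          class = "metafoot_integrity_error")
  }
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d metabolites, %d reactions (%d compartments)\n",
              nrow(x$metabolites), nrow(x$reactions),
              length(unique(x$metabolites$compartment))))
  invisible(x)
}

#' Count atoms in an elemental formula
#'
#' Sums the element multiplicities of a Hill-style formula such as
#' `"C6H12O6"`. The count feeds the small-molecule filter that removes
#' species of fewer than four atoms before graph construction.
#'
#' @param formula Character vector of formulas; `NA` entries yield `NA`.
#' @return Integer vector of total atom counts.
#' @export
#' @examples
#' atom_count_from_formula(c("CO2", "C6H13NO2", "H"))  # 3, 22, 1
atom_count_from_formula <- function(formula) {
  map_int(formula, function(f) {
    if (is.na(f)) return(NA_integer_)
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", f)) {
      abort(sprintf("malformed elemental formula: '%s'", f),
            class = "metafoot_parse_error")
    }
    m <- gregexpr("[A-Z][a-z]?([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    counts <- vapply(tokens, function(tok) {
      num <- sub("^[A-Za-z]+", "", tok)
      if (num == "") 1L else as.integer(num)
    }, integer(1))
    sum(counts)
  })
}

# per-species tolerant variant: malformed formula -> NA count + one warning
atom_count_safe <- function(formula) {
  bad <- character()
  out <- map_int(formula, function(f) {
    res <- tryCatch(atom_count_from_formula(f), error = function(e) {
      bad <<- c(bad, f)
      NA_integer_
    })
    res
  })
  if (length(bad) > 0) {
    warn(sprintf("could not parse formula(s) %s; atom counts set to NA",
                 paste(sprintf("'%s'", unique(bad)), collapse = ", ")))
  }
  out
}

#' Read a reaction network from its two-sheet CSV dialect
#'
#' The network is stored as `metabolites.csv` (species_id, base_name,
#' compartment, formula) plus `reactions.csv` (reaction_id, reactants,
#' products, direction, gpr) where reactant/product cells hold
#' semicolon-separated `coef*species_id` tokens (`"2*A_c;B_c"`; a missing
#' coefficient means 1). The dialect is deliberately hand-editable so toy
#' networks can be written in a text editor.
#'
#' @param path Directory containing the two sheets, or the path to
#'   `reactions.csv` when `metabolites` is given explicitly.
#' @param metabolites Optional explicit path to the metabolite sheet.
#' @return A validated [reaction_network()]. Row order in the files does not
#'   affect the result.
#' @export
read_reaction_network <- function(path, metabolites = NULL) {
  if (is.null(metabolites) && dir.exists(path)) {
    reactions_path <- file.path(path, "reactions.csv")
    metabolites_path <- file.path(path, "metabolites.csv")
  } else {
    reactions_path <- path
    metabolites_path <- metabolites
  }
  for (p in c(reactions_path, metabolites_path)) {
    if (!file.exists(p)) {
      abort(sprintf("file not found: %s", p), class = "metafoot_io_error")
    }
  }
  mets <- readr::read_csv(metabolites_path, col_types = readr::cols(.default = "c"))
  need <- c("species_id", "base_name", "compartment")
  missing_cols <- setdiff(need, names(mets))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", metabolites_path,
                  paste(missing_cols, collapse = ", ")),
          class = "metafoot_format_error")
  }
  rxns <- readr::read_csv(reactions_path, col_types = readr::cols(.default = "c"))
  need <- c("reaction_id", "reactants", "products", "direction", "gpr")
  missing_cols <- setdiff(need, names(rxns))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", reactions_path,
                  paste(missing_cols, collapse = ", ")),
          class = "metafoot_format_error")
  }
  rxns$gpr[is.na(rxns$gpr)] <- ""
  reaction_network(
    metabolites = mets,
    reactions = tibble(
      reaction_id = rxns$reaction_id,
      direction = rxns$direction,
      gpr = rxns$gpr,
      reactants = map(rxns$reactants, parse_participants),
      products = map(rxns$products, parse_participants)
    )
  )
}

parse_participants <- function(cell) {
  if (is.na(cell) || trimws(cell) == "") {
    return(tibble(species_id = character(), coef = numeric()))
  }
  tokens <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  tokens <- tokens[tokens != ""]
  parsed <- map(tokens, function(tok) {
    if (grepl("*", tok, fixed = TRUE)) {
      parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
      if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[1])))) {
        abort(sprintf("cannot parse participant token '%s'", tok),
              class = "metafoot_parse_error")
      }
      list(species_id = trimws(parts[2]), coef = as.numeric(parts[1]))
    } else {
      list(species_id = tok, coef = 1)
    }
  })
  tibble(
    species_id = map_chr(parsed, "species_id"),
    coef = map_dbl(parsed, "coef")
  )
}

format_participants <- function(side) {
  if (nrow(side) == 0) return("")
  tok <- ifelse(side$coef == 1, side$species_id,
                paste0(format(side$coef, trim = TRUE, scientific = FALSE),
                       "*", side$species_id))
  paste(tok, collapse = ";")
}

#' Write a reaction network in the two-sheet CSV dialect
#'
#' @param network A [reaction_network()].
#' @param path Output directory (created if needed); writes
#'   `metabolites.csv` and `reactions.csv` in the dialect
#'   [read_reaction_network()] reads back field-for-field.
#' @return `path`, invisibly.
#' @export
write_reaction_network <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(network$metabolites, file.path(path, "metabolites.csv"), na = "")
  rx <- tibble(
    reaction_id = network$reactions$reaction_id,
    reactants = map_chr(network$reactions$reactants, format_participants),
    products = map_chr(network$reactions$products, format_participants),
    direction = network$reactions$direction,
    gpr = network$reactions$gpr
  )
  readr::write_csv(rx, file.path(path, "reactions.csv"), na = "")
  invisible(path)
}

#' Write edges as a Simple Interaction Format (SIF) table
#'
#' Three tab-separated columns, `source <TAB> 1 <TAB> target`, one row per
#' edge, sorted lexicographically by source then target (byte order, so the
#' file is reproducible across locales). The constant relation "1" encodes
#' activation: a reactant row states the enzyme needs the reactant, a
#' product row states the product depends on the enzyme.
#'
#' @param edges Data frame with columns `source`, `relation`, `target`;
#'   `relation` must be the constant `"1"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  edges <- as_tibble(edges)
  if (nrow(edges) > 0 && !all(edges$relation == "1")) {
    abort("SIF relation column must be the constant \"1\"",
          class = "metafoot_format_error")
  }
  edges <- edges[radix_order(edges$source, edges$target), ]
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(sprintf("cannot write SIF file: %s", path), class = "metafoot_io_error")
  })
  on.exit(close(con))
  if (nrow(edges) > 0) {
    writeLines(paste(edges$source, "1", edges$target, sep = "\t"), con = con)
  }
  invisible(path)
}
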