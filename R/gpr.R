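#' Expand a gene-reaction rule into catalyst alternatives
#'
#' Parses a boolean AND/OR expression over gene identifiers (parentheses
#' allowed, operators case-insensitive) and rewrites it in disjunctive
#' normal form. Each disjunct is one alternative catalyst: a single gene
#' for a plain enzyme, several genes for an obligate complex (AND group
#' acting as a single entity). `"(g1 AND g2) OR g3"` therefore yields the
#' two catalysts `{g1, g2}` and `{g3}`.
#'
#' @param gpr The rule string; an empty or all-whitespace rule yields an
#'   empty list (callers substitute a synthetic orphan catalyst).
#' @return List of character vectors, one sorted gene set per alternative
#'   catalyst, deduplicated.
#' @export
#' @examples
#' expand_gpr("(g1 AND g2) OR g3")
expand_gpr <- function(gpr) {
  if (is.na(gpr) || trimws(gpr) == "") return(list())
  tree <- parse_gpr(gpr)
  disjuncts <- gpr_dnf(tree)
  disjuncts <- map(disjuncts, function(g) radix_sort(unique(g)))
  unique(disjuncts)
}

tokenize_gpr <- function(gpr) {
  spaced <- gsub("\\(", " ( ", gsub("\\)", " ) ", gpr))
  tokens <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  tokens[tokens != ""]
}

# recursive descent: expr := term (OR term)* ; term := atom (AND atom)* ;
# atom := gene | "(" expr ")"
parse_gpr <- function(gpr) {
  tokens <- tokenize_gpr(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  fail <- function(what) {
    abort(sprintf("cannot parse gene-reaction rule '%s' (%s)", gpr, what),
          class = "metafoot_parse_error")
  }
  is_op <- function(tok, op) !is.na(tok) && toupper(tok) == op

  parse_expr <- function() {
    terms <- list(parse_term())
    while (is_op(peek(), "OR")) {
      take()
      terms <- c(terms, list(parse_term()))
    }
    if (length(terms) == 1) terms[[1]] else list(op = "or", args = terms)
  }
  parse_term <- function() {
    atoms <- list(parse_atom())
    while (is_op(peek(), "AND")) {
      take()
      atoms <- c(atoms, list(parse_atom()))
    }
    if (length(atoms) == 1) atoms[[1]] else list(op = "and", args = atoms)
  }
  parse_atom <- function() {
    tok <- take()
    if (is.na(tok)) fail("unexpected end of rule")
    if (tok == "(") {
      inner <- parse_expr()
      if (!identical(take(), ")")) fail("missing closing parenthesis")
      return(inner)
    }
    if (tok == ")" || toupper(tok) %in% c("AND", "OR")) {
      fail(sprintf("unexpected token '%s'", tok))
    }
    list(op = "gene", name = tok)
  }

  out <- parse_expr()
  if (!is.na(peek())) fail(sprintf("trailing token '%s'", peek()))
  out
}

gpr_dnf <- function(node) {
  switch(node$op,
    gene = list(node$name),
    or = unlist(map(node$args, gpr_dnf), recursive = FALSE),
    and = Reduce(function(acc, arg) {
      rhs <- gpr_dnf(arg)
      unlist(map(acc, function(a) map(rhs, function(b) c(a, b))),
             recursive = FALSE)
    }, node$args[-1], init = gpr_dnf(node$args[[1]]))
  )
}

#' Enumerate enzyme instances of a network
#'
#' Every (catalyst alternative, reaction) pair becomes one enzyme instance —
#' the unique root of a footprint tree. Complexes (AND groups) are single
#' catalysts joined with `+`; OR alternatives become separate instances
#' sharing the reaction; reactions with an empty rule get a synthetic
#' `orphan:<reaction_id>` catalyst so spontaneous and transport steps still
#' propagate distance. Reversible reactions expand into two opposed
#' instances tagged `@fwd` / `@bwd`.
#'
#' @param network A [reaction_network()].
#' @return Tibble with `instance_id` (`catalyst@reaction_id[@tag]`),
#'   `catalyst`, `members` (list of gene ids), `reaction_id`, and `swapped`
#'   (`TRUE` when the instance runs the reaction right-to-left, i.e. the
#'   declared products act as its reactants).
#' @export
enzyme_instances <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  rxns <- network$reactions
  rows <- pmap(list(rxns$reaction_id, rxns$direction, rxns$gpr),
               function(rid, dir, gpr) {
    catalysts <- expand_gpr(gpr)
    if (length(catalysts) == 0) catalysts <- list(paste0("orphan:", rid))
    labels <- map_chr(catalysts, paste, collapse = "+")
    base <- tibble(catalyst = labels, members = catalysts, reaction_id = rid)
    if (dir == "reversible") {
      bind_rows(
        mutate(base, instance_id = paste0(.data$catalyst, "@", rid, "@fwd"),
               swapped = FALSE),
        mutate(base, instance_id = paste0(.data$catalyst, "@", rid, "@bwd"),
               swapped = TRUE)
      )
    } else {
      mutate(base, instance_id = paste0(.data$catalyst, "@", rid),
             swapped = dir == "backward")
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(instance_id = character(), catalyst = character(),
                  members = list(), reaction_id = character(),
                  swapped = logical()))
  }
  out <- out[, c("instance_id", "catalyst", "members", "reaction_id", "swapped")]
  out[radix_order(out$instance_id), ]
}
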