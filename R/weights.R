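#' Dissipation weight of a metabolite at a given distance
#'
#' The weight starts at 1 for direct reactants and products and decays
#' geometrically, `penalty^(distance - 1)`, with each further reaction
#' step: the recurrence x_{i+1} = x_i * penalty with x_0 = 1. With the
#' default penalty 0.8 the weight drops by 20% per step. `penalty = 1`
#' means no decay; `penalty = 0` keeps only direct neighbours (0^0 is
#' taken as 1).
#'
#' @param distance Positive integer reaction-step distance(s).
#' @param penalty Dissipation parameter in \[0, 1\].
#' @return Numeric weight(s) in (0, 1\].
#' @export
#' @examples
#' weight_from_distance(1:4, penalty = 0.8)
weight_from_distance <- function(distance, penalty = 0.8) {
  if (length(penalty) != 1 || is.na(penalty) || penalty < 0 || penalty > 1) {
    abort("penalty must be a single value in [0, 1]",
          class = "metafoot_domain_error")
  }
  ok <- !is.na(distance)
  if (any(distance[ok] < 1) || any(distance[ok] != floor(distance[ok]))) {
    abort("distance must be a positive integer (direct neighbours sit at 1)",
          class = "metafoot_domain_error")
  }
  penalty^(distance - 1)
}

#' Signed dissipation weights for a footprint forest
#'
#' Converts the up/down distances of every (enzyme root, species) pair into
#' a single signed weight in \[-1, 1\]: downstream-only species get
#' `+penalty^(down - 1)`, upstream-only species `-penalty^(up - 1)`, and
#' species reachable both ways (cycles) the arithmetic mean of the two
#' signed values — so a tight cycle with both distances 1 cancels to 0.
#'
#' @param forest A [build_forest()] result.
#' @param penalty Dissipation parameter in \[0, 1\]; default 0.8.
#' @return A `weight_map` tibble with `root_id`, `species_id`,
#'   `down_distance`, `up_distance`, `weight`; the penalty is carried in
#'   attribute `"penalty"`.
#' @export
signed_weights <- function(forest, penalty = 0.8) {
  stopifnot(is.data.frame(forest))
  down_w <- ifelse(is.na(forest$down_distance), NA_real_,
                   weight_from_distance(forest$down_distance, penalty))
  up_w <- ifelse(is.na(forest$up_distance), NA_real_,
                 weight_from_distance(forest$up_distance, penalty))
  weight <- dplyr::case_when(
    !is.na(down_w) & !is.na(up_w) ~ (down_w - up_w) / 2,
    !is.na(down_w) ~ down_w,
    !is.na(up_w) ~ -up_w
  )
  out <- tibble(
    root_id = forest$root_id,
    species_id = forest$species_id,
    down_distance = forest$down_distance,
    up_distance = forest$up_distance,
    weight = weight
  )
  out <- out[radix_order(out$root_id, out$species_id), ]
  structure(out, penalty = penalty,
            class = c("weight_map", class(tibble())))
}

#' Write a weight map as CSV
#'
#' @param weights A [signed_weights()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  readr::write_csv(as_tibble(weights), path, na = "")
  invisible(path)
}

#' Read a weight map written by [write_weight_table()]
#'
#' @param path CSV file.
#' @param penalty The penalty the weights were computed with (recorded as
#'   attribute; needed when base-name collapsing recomputes weights).
#' @return A `weight_map` tibble.
#' @export
read_weight_table <- function(path, penalty = 0.8) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "metafoot_io_error")
  }
  out <- readr::read_csv(path, col_types = readr::cols(
    root_id = "c", species_id = "c", down_distance = "i",
    up_distance = "i", weight = "d"
  ))
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  structure(out, penalty = penalty,
            class = c("weight_map", class(tibble())))
}
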