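#' Specification for a synthetic fixture
#'
#' Bundles the knobs of the deterministic generators: a network topology
#' and size, the random seed (which fully determines both the network and
#' the abundance draws), and the abundance model — a planted enzyme whose
#' footprint receives a signed shift of `effect_size` standard deviations,
#' attenuated with distance by the same `penalty^(d-1)` law the scorer
#' uses (stated openly: generator and scorer share the dissipation law, so
#' parameter-recovery tests close the loop on the implementation, not on a
#' different physics).
#'
#' @param topology One of `"chain"`, `"branch"`, `"cycle"`,
#'   `"hub_cofactor"`, `"two_compartment"`, `"complex_gpr"`, `"random"`.
#' @param n_species Number of metabolite species (per compartment for
#'   `two_compartment`).
#' @param n_reactions Number of reactions for `"random"` (default
#'   `round(1.3 * n_species)`); derived from the topology otherwise.
#' @param seed Integer seed; same spec, same output, everywhere.
#' @param planted_enzyme Instance id (or gene/catalyst selector) whose
#'   footprint carries the planted group difference; `NULL` for a null
#'   data set.
#' @param effect_size Planted shift in units of `noise_sd` (default 3).
#' @param noise_sd Log2-scale residual standard deviation (default 0.25,
#'   a typical LC-MS replicate spread).
#' @param n_samples Samples per biological group (default 5 independent
#'   cultures).
#' @param n_qc Pooled QC injections (default 3).
#' @param n_batches Number of batches the biological samples are split
#'   across (default 1).
#' @param batch_offsets Additive log2 offsets per batch (default
#'   `0, 0.5, 1, ...`).
#' @param penalty Dissipation parameter used to attenuate the planted
#'   effect (default 0.8).
#' @param n_background Measured metabolites outside the network (no planted
#'   effect; default 50). Real LC-MS panels are dominated by species the
#'   network does not model; without this background the total ion count
#'   would be driven by the planted species and TIC normalization would
#'   redistribute the effect compositionally.
#' @param compartment Compartment tag for single-compartment topologies.
#' @param transport For `two_compartment`: add one transport reaction
#'   linking the compartments (default `TRUE`).
#' @param hub_consumers For `hub_cofactor`: number of reactions consuming
#'   the hub species (default 101, just past the promiscuity threshold).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(topology = c("chain", "branch", "cycle",
                                      "hub_cofactor", "two_compartment",
                                      "complex_gpr", "random"),
                         n_species = 5, n_reactions = NULL, seed = 1L,
                         planted_enzyme = NULL, effect_size = 3,
                         noise_sd = 0.25, n_samples = 5, n_qc = 3,
                         n_batches = 1, batch_offsets = NULL, penalty = 0.8,
                         n_background = 50, compartment = "c",
                         transport = TRUE, hub_consumers = 101) {
  topology <- match.arg(topology)
  minimum <- c(chain = 2, branch = 4, cycle = 2, hub_cofactor = 3,
               two_compartment = 2, complex_gpr = 4, random = 3)
  if (n_species < minimum[[topology]]) {
    abort(sprintf("topology '%s' needs at least %d species", topology,
                  minimum[[topology]]),
          class = "metafoot_generation_error")
  }
  if (is.null(n_reactions)) n_reactions <- round(1.3 * n_species)
  if (is.null(batch_offsets)) batch_offsets <- 0.5 * (seq_len(n_batches) - 1)
  if (length(batch_offsets) != n_batches) {
    abort("batch_offsets must have one entry per batch",
          class = "metafoot_generation_error")
  }
  structure(list(
    topology = topology, n_species = n_species, n_reactions = n_reactions,
    seed = as.integer(seed), planted_enzyme = planted_enzyme,
    effect_size = effect_size, noise_sd = noise_sd, n_samples = n_samples,
    n_qc = n_qc, n_batches = n_batches, batch_offsets = batch_offsets,
    penalty = penalty, n_background = n_background,
    compartment = compartment, transport = transport,
    hub_consumers = hub_consumers
  ), class = "fixture_spec")
}

species_names <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("M%03d", seq_len(n))
}

simple_net <- function(bases, compartment, reactions) {
  mets <- tibble(
    species_id = paste0(bases, "_", compartment),
    base_name = bases,
    compartment = compartment,
    formula = NA_character_
  )
  reaction_network(mets, reactions)
}

rx_row <- function(rid, from, to, gpr, direction = "forward") {
  tibble(
    reaction_id = rid, direction = direction, gpr = gpr,
    reactants = list(tibble(species_id = from, coef = rep(1, length(from)))),
    products = list(tibble(species_id = to, coef = rep(1, length(to))))
  )
}

#' Generate a toy reaction network
#'
#' Deterministic network builders for every topology the test-bed needs:
#' linear chains, branched chains, cycles, a currency-metabolite hub that
#' trips the promiscuity filter, duplicated compartments with or without a
#' transport step, AND/OR gene-reaction rules, and seeded random
#' bipartite networks.
#'
#' @param spec A [fixture_spec()].
#' @return A validated [reaction_network()].
#' @export
#' @examples
#' make_network(fixture_spec("chain", n_species = 3))
make_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, make_network_impl(spec))
}

make_network_impl <- function(spec) {
  n <- spec$n_species
  comp <- spec$compartment
  bases <- species_names(n)
  ids <- paste0(bases, "_", comp)
  chain_rx <- function(idx, prefix = "r", gpr_fun = function(i) paste0("g", i)) {
    bind_rows(map(seq_along(idx)[-1], function(i) {
      rx_row(sprintf("%s%d", prefix, i - 1), idx[i - 1], idx[i],
             gpr_fun(i - 1))
    }))
  }
  switch(spec$topology,
    chain = simple_net(bases, comp, chain_rx(ids)),
    branch = {
      # main chain over the first half; remaining species branch off its middle
      n_main <- max(2, ceiling(n / 2))
      main <- ids[seq_len(n_main)]
      extras <- ids[-seq_len(n_main)]
      anchor <- main[ceiling(n_main / 2)]
      rx <- chain_rx(main)
      rx <- bind_rows(rx, bind_rows(imap(extras, function(sp, i) {
        rx_row(sprintf("rb%d", i), anchor, sp, sprintf("gb%d", i))
      })))
      simple_net(bases, comp, rx)
    },
    cycle = {
      rx <- bind_rows(map(seq_len(n), function(i) {
        rx_row(sprintf("r%d", i), ids[i], ids[i %% n + 1], paste0("g", i))
      }))
      simple_net(bases, comp, rx)
    },
    hub_cofactor = {
      hub_id <- paste0("HUB_", comp)
      mets <- tibble(
        species_id = c(ids, hub_id),
        base_name = c(bases, "HUB"),
        compartment = comp,
        formula = c(rep(NA_character_, n), "H2O")
      )
      rx <- chain_rx(ids)
      rx <- bind_rows(rx, bind_rows(map(seq_len(spec$hub_consumers),
        function(k) {
          rx_row(sprintf("rh%d", k), hub_id, ids[(k - 1) %% n + 1],
                 sprintf("gh%d", k))
        })))
      reaction_network(mets, rx)
    },
    two_compartment = {
      ids_c <- paste0(bases, "_c")
      ids_m <- paste0(bases, "_m")
      mets <- tibble(
        species_id = c(ids_c, ids_m),
        base_name = rep(bases, 2),
        compartment = rep(c("c", "m"), each = n),
        formula = NA_character_
      )
      rx <- bind_rows(
        chain_rx(ids_c, prefix = "rc", gpr_fun = function(i) paste0("gc", i)),
        chain_rx(ids_m, prefix = "rm", gpr_fun = function(i) paste0("gm", i))
      )
      if (isTRUE(spec$transport)) {
        rx <- bind_rows(rx, rx_row("t1", ids_c[1], ids_m[1], ""))
      }
      reaction_network(mets, rx)
    },
    complex_gpr = {
      gprs <- c("g1", "gA AND gB", "(gA AND gB) OR gC", "gD OR gE")
      rx <- bind_rows(map(seq_len(n - 1), function(i) {
        rx_row(sprintf("r%d", i), ids[i], ids[i + 1],
               gprs[(i - 1) %% length(gprs) + 1])
      }))
      simple_net(bases, comp, rx)
    },
    random = {
      rx <- bind_rows(map(seq_len(spec$n_reactions), function(k) {
        n_r <- sample(1:2, 1)
        n_p <- sample(1:2, 1)
        picks <- sample(ids, n_r + n_p)
        dir <- if (stats::runif(1) < 0.1) "reversible" else "forward"
        rx_row(sprintf("r%d", k), picks[seq_len(n_r)], picks[-seq_len(n_r)],
               paste0("g", k), direction = dir)
      }))
      simple_net(bases, comp, rx)
    }
  )
}

#' Generate an abundance table with a planted enzyme signal
#'
#' Draws log2-normal baseline abundances per metabolite (base-name level,
#' as a mass spectrometer cannot see compartments), then shifts the case
#' group by `effect_size * noise_sd * weight` where `weight` is the planted
#' enzyme's signed dissipation weight for the metabolite: downstream
#' metabolites accumulate, upstream ones deplete, attenuated with
#' distance. Batch offsets are added to biological samples; QC samples are
#' drawn around the pooled mean with a fifth of the biological noise.
#' Areas are returned on the raw scale (2^log2), ready for the
#' [tic_normalize()] / [log2_transform()] pipeline.
#'
#' @param spec A [fixture_spec()]; `effect_size = 0` or
#'   `planted_enzyme = NULL` gives a null data set.
#' @param network The network from [make_network()] on the same spec.
#' @return List with `abundance` (wide tibble), `design` (sample, group,
#'   batch, is_qc; groups `"CASE"`/`"CTRL"`), and `mapping` (identity
#'   measured-name -> base-name tibble).
#' @export
make_abundances <- function(spec, network) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(network, "reaction_network"))
  withr::with_seed(spec$seed + 10000L, make_abundances_impl(spec, network))
}

make_abundances_impl <- function(spec, network) {
  net_bases <- radix_sort(unique(network$metabolites$base_name))
  background <- if (spec$n_background > 0) {
    sprintf("bg%03d", seq_len(spec$n_background))
  } else {
    character()
  }
  bases <- c(net_bases, background)
  shift <- setNames(rep(0, length(bases)), bases)
  if (!is.null(spec$planted_enzyme) && spec$effect_size != 0) {
    graph <- build_instance_graph(network)
    forest <- build_forest(graph)
    w <- collapse_to_base_names(signed_weights(forest, spec$penalty), network)
    roots <- resolve_roots(w, spec$planted_enzyme)
    wr <- w[w$root_id == roots[1], ]
    shift[wr$base_name] <- spec$effect_size * spec$noise_sd * wr$weight
  }
  n <- spec$n_samples
  groups <- c(rep("CASE", n), rep("CTRL", n))
  samples <- c(sprintf("case_%02d", seq_len(n)), sprintf("ctrl_%02d", seq_len(n)))
  batch <- sprintf("B%d", (seq_along(samples) - 1) %% spec$n_batches + 1)
  offsets <- spec$batch_offsets[(seq_along(samples) - 1) %% spec$n_batches + 1]

  baseline <- stats::rnorm(length(bases), mean = 17, sd = 1.5)
  names(baseline) <- bases
  bio <- map(seq_along(samples), function(i) {
    mu <- baseline + if (groups[i] == "CASE") shift else 0
    mu + offsets[i] + stats::rnorm(length(bases), 0, spec$noise_sd)
  })
  qc_mu <- baseline + shift / 2  # pooled mean of the two groups
  qc <- map(seq_len(spec$n_qc), function(i) {
    qc_mu + stats::rnorm(length(bases), 0, spec$noise_sd / 5)
  })
  log2_mat <- do.call(rbind, c(bio, qc))
  all_samples <- c(samples, sprintf("qc_%02d", seq_len(spec$n_qc)))
  abundance <- dplyr::bind_cols(
    tibble(sample = all_samples),
    as_tibble(setNames(as.data.frame(2^log2_mat), bases))
  )
  design <- tibble(
    sample = all_samples,
    group = c(groups, rep("QC", spec$n_qc)),
    batch = c(batch, rep("B1", spec$n_qc)),
    is_qc = c(rep(FALSE, length(samples)), rep(TRUE, spec$n_qc))
  )
  mapping <- tibble(measured_name = net_bases, base_name = net_bases)
  list(abundance = abundance, design = design, mapping = mapping)
}
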