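base_weight_map <- function(rows, penalty = 0.8) {
  structure(rows, penalty = penalty,
            class = c("weight_map", class(tibble::tibble())))
}

test_that("collapsing keeps the minimal distance per direction", {
  net <- reaction_network(
    tibble::tibble(species_id = c("asp_c", "asp_m", "E_in_c"),
                   base_name = c("asp", "asp", "E_in"), compartment = c("c", "m", "c")),
    tibble::tibble(reaction_id = "r0", direction = "forward", gpr = "gx",
                   reactants = list(tibble::tibble(species_id = "E_in_c", coef = 1)),
                   products = list(tibble::tibble(species_id = "asp_c", coef = 1)))
  )
  w <- base_weight_map(tibble::tibble(
    root_id = "gx@r0",
    species_id = c("asp_c", "asp_m"),
    down_distance = c(2L, 4L),
    up_distance = c(NA_integer_, NA_integer_),
    weight = weight_from_distance(c(2, 4), 0.8)
  ))
  collapsed <- collapse_to_base_names(w, net)
  asp <- collapsed[collapsed$base_name == "asp", ]
  expect_equal(asp$down_distance, 2L)
  expect_equal(asp$down_species, "asp_c")
  expect_equal(asp$weight, 0.8)

  # tie: lexicographic winner recorded, same collapsed result either way
  w_tie <- base_weight_map(tibble::tibble(
    root_id = "gx@r0", species_id = c("asp_m", "asp_c"),
    down_distance = c(2L, 2L), up_distance = c(NA_integer_, NA_integer_),
    weight = c(0.8, 0.8)
  ))
  tie <- collapse_to_base_names(w_tie, net)
  expect_equal(tie$down_species[tie$base_name == "asp"], "asp_c")
  expect_equal(tie$down_distance[tie$base_name == "asp"], 2L)
})

test_that("collapsing a single-compartment map is the identity on distances", {
  net <- toy_network()
  w <- signed_weights(build_forest(build_instance_graph(net)), 0.8)
  collapsed <- collapse_to_base_names(w, net)
  expect_equal(collapsed$down_distance, w$down_distance)
  expect_equal(collapsed$up_distance, w$up_distance)
  expect_equal(collapsed$weight, w$weight)
})

test_that("cross-compartment duplicates collapse before signing", {
  # a catalyzed transporter moves X between compartments: X_m is the root's
  # direct reactant and X_c its direct product, so the collapsed base name X
  # must combine both directions (mean of +1 and -1 = 0), not inherit the
  # signed weight of either species alone
  net <- reaction_network(
    tibble::tibble(species_id = c("X_c", "X_m"),
                   base_name = c("X", "X"), compartment = c("c", "m")),
    tibble::tibble(reaction_id = "t1", direction = "forward", gpr = "g1",
                   reactants = list(tibble::tibble(species_id = "X_m", coef = 1)),
                   products = list(tibble::tibble(species_id = "X_c", coef = 1)))
  )
  w <- signed_weights(build_forest(build_instance_graph(net)), 0.8)
  expect_equal(w$weight, c(1, -1))  # species-level: signed per compartment
  collapsed <- collapse_to_base_names(w, net)
  expect_equal(collapsed$down_distance, 1L)
  expect_equal(collapsed$up_distance, 1L)
  expect_equal(collapsed$weight, 0)
})

test_that("the footprint scatter multiplies t by the weighted distance index", {
  net <- toy_network()
  wb <- collapse_to_base_names(
    signed_weights(build_forest(build_instance_graph(net)), 0.8), net)
  stats <- tibble::tibble(metabolite = c("A", "B", "C"),
                          t_value = c(-2, 0, 5))
  sc <- footprint_scatter(wb, stats, root = "g1")
  expect_equal(sc$dot_size[sc$metabolite == "C"], 0.8 * 5)
  expect_equal(sc$weight[sc$metabolite == "C"], 0.8)
  expect_equal(sc$t_value[sc$metabolite == "C"], 5)
  expect_equal(sc$dot_size[sc$metabolite == "B"], 0)
  expect_equal(sc$side[sc$metabolite == "A"], "upstream")
  expect_lt(sc$weight[sc$metabolite == "A"], 0)
  # sorted by decreasing dot size
  expect_equal(sc$dot_size, sort(sc$dot_size, decreasing = TRUE))

  empty <- footprint_scatter(wb, stats[0, ], root = "g1")
  expect_equal(nrow(empty), 0)
  expect_error(footprint_scatter(wb, stats, root = "nothing"),
               class = "metafoot_lookup_error")
})

test_that("dot sizes are symmetric under t -> -t", {
  net <- random_net(3, n_species = 10, n_reactions = 14)
  wb <- collapse_to_base_names(
    signed_weights(build_forest(build_instance_graph(net)), 0.8), net)
  stats <- tibble::tibble(metabolite = unique(wb$base_name),
                          t_value = rnorm(length(unique(wb$base_name))))
  root <- wb$root_id[1]
  sc_pos <- suppressMessages(footprint_scatter(wb, stats, root = root))
  sc_neg <- suppressMessages(footprint_scatter(
    wb, dplyr::mutate(stats, t_value = -t_value), root = root))
  expect_equal(sc_pos$dot_size, sc_neg$dot_size)
})

test_that("a measured name mapped to several species takes the nearest", {
  net <- toy_network()
  wb <- collapse_to_base_names(
    signed_weights(build_forest(build_instance_graph(net)), 0.8), net)
  mapping <- tibble::tibble(measured_name = c("mmc+succ", "mmc+succ"),
                            base_name = c("B", "C"))
  stats <- tibble::tibble(metabolite = "mmc+succ", t_value = 4)
  sc <- footprint_scatter(wb, stats, root = "g1", mapping = mapping)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$base_name, "B")  # distance 1 beats distance 2
  expect_equal(sc$weight, 1)
})

test_that("the imbalance score is a |weight|-normalized weighted mean", {
  w <- base_weight_map(tibble::tibble(
    root_id = "E@r", species_id = c("P_c", "S_c"),
    base_name = c("P", "S"),
    down_distance = c(1L, NA), up_distance = c(NA, 1L),
    weight = c(1, -1)
  ))
  one <- imbalance_score(w, tibble::tibble(metabolite = "P", t_value = 3))
  expect_equal(one$score, 3)
  # symmetric pair cancels
  both <- imbalance_score(w, tibble::tibble(metabolite = c("P", "S"),
                                            t_value = c(3, 3)))
  expect_equal(both$score, 0)
  # empty intersection scores 0
  none <- imbalance_score(w, tibble::tibble(metabolite = "Z", t_value = 3))
  expect_equal(none$score, 0)
  expect_equal(none$n_metabolites, 0L)
})

test_that("the imbalance score is linear in t", {
  net <- random_net(5, n_species = 10, n_reactions = 14)
  wb <- collapse_to_base_names(
    signed_weights(build_forest(build_instance_graph(net)), 0.8), net)
  set.seed(2)
  stats <- tibble::tibble(metabolite = unique(wb$base_name),
                          t_value = rnorm(length(unique(wb$base_name))))
  s1 <- imbalance_score(wb, stats)
  s3 <- imbalance_score(wb, dplyr::mutate(stats, t_value = 3 * t_value))
  expect_equal(s3$score[match(s1$root_id, s3$root_id)], 3 * s1$score)
})

test_that("the planted enzyme wins the imbalance ranking (spot check)", {
  hits <- 0
  for (seed in 1:5) {
    spec <- fixture_spec("chain", n_species = 9, seed = seed,
                         planted_enzyme = "g4")
    net <- make_network(spec)
    sim <- make_abundances(spec, net)
    prepped <- sim$abundance |>
      qc_rsd_filter(sim$design) |>
      tic_normalize() |>
      log2_transform()
    stats <- moderated_t(prepped, sim$design, c("CASE", "CTRL"))
    wb <- collapse_to_base_names(
      signed_weights(build_forest(build_instance_graph(net)), 0.8), net)
    rank <- imbalance_score(wb, stats, mapping = sim$mapping)
    if (rank$root_id[1] == "g4@r4") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("scatter plots build without error", {
  net <- toy_network()
  wb <- collapse_to_base_names(
    signed_weights(build_forest(build_instance_graph(net)), 0.8), net)
  stats <- tibble::tibble(metabolite = c("A", "B", "C"), t_value = c(-2, 1, 5))
  sc <- footprint_scatter(wb, stats, root = "g1")
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
})
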