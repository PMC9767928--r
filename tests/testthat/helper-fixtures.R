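# Shared in-code fixtures: everything is built programmatically, nothing
# is read from disk.

# Minimal two-reaction chain A_c -(g1)-> B_c -(g2)-> C_c
toy_network <- function() {
  reaction_network(
    metabolites = tibble::tibble(
      species_id = c("A_c", "B_c", "C_c"),
      base_name = c("A", "B", "C"),
      compartment = "c",
      formula = NA_character_
    ),
    reactions = tibble::tibble(
      reaction_id = c("r1", "r2"),
      direction = "forward",
      gpr = c("g1", "g2"),
      reactants = list(tibble::tibble(species_id = "A_c", coef = 1),
                       tibble::tibble(species_id = "B_c", coef = 1)),
      products = list(tibble::tibble(species_id = "B_c", coef = 1),
                      tibble::tibble(species_id = "C_c", coef = 1))
    )
  )
}

# 2-cycle A -(g1)-> B -(g2)-> A
cycle2_network <- function() {
  make_network(fixture_spec("cycle", n_species = 2, seed = 1))
}

random_net <- function(seed, n_species = 20, n_reactions = NULL) {
  make_network(fixture_spec("random", n_species = n_species,
                            n_reactions = n_reactions, seed = seed))
}

# two-group null abundance table with a spread of true variances
make_null_data <- function(seed, n_mets = 60, n_per_group = 4, sd_spread = TRUE) {
  set.seed(seed)
  groups <- rep(c("CASE", "CTRL"), each = n_per_group)
  sds <- if (sd_spread) sqrt(1 / rgamma(n_mets, 4, 4)) else rep(1, n_mets)
  m <- vapply(seq_len(n_mets), function(j) rnorm(length(groups), 10, sds[j]),
              numeric(length(groups)))
  colnames(m) <- sprintf("m%03d", seq_len(n_mets))
  list(
    abundance = dplyr::bind_cols(
      tibble::tibble(sample = sprintf("s%02d", seq_along(groups))),
      tibble::as_tibble(m)
    ),
    design = tibble::tibble(sample = sprintf("s%02d", seq_along(groups)),
                            group = groups, batch = "B1", is_qc = FALSE)
  )
}

# tiny abundance/design pair built by hand (3 metabolites, 2x3 samples + QC)
toy_abundance <- function() {
  list(
    abundance = tibble::tibble(
      sample = c("s1", "s2", "s3", "s4", "s5", "s6", "q1", "q2"),
      A = c(10, 11, 12, 20, 21, 22, 15, 16),
      B = c(5, 6, 5, 5, 6, 5, 5, 6),
      C = c(100, 110, 105, 100, 95, 102, 101, 99)
    ),
    design = tibble::tibble(
      sample = c("s1", "s2", "s3", "s4", "s5", "s6", "q1", "q2"),
      group = c("CTRL", "CTRL", "CTRL", "CASE", "CASE", "CASE", "QC", "QC"),
      batch = "B1",
      is_qc = c(rep(FALSE, 6), TRUE, TRUE)
    )
  )
}
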