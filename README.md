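# metafoot

Enzyme-centric metabolic footprint analysis in R.

## The problem

Differential metabolomics tells you *which* metabolites changed between two
conditions, but not *which enzymes* are responsible. Pathway enrichment
blurs the question further: a pathway label says nothing about whether a
metabolite sits upstream or downstream of the enzyme you care about. When
an enzyme's activity changes, its substrates and products move in opposite
directions — substrates accumulate or deplete on one side of the reaction
while products do the opposite — and that *imbalance across the reaction*
is the signature worth looking for.

`metafoot` makes that signature computable. Starting from a curated,
direction-resolved metabolic reaction network (compartment-tagged
metabolites, stoichiometry, gene–reaction rules), it:

1. **filters accessory metabolites** — cofactor/nucleotide classes, an
   explicit list (CO2, ITP, IDP, NADH), species of fewer than 4 atoms, and
   over-promiscuous species consumed as reactants by more than 100
   reactions — which would otherwise short-circuit every path;
2. **expands gene–reaction rules**: AND-complexes become single catalyst
   entities, OR-alternatives become separate enzyme instances, each bound
   to one specific reaction (the unique roots of footprint trees);
3. **builds a bipartite graph** (reactant → enzyme instance → product) and
   runs a breadth-first search from every root, forward and reversed,
   yielding a *reaction network forest*: the minimal number of reaction
   steps from each enzyme to every reachable metabolite, downstream and
   upstream;
4. **assigns signed dissipation weights**

   w(m, E) = ± p^(d−1),  p ∈ [0, 1]

   starting at 1 for direct reactants/products and decaying by a factor
   `p` (default 0.8, i.e. −20%) per further reaction step; downstream
   weights are positive, upstream negative, and metabolites reachable both
   ways (cycles) get the mean of the two signed values;
5. **scores footprints against differential metabolomics**: per-metabolite
   moderated t-statistics (empirical-Bayes shrunken variances,
   Benjamini–Hochberg correction) are joined with the weight map to draw
   per-enzyme scatter plots — weight on x, t-value on y, dot size
   |t × w| — and to rank enzymes by the imbalance score
   Σ w·t / Σ |w|.

The supporting metabolomics statistics (total-ion-count normalization,
QC relative-standard-deviation filtering at 30%, additive batch
regression) are included, as are deterministic synthetic-data generators
with planted ground truth so the whole chain is testable without any
external data.

## Worked example

A 9-metabolite chain with the signal planted on the fourth enzyme (`g4`),
pushed through the full pipeline:

```r
library(metafoot)

spec    <- fixture_spec("chain", n_species = 9, seed = 11, planted_enzyme = "g4")
network <- make_network(spec)
sim     <- make_abundances(spec, network)

weights <- network |>
  build_instance_graph() |>
  build_forest() |>
  signed_weights(penalty = 0.8) |>
  collapse_to_base_names(network)

stats <- sim$abundance |>
  qc_rsd_filter(sim$design) |>
  tic_normalize() |>
  log2_transform() |>
  moderated_t(sim$design, c("CASE", "CTRL"))

footprint_scatter(weights, stats, root = "g4", mapping = sim$mapping)
#> # A tibble: 9 × 7
#>   root_id metabolite base_name weight t_value dot_size side
#> * <chr>   <chr>      <chr>      <dbl>   <dbl>    <dbl> <chr>
#> 1 g4@r4   D          D          -1      -4.86     4.86 upstream
#> 2 g4@r4   E          E           1       3.42     3.42 downstream
#> 3 g4@r4   C          C          -0.8    -4.07     3.26 upstream
#> 4 g4@r4   B          B          -0.64   -3.56     2.28 upstream

head(imbalance_score(weights, stats, mapping = sim$mapping), 3)
#> # A tibble: 3 × 3
#>   root_id score n_metabolites
#>   <chr>   <dbl>         <int>
#> 1 g4@r4    3.01             9
#> 2 g5@r5    1.76             9
#> 3 g3@r3    1.50             9
```

Reading the scatter: the enzyme's direct substrate `D` (weight −1) is
depleted (t = −4.9) while its direct product `E` (weight +1) accumulates
(t = +3.4) — substrates down, products up, exactly the imbalance pattern
of an activated reaction step. The planted enzyme `g4` tops the imbalance
ranking across all eight candidate roots. `autoplot(scatter)` draws the
corresponding footprint plot.

The same run is available non-interactively:

```sh
Rscript inst/cli/metafoot.R run --config run.yaml --out results/
```

with stages (`simulate`, `filter`, `sif`, `forest`, `weights`, `stats`,
`footprint`) also callable individually; identical configuration and
inputs give byte-identical outputs, and every run writes a manifest with
input/output checksums.

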