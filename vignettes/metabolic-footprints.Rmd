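---
title: "Enzyme-centric metabolic footprints: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-centric metabolic footprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafoot)
```

## The model

`metafoot` estimates, for every enzyme in a metabolic reaction network,
how the metabolites around it have moved in a two-group comparison — and
whether they moved *coherently with the enzyme's position*: substrates one
way, products the other. The unit of analysis is the **enzyme instance**,
one (catalyst, reaction) pair. Gene–reaction rules are expanded to
disjunctive normal form, so an AND-group acts as a single complex entity
and each OR-alternative becomes its own instance; a reaction without a
rule receives a synthetic `orphan:<reaction>` catalyst so spontaneous and
transport steps still propagate distance. Reversible reactions are split
into two opposed instances (`@fwd`, `@bwd`) rather than undirected edges,
because the whole method rests on an up/down sign convention that
undirected edges would destroy.

On the bipartite graph (reactant &rarr; instance &rarr; product), a
breadth-first search from each root along edge direction gives the
**downstream distance** of every reachable metabolite; the same search on
the reversed graph gives the **upstream distance**. Distances count
reactions traversed, root included: a direct reactant or product sits at
distance 1. Compartments are part of species identities, so paths conserve
compartment information automatically; only explicit transport reactions
connect compartments.

Distances become **signed dissipation weights**

$$w = \pm\,p^{\,d-1}, \qquad p \in [0,1],$$

positive downstream, negative upstream, starting at exactly 1 for direct
neighbours and decaying by a factor $p$ per additional reaction step
($0^0$ is taken as 1, so $p = 0$ keeps only direct neighbours). A
metabolite reachable in both directions — common in cycles — receives the
**unweighted arithmetic mean** of its two signed weights. The averaging
rule deserves emphasis because it determines cancellation: a metabolite at
distance 1 both ways (e.g. the transported species of a catalyzed
transporter) cancels to exactly 0, and with $p = 1$ every both-way
metabolite cancels. Averaging the signed values (rather than averaging
magnitudes and re-signing) was an open choice; the signed mean was adopted
because it is the only variant in which "equidistant both ways" means
"positionally uninformative", which is what the sign is supposed to
encode.

Footprints are reported at the level of compartment-free **base names**:
for each (root, base name) the minimal distance per direction across
compartment duplicates is kept *before* signing and averaging, with ties
broken lexicographically on species id and the winning species recorded
for provenance. Collapsing after signing would let a far-away duplicate's
sign leak into the report.

## Network reduction

Currency metabolites short-circuit every path (everything is two steps
from everything through ATP or water), so before graph construction the
filter removes, in one pass over the input network:

| rule | default | matching |
|---|---|---|
| cofactor/nucleotide class list | externally supplied file | species id *or* base name |
| explicit removals | CO2, ITP, IDP, NADH | base name |
| minimum size | < 4 atoms | parsed elemental formula |
| promiscuity | reactant degree > 100 | computed on the input network |

Species whose formula is missing or unparseable keep an `NA` atom count
and are never removed by the size rule — the conservative reading when no
treatment is specified. The promiscuity degree is computed once on the
input network, not iteratively: degrees can only shrink after removals, so
a single pass is also a fixed point (the test suite asserts idempotence
explicitly). A reaction that loses one entire side keeps the surviving
side: the filter targets metabolites, and a half-stripped reaction still
anchors its enzyme to the remaining species. The class list is an input
file rather than a bundled ontology snapshot; it accepts species ids or
base names because published cofactor lists mix both conventions.

## Metabolomics statistics

The differential input to a footprint is a per-metabolite t-value. The
chain is: QC relative-standard-deviation filter (drop metabolites with
RSD &ge; 30% across &ge; 2 pooled QC injections), total-ion-count
normalization (each sample divided by its total, rows sum to 1), log2
transform with a half-minimum pseudo-count, optional additive batch
regression, then an empirical-Bayes moderated two-group t.

The log2 transform is this package's choice (the variance-shrinkage model
needs roughly homoskedastic log-scale data; peak areas are multiplicative).
Batch correction fits per-metabolite least squares on group + batch
indicators and subtracts only the batch terms — group structure is
retained, and a batch confounded with the contrast is refused rather than
silently absorbed.

The moderated t shrinks each pooled variance $s_g^2$ ($d$ residual df)
toward a prior $s_0^2$ with prior df $d_0$:
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, with p-values on
$d_0 + d$ df. Hyperparameters come from closed-form moments of
$\log s_g^2$ (digamma/trigamma identities, Newton inversion of the
trigamma). Numerical edges: with fewer than 3 metabolites, or a failed
fit, $d_0 = 0$ (ordinary pooled t) with a warning; when the observed
spread of log-variances does not exceed sampling noise the prior becomes
infinitely strong and is anchored at the *pooled mean* of the $s_g^2$ —
unbiased for the common variance, and exact in the degenerate case where
every metabolite shows the same residual variance. The plain form is
implemented (no intensity trend, no robustness weights); the test suite
cross-checks t-values, p-values and both hyperparameters against limma on
random data. Benjamini–Hochberg adjustment is delegated to
`stats::p.adjust` behind a validated wrapper and tested against a literal
step-up oracle.

## Scoring and visualization

The footprint scatter places each measured metabolite at
(x = signed weight, y = t-value) with dot size $|t \times w|$, so
prominence requires being both deregulated and close. The x-axis
"weighted distance index" *is* the signed dissipation weight — the two
notions are the same number here. A measured name mapped to several
network species (co-eluting isomers) resolves to the minimum-distance
target. Multi-substrate reactions can be restricted to one conversion
channel by seeding the downstream search at a chosen direct product and/or
the upstream search at a direct reactant (`channel_forest()`); the
unseeded side keeps the full footprint.

The **imbalance score** $\sum_m w_m t_m / \sum_m |w_m|$ is a summary this
package adds for ranking enzymes; the scatter remains the primary
output. The score is linear in t, symmetric under footprint
reflection, and 0 when a footprint meets no measured metabolite.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `penalty` | 0.8 | dimensionless, [0, 1] | 20% weight drop per reaction step; deliberately mild so indirect neighbours stay visible. The value is a presentation choice, not a fitted quantity. |
| `min_atoms` | 4 | atoms, exclusive (< 4 removed) | removes protons, water, CO2-sized species |
| `max_promiscuity` | 100 | reactions (reactant degree) | currency-metabolite cutoff |
| `qc_rsd` threshold | 0.30 | fraction | standard LC-MS repeatability cutoff |
| contrast | `CASE - CTRL` | — | positive t = higher in cases |

## The synthetic generator

`fixture_spec()` / `make_network()` / `make_abundances()` produce
deterministic toy systems: chains, branches, cycles, a currency hub of
reactant degree 101, duplicated compartments with or without transport,
AND/OR rules, and seeded random networks. Abundances are log2-normal
(baseline mean 17, sd 1.5 across metabolites) with residual sd 0.25 log2
units and 5 samples per group — the scale of replicate spread and group
sizes in cell-line LC-MS work. QC injections sit at the pooled mean with a
fifth of the biological noise. A planted enzyme shifts the case group by
`effect_size × noise_sd × w(m)` per metabolite — the generator reuses the
scorer's own dissipation law, stated openly: parameter-recovery tests
close a loop on the implementation's internal consistency, not on an
independent physical model of metabolism. Fifty background metabolites
outside the network are included by default because real LC-MS panels are
dominated by species a curated network does not model; without them the
planted signal itself would move the total ion count and TIC normalization
would redistribute the effect compositionally.

What passing tests therefore show: the machinery recovers a signal that
propagates the way the weights assume, under Gaussian log-scale noise,
additive batch structure and honest QC behaviour. What they do not show:
performance under real metabolic regulation (allostery, mass-action
kinetics, fluxes that do not follow shortest paths), missing values,
heavy-tailed peak-area noise, or annotation error beyond the simple
many-to-one mapping exercised here.

## Determinism and problem sizes

Every output table is sorted with locale-independent byte ordering, JSON
keys are sorted, and the pipeline manifest records md5 checksums of inputs
and outputs — reruns are byte-identical, which the suite asserts. All
randomness flows through explicit seeds (R's default Mersenne-Twister via
`withr::with_seed`, so the global RNG state is never touched).

The shipped verification runs at deliberately desk-friendly sizes chosen
as the package's own test conditions: forest distances are checked against
a naive boolean matrix-power oracle on 200 random networks of 10–50
species; the moderated-t null calibration uses 1000 replicates of 200
metabolites at 4 samples per group (pooled rejection rate inside the 99%
binomial band around 0.05); planted-enzyme recovery uses 100 seeded
9-species chains at effect size 3 sd, requiring the planted root to top
the imbalance ranking in at least 95.

## Known limitations

- Stoichiometric coefficients are validated and carried but do not enter
  the graph: a doubled coefficient does not shorten or strengthen a path.
- Distances are shortest paths only; parallel routes, path multiplicity
  and flux magnitudes are invisible (no k-shortest paths, no flux
  weighting).
- One dissipation kernel (geometric decay) is provided.
- The filter's 421 &rarr; 321 metabolite count on the reduced human
  network it was designed around can only be reproduced with that external
  network file, which is not bundled; the filter's behaviour is instead
  pinned by its property suite and counting oracles on generated fixtures.
- Footprint enrichment p-values are out of scope; the imbalance score is
  a ranking device, not a calibrated test statistic.
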