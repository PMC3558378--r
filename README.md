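# perfectphylo

Decide whether a matrix of taxa scored on characters with **at most
three states** fits tree-like evolution under the infinite-alleles
model without recombination — and when it does, build the tree.

## The problem and who it is for

A *perfect phylogeny* for an `n × m` matrix `M` (taxa in rows,
characters in columns, no missing values) is a tree in which every
taxon labels a node, every leaf is taxon-labeled, and for every
character each state occupies a connected subtree (convexity; each
character mutates to each state only once).  For binary characters
this is the classic infinite-sites / four-gamete setting; for three
states, which arise in population-genetic and morphological data, the
decision and construction problems are still polynomial but need more
machinery.  This package is for researchers who want an exact,
certificate-producing implementation at desk-to-moderate scale, with
every structural claim cross-checked by brute-force oracles.

## The method

By Buneman's characterization, `M` admits a perfect phylogeny iff its
**partition intersection graph** `G(M)` — one vertex per character
state, colored by character, edges between states co-occurring in a
taxon — has a **proper triangulation**: a chordal supergraph whose
fill edges never join two states of one character.  The pipeline:

1. reject if any character pair induces a cycle in its two-color
   subgraph;
2. generate `Δ*`, the legal minimal separators with fewer than `m`
   vertices, from **proper clusters** (taxa bipartitions in which every
   character shares ≤ 1 state and some character shares none) — at
   most 3 candidates per character, never a subset search;
3. reject if some monochromatic vertex pair is separated by no member
   of `Δ*`;
4. compute the pairwise **parallel** relation through the taxa
   partitions in `O(n)` per pair;
5. greedily pick a maximal pairwise parallel family `Q` (`|Q| ≤ 2n−3`);
6. saturate each `S ∈ Q` into a clique, yielding a proper *minimal*
   triangulation;
7. read a Maximum Cardinality Search clique tree out as the phylogeny:
   each maximal clique spells a species, each taxon's row clique is its
   node.

Incompatibility is a verdict, not an error: you get a report naming
the failing step (1 or 3) and a concrete witness.

## Worked example

```r
library(perfectphylo)
fx <- pp_fixtures()
fx$F1$states
#>    c1 c2 c3
#> t1  0  0  1
#> t2  1  0  2
#> t3  1  1  0
#> t4  0  2  0

legal_minimal_separators(fx$F1)
#> pp_separator_set: 5 legal minimal separators
#>   {c0_s0, c1_s0}
#>   {c0_s0, c2_s0}
#>   {c0_s1, c1_s0}
#>   {c0_s1, c2_s0}
#>   {c1_s0, c2_s0}

construct_phylogeny(fx$F1)
#> perfect_phylogeny: 6 nodes, 4 taxa, 3 characters
#>   N0 (0,0,0)
#>   N1 (1,0,0)
#>   N2 (1,1,0) <- t3
#>   N3 (0,2,0) <- t4
#>   N4 (0,0,1) <- t1
#>   N5 (1,0,2) <- t2
```

The five separators are pairwise parallel, so all five are saturated
(adding the single forced fill edge `c1_s0–c2_s0`) and the clique tree
has six maximal cliques: the four taxon rows plus two inferred
(Steiner) species `(0,0,0)` and `(1,0,0)` — ancestral states never
observed in the data.  Five clique-tree edges carry exactly the five
separators: the `2n − 3` bound on minimal separators of a proper
minimal triangulation is tight at `n = 4`.  An incompatible input
instead returns, e.g.:

```r
construct_phylogeny(fx$F5)
#> incompatible (step 3): monochromatic pair {c0_s0, c0_s1} is separated
#> by no legal minimal separator
```

Command line (same pipeline, stable exit codes — 0 compatible, 3
incompatible, 1/2/4 usage/input/internal):

```sh
Rscript inst/cli/perfectphylo.R construct data.csv -o tree.nwk --labels nodes.tsv
Rscript inst/cli/perfectphylo.R verify data.csv tree.nwk nodes.tsv
```

## Synthetic data and oracles

`random_pp_matrix()` derives characters from a random tree (one edge
cut for binary, two for three-state characters), returning the matrix
*and* the generating phylogeny; `mstar_matrix(n)` builds the
caterpillar-interval family whose graph has ≥ `choose(n, 4)` edges —
compatible, but quadratic-size; `make_incompatible()` plants certified
step-1 or step-3 obstructions.  The `brute_*` functions are naive,
independent reference implementations (subset-scan separators,
simplicial-elimination chordality, chordless-cycle branching over
proper triangulations) used throughout the tests.

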