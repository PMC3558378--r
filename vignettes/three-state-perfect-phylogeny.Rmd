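---
title: "Constructing perfect phylogenies for three-state characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing perfect phylogenies for three-state characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfectphylo)
```

## The problem

An $n \times m$ matrix $M$ scores $n$ taxa on $m$ discrete characters,
each with at most $r = 3$ states and no missing values.  Under the
infinite-alleles model without recombination, the data fit evolution on
a tree exactly when $M$ admits a *perfect phylogeny*: a tree in which
every taxon labels a node, every leaf is taxon-labeled, every node
carries a species (missing entries `*` allowed on inferred nodes), and
each character state occupies a connected subtree (convexity).  For
$r \le 3$ the decision and construction problems are polynomial;
`perfectphylo` implements an $O(nm^2)$-style pipeline built on minimal
separators of the *partition intersection graph* and returns either a
verified tree or a two-part incompatibility certificate.

## The partition intersection graph

$G(M)$ has one vertex per realized character state, colored by
character, and an edge between two states that co-occur in a taxon, so
each taxon row induces an $m$-clique.  Buneman's theorem turns the
phylogeny question into a graph question: $M$ admits a perfect
phylogeny iff $G(M)$ has a *proper triangulation* — a chordal
supergraph whose added (fill) edges never join two states of one
character.  A phylogeny is then read off a clique tree of the
triangulated graph: each maximal clique spells a species (one state per
character present in the clique, missing otherwise), and each taxon's
row clique is itself a maximal clique, giving the taxon's node.

Two prior structural results carry the algorithm:

* a matrix over $\le 3$-state characters is compatible iff every
  character pair's two-color subgraph is acyclic **and** every
  monochromatic vertex pair is separated by some *legal* minimal
  separator (one containing at most one state per character);
* saturating any maximal pairwise parallel set $Q$ of minimal
  separators (completing each member into a clique) yields a minimal
  triangulation whose minimal separator set is exactly $Q$.

For compatible input the legal minimal separators of $G(M)$ coincide
with the minimal separators of the augmented graph $G'(M)$ obtained by
adding the forced chord of every three-color chordless 4-cycle
(F-edges), which is why illegal separators can be ignored wholesale.
`augmented_pig()` exists to test exactly this equivalence; the
construction path never builds $G'(M)$.

## The pipeline

`construct_phylogeny()` runs seven steps:

1. **Pair screen.**  Reject if any character pair induces a cycle
   (component-wise $|E| \ge |V|$ test on a $\le 6$-vertex graph).
2. **Separator generation.**  Enumerate *proper clusters*: taxa
   bipartitions in which every character shares at most one state
   across the split and some character shares none.  Candidates come
   from the $\le 3$ state-bipartitions of each character, never from a
   subset search.  A cluster's shared states (its splitting vector) are
   a candidate separator $S$; the *S-partition* of the taxa (union-find
   over the transitive relation "shares an off-$S$ state") yields the
   components of $G(M) - S$, and $S$ is kept iff at least two
   components are full.  This produces $\Delta^*$, the legal minimal
   separators with fewer than $m$ vertices, at most one per state-split
   per character.
3. **Monochromatic screen.**  Reject if some same-character vertex pair
   is separated by no member of $\Delta^*$.
4. **Crossing relation.**  $S \parallel S'$ iff some full component $C$
   of $G(M)-S$ has its taxa $t(C)$ inside a single part of the
   $S'$-partition — an $O(n)$ test on the stored partitions.
5. **Greedy family.**  Scan $\Delta^*$ in canonical order (or a seeded
   shuffle) keeping everything parallel to the current family.  Any
   maximal family works, so the order changes which tree is returned,
   never whether one is found; exceeding $2n-3$ members would signal an
   implementation bug and raises an internal error.
6. **Saturation.**  Fill each chosen separator into a clique.  Legality
   guarantees no monochromatic fill; the result is verified chordal.
7. **Clique tree.**  Maximum Cardinality Search in the Blair–Peyton
   formulation (ties broken by lowest vertex id, so output is
   deterministic): a new maximal clique opens when the visited-neighbor
   count stops growing, attaches to the clique of the most recently
   visited boundary vertex, and the edge intersections are exactly the
   minimal separators of the triangulation.  The tree is read out as a
   phylogeny and re-checked by `verify_phylogeny()` before being
   returned.

Incompatibility is a *verdict*, not an error: the CLI maps it to exit
code 3 and a JSON report naming the failing step and a witness.

```{r}
fx <- pp_fixtures()
construct_phylogeny(fx$F1)
construct_phylogeny(fx$F5)
```

## Design decisions

**Canonical states.**  Each column's states must be $\{0,\dots,k-1\}$,
$k \le 3$.  A column already written that way is kept verbatim; any
other symbols (letters, gapped integers) are recoded in order of first
appearance down the column.  Keeping already-canonical digit columns
verbatim makes `read`/`write` a strict round trip and keeps the
packaged fixtures exactly as documented.  Canonicalization is
idempotent.

**Missing values are rejected.**  Every correctness argument above
assumes fully observed taxa; imputation would silently change the
instance.  The missing marker appears only on *output* species, where
a character absent from a clique is reported as `*`, never guessed.

**Constant characters** carry no signal and are dropped with a warning
— except when *all* characters are constant (e.g. a single-taxon
matrix), where the degenerate instance is kept whole and resolves to a
one-node phylogeny.  Dropping everything would otherwise erase a
perfectly well-posed input.

**Duplicates.**  Duplicate taxa map to the same node and are listed
together; duplicate characters are kept (they only duplicate colors)
unless `dedupe_characters()` / `--dedupe` is asked for.

**The empty separator** is admitted when $G(M)$ is disconnected: it is
legal, smaller than $m$, and has $\ge 2$ full components.  Saturating
it is a no-op and the clique-tree stage joins the resulting forest with
edges between the lexicographically smallest cliques of each component,
flagged `artificial` in the output — cross-component states never
conflict, so convexity survives any joining.

**Degree-two Steiner nodes are not suppressed.**  The clique tree is
returned as-is; resolving or collapsing inferred nodes is presentation,
and `ape::collapse.singles()` is available downstream via `as_phylo()`.

**Ties and reproducibility.**  $\Delta^*$ is stored sorted by vertex
tuples; MCS breaks ties by lowest vertex id; the greedy order is the
canonical order unless a seed is given.  Identical input plus seed
gives byte-identical output.

## Synthetic data: what it emulates and what it does not

`random_pp_matrix(n, m, three_state_fraction, seed)` draws a uniform
random unrooted binary topology (leaves attached to a uniformly chosen
edge one at a time) and derives characters the only way a compatible
character can arise: a binary character cuts one edge, a three-state
character cuts two, and each resulting subtree is a state.  Draws are
redone until all three subtrees contain a leaf so the requested arity
is realized among the taxa.  Defaults (`three_state_fraction = 0.5`,
$n \le 12$, $m \le 30$ in the test battery) keep instances in the
regime where the brute-force oracles can certify answers.  The
generator produces *clean* data only: no homoplasy, no missing entries,
no rate heterogeneity, no branch lengths.  A green end-to-end test
therefore establishes correctness of the combinatorial pipeline on
tree-derived data, not robustness to real noisy alignments — real data
failing these assumptions is rejected, not repaired.

`mstar_matrix(n)` builds the caterpillar-interval family: one
three-state character per pair $1 \le i < j < n$ with taxa intervals
$[1,i]$, $[i+1,j]$, $[j+1,n]$ as cells.  It is compatible by
construction yet its graph has at least $\binom{n}{4}$ edges — the
worst case showing that any method reading all of $G(M)$ pays
$\Omega(m^2)$.  `make_incompatible()` plants either a four-gamete
character pair (step-1 rejection) or a five-cycle pattern whose pairs
are all acyclic (step-3 rejection), padded by row duplication, which
cannot remove an obstruction.

## Oracles and numerical choices

The `brute_*` functions are deliberately naive, independent
re-implementations used by the tests: subset-scan minimal separators
(definitional, $\le 20$ vertices), a neighborhood-expansion enumerator
for larger graphs (every candidate re-certified by the two-full-
components test), chordality by simplicial elimination (distinct from
the MCS test on the main path, and cross-checked against igraph), and
proper-triangulation enumeration by branching over the legal chords of
chordless cycles, with inclusion-minimality certified by single-edge
removal.  The decision oracle uses the literal all-subsets definition
up to 12 candidate fill edges and the branching search beyond, where
the subset scan would be infeasible; the two are tested for agreement
wherever both run.  Hard size guards raise explicit errors rather than
running silently for hours.

The exhaustive four-taxon audit enumerates all $2^{13}-1$ subsets of
the 13 distinct non-constant columns on four taxa (duplicate columns
are omitted: they change neither verdicts nor separator counts), runs
the full pipeline and all oracles on each, and confirms among other
things that the $2n-3$ bound on minimal separators of a proper minimal
triangulation is attained: the maximum over the family is exactly 5.

## Limitations

* No support for $r \ge 4$ states (the monochromatic-separation
  characterization genuinely fails there), for missing values, or for
  sequence-format input; characters are abstract columns.
* The phylogeny returned is *a* valid one, not canonical: different
  greedy orders give different (all correct) trees, and no optimization
  over Steiner nodes is attempted.
* Oracles and the exhaustive audit are desk-scale tools; the main
  pipeline itself is polynomial but the package is written for clarity
  at small-to-moderate sizes, not for genome-scale matrices.
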