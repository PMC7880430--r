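---
title: "Branched metabolic pathway search by atom group tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branched metabolic pathway search by atom group tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agtpath)
```

## The problem

Graph-based pathfinding in metabolic networks tends to route through hub
metabolites: water, ATP or CoA connect thousands of reactions, so the
shortest connectivity path between two compounds is rarely a chemically
meaningful transformation. Atom-group tracking suppresses such routes by
demanding that every compound on a pathway retain a *conserved atom
group* — a connected set of covalently bonded atoms — traceable to the
source compound through the atom mappings of the traversed reactions.

Linear pathways are only half the picture. Real pathways branch: several
chains split from and rejoin at *branched compounds*. `agtpath`
enumerates linear atom-group-conserving pathways and then merges them at
branched compounds, classifying each merge by the bond structure of the
conserved groups at the branch point.

## Data model

A compound is a labelled graph: atoms carry element symbols, bonds are
untyped and undirected, and hydrogens are absent (atom-mapped
reactant-pair data of the kind modelled here is heavy-atom based; the
conservation test never consults bond order). A *reactant pair* is a
substrate/product pair within one reaction, annotated with a partial
injective atom mapping, an optional Gibbs free-energy change, and a
reversibility flag. By default pairs are traversable in both directions,
with the inverse mapping on the reverse edge: reaction databases
typically write reactions without a committed direction, and nothing in
the conservation test is direction-specific. The flag can be overridden
per record and, in the command-line front end, globally
(`--irreversible`). Parallel reactions between the same compound pair
are kept distinct, keyed by reaction id.

## Conserved atom groups

For a reactant pair with substrate adjacency matrix $MA$, product
adjacency matrix $MB$ and 0/1 mapping matrix $M$, the candidate
mapped-edge matrix is

$$MC = M\,(M\,MB)'$$

evaluated over Boolean semantics (any entry $\ge 1$ becomes 1):
$MC[u,v]=1$ exactly when the images of substrate atoms $u$ and $v$ are
adjacent in the product. A substrate bond $(u,v)$ is *conserved* when
additionally $MA[u,v]=1$ and both endpoints are mapped. The connected
components of the conserved bonds are the atom groups transferred by the
step. Two deliberate consequences:

* a **single mapped atom with no conserved incident bond is not an atom
  group** — the minimal atom group is one bond with its two atoms; this
  is exactly the property the decoy reactions of the synthetic generator
  probe;
* groups and bonds are kept in a deterministic order (lexicographic by
  atom index) so that serialized output is stable.

Along a multi-step path, conservation is propagated *stepwise*: a source
bond survives step $i$ if its current image is a conserved bond of that
step's pair, and its image then advances through the step's mapping.
This is stricter than testing source-against-target only, and it is what
the branch-merging stage needs: every intermediate compound carries its
correct conserved groups. Survival is monotone — the conserved bond
count can only decrease along a path.

## Linear search

Candidate routes are the top-$k$ shortest simple paths over the directed
reactant-pair edges, "shortest" meaning fewest reaction steps (no edge
weighting is applied at this stage). The enumeration is best-first over
partial simple paths with a total order: path length first, then the
interleaved compound/reaction sequence lexicographically. Any
enumeration honouring that order contract would be acceptable; the
best-first scheme was chosen because it emits paths lazily in exactly
the contract order. Paths are compound-simple (no repeated compounds),
matching the acyclic linear pathways the method composes, and
`max_path_len` (default 12 reactions) bounds the enumeration on dense
networks. A path is retained when at least `min_groups` conserved bonds
reach the target; the filter applies at the target only, since a path
whose conservation dies at an intermediate can never conserve anything
at the target.

## Merging rules

At every *candidate branched compound* — a compound contained in at
least two linear pathways, excluding source and target — the pathways
carrying conserved bonds there are classified in search-rank order. A
running overlap set is seeded from the first consecutive pair of
pathways and intersected with each member that shares a bond with it;
members sharing no bond go to the non-overlapping side. The compound
qualifies as *overlapping* if the running overlap is non-empty with more
than one overlap member, and as *non-overlapping* if more than one
member landed on the disjoint side.

Three design points deserve explicit statement:

* **Overlap is defined at bond granularity.** Two conserved-group sets
  overlap iff they share at least one bond of the branched compound;
  sharing atoms without a shared bond counts as non-overlapping. This
  matches the published examples, which identify overlaps by shared
  bonds.
* **The classification is order-dependent** (the running overlap is
  seeded from consecutive pathways). Whether a symmetric all-pairs
  variant was intended is not decidable from the published pseudocode,
  so the pseudocode is followed literally, with the input fixed to
  search-rank order. The sensitivity is confined to networks where three
  or more pathways meet at one compound with partially overlapping
  groups.
* **Combinations of branched compounds merge by union of their member
  pathways.** The published procedure enumerates combinations of
  qualifying compounds but does not state how members combine when a
  combination has several compounds; union is used, each chosen
  compound remaining branched (contained in at least two members) in the
  merged result. Enumeration is capped (`max_combo_size`, default 3;
  `max_results`, default 10000) because the combinatorial growth is
  real. Duplicates under canonical member-set equality are dropped,
  keeping the smallest qualifying compound combination.

## Scoring

A linear pathway $p$ with reactions $r_1..r_{l_c}$ joining consecutive
compounds $(v_i, v_j)$ scores

$$\mathrm{Score}(p) = \alpha_s \sum \mathrm{sim}(v_i, v_j)
  \;-\; \alpha_{sf} \sum \frac{3200 + \Delta G_r(r_i)}{10000}
  \;+\; \alpha_t \, \frac{t}{e}$$

* $\mathrm{sim}$ is a compound similarity in $[0,1]$, evaluated on the
  consecutive pathway compounds joined by each reaction. The built-in
  provider is an exhaustive maximum-common-edge-subgraph Tanimoto,
  $|mcs| / (|b_a| + |b_b| - |mcs|)$, exact for fixture-scale compounds
  (roughly up to a dozen atoms; the maximum clique underneath is
  exponential in the worst case). For larger molecules a precomputed
  similarity table (`similarity_table()`, TSV-readable) is the drop-in
  provider; scores from different providers are not comparable across
  runs. Degenerate inputs are pinned: bond-less versus bonded scores 0,
  two bond-less compounds score 1 iff their element multisets match.
* $\Delta G_r$ is the reaction Gibbs free-energy change. The affine
  normalization $(3200 + \Delta G_r)/10^4$ maps the tabulated range
  $[-2233.7,\,10194.7]$ into $[0.097, 1.339]$, commensurate with the
  similarity term. A reaction's own value takes precedence, then a
  user-supplied table, then the default 0 (normalized 0.32, mid-scale) —
  the choice for missing thermodynamic data had to be made here and
  mid-scale is the least informative prior.
* $t$ is the number of minimal atom groups (conserved bonds) at the
  target and $e$ the source bond count, so $t/e \in [0,1]$. A source
  compound without bonds cannot be scored (error, not silent 0): $t/e$
  is undefined and such a source cannot conserve any atom group anyway.

A branched pathway with $n_b$ branched compounds and members
$p_1..p_{l_b}$ scores
$\alpha_p n_b + (1 - \alpha_p)\,\overline{\mathrm{Score}(p_i)}$.
Results are ranked by descending score with deterministic tie-breaking
(fewer total reactions, then canonical serialization).

Defaults ($\alpha_s, \alpha_{sf}, \alpha_t, \alpha_p$) =
(0.1, 0.2, 0.2, 0.8), $k = 2000$, `min_groups` = 2 — the method's
standard evaluation settings. All weights live in $[0,1]$ and are
dimensionless. Floating-point comparisons in the test suite use absolute
tolerance $10^{-9}$.

## Comparison metrics

Computed and known pathways are compared as directed bipartite graphs
(compound and reaction nodes, edges substrate→reaction→product). Seven
metrics are produced: `R_ELCCS` plus sensitivity / positive predictive
value / accuracy over compounds and over reactions.

* **Labelled intersection, not isomorphism search.** Both pathways live
  in the same compound/reaction namespace, so the largest common
  connected sub-graph reduces to the largest connected component of the
  label-matched edge intersection. Connectivity is judged on the
  undirected skeleton — pathway DAGs are rarely strongly connected, and
  nothing in the metric's definition demands strong connectivity.
* **Order consistency for branched topologies** is operationalized as
  pairwise precedence under directed reachability restricted to shared
  nodes: a shared node is a true positive iff its reachability pattern
  against every other shared node of its kind agrees in both pathways.
  The published definition covers linear pathways only; this reading
  reduces to it on chains and is symmetric, which yields the expected
  Sn↔PPV swap when computed and known are exchanged.
* Zero denominators (no shared nodes) yield metric 0, not an error.

## The synthetic data generator

`generate_network()` builds networks in which the correct answer is
known by construction. The source compound is a chain backbone (8–12
heavy atoms by default, alphabet C/N/O/P/S) with random extra bonds;
every compound on a planted route is a structural copy of it, and every
planted step maps a contiguous atom run identically. Runs that share
atoms share chain bonds (overlapping mode: all runs contain a common
2-bond core) and atom-disjoint runs are bond-disjoint (non-overlapping
mode), so the conserved-group structure at the planted branch compound
is exactly controllable. Mixed mode plants an overlapping pair plus
bond-disjoint extra routes. Decoy reactions map only pairwise
non-adjacent atoms onward — no bonded pair survives, a direct probe of
the one-conserved-bond group definition — and filler compounds pad the
network. Reaction free-energy changes are drawn from N(0, 25²), small
values typical of central metabolism.

Planted route steps are written **directed**, while decoy and filler
pairs stay reversible. The figure-style constructions the generator
emulates are directed chains; traversing planted steps backwards would
only manufacture crossover routes through the branch compound, blurring
the planted ground truth that the generator exists to provide. (Forward
crossovers — first half of one route, second half of another — still
arise and are legitimate conserving pathways; in overlapping mode they
carry the shared core.)

What the generator deliberately does **not** emulate: chemistry
(valence, aromaticity, stereochemistry), realistic compound-size
distributions, hub metabolites with thousands of incident reactions,
and atom mappings that rearrange rather than preserve indices. Passing
the recovery tests therefore demonstrates the correctness of the
tracking/merging/scoring machinery, not performance on a real reaction
database.

`fig_branch_fixture()` complements the generator with two fixed,
hand-coded networks realizing the canonical overlapping
(shared bonds e5, e6 at `bn1`) and non-overlapping (`{e3, e4}` versus
the single bond `e1` at `bn2`) configurations on an 8-atom chain.

## Problem sizes and determinism

The test suite validates the matrix conservation test against exhaustive
brute-force enumeration on 500 random reactant pairs (up to 7 atoms per
compound), the path enumeration against exhaustive DFS on random
12-compound networks, the similarity backend against an independent
backtracking MCS enumerator on graphs of up to 6 atoms, and end-to-end
recovery (a top-5 result with `R_ELCCS` = 1 against ground truth) on 50
seeded fixtures across both overlap modes. These sizes were chosen so
the oracles stay exact while exercising every code path; all randomness
is seed-controlled, and `generate_network()` restores the caller's RNG
state.

## Limitations

* The merge stage inherits the published procedure's order dependence at
  branch compounds with three or more partially overlapping pathways.
* The built-in similarity is exact MCS, exponential in the worst case;
  large compounds need a precomputed similarity table.
* Combination enumeration over branched compounds is capped; on networks
  with many qualifying branch compounds the result set is a deterministic
  prefix, not the full set.
* Single-source, single-target queries only; multi-source or
  multi-target search and stoichiometric balancing are out of scope.
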