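---
title: "Worst-case Robinson-Foulds distances for fixed topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worst-case Robinson-Foulds distances for fixed topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfbound)
```

## Model and definitions

A *topological tree* is an unlabeled tree shape; a *phylogenetic tree*
adds a bijection between its $n$ leaves and the label set
$\{1, \dots, n\}$ (taxa).  An edge touching no leaf is an *internal
edge*; $m$ counts them.  An internal node of degree 2 is a
*unifurcation*; $k$ counts them.  A tree is *proper* when $k = 0$, i.e.
every internal node has degree $\ge 3$.  The root of a rooted tree is
exempt: it needs degree $\ge 2$ and is never counted as internal, so a
rooted tree produced by subdividing an edge of an unrooted tree (the
standard rooting operation, `root_on_edge()`) is still proper.

Cutting an internal edge of an unrooted tree partitions the labels in
two; the set $P(T)$ of non-trivial bipartitions (both sides of size
$\ge 2$) characterizes the tree's resolved structure.  The **tree
partition distance** is $d(T_1, T_2) = |P(T_1) \,\triangle\, P(T_2)|$.
For rooted trees the analogous object is the set $Cl(T)$ of non-trivial
clusters (leaf-label sets below internal nodes, sizes in $[2, n-1]$) and
the **cluster distance** $d_r = |Cl(T_1) \,\triangle\, Cl(T_2)|$.  The
**unrooted cluster distance** between an unrooted $T_1$ and a rooted
$T_2$ is $d_{ur}(T_1, T_2) = \min_e d_r(T_{1,e}, T_2)$ over all edges
$e$ of $T_1$, leaf edges included.

All three are purely topological: branch lengths in Newick input are
parsed and discarded with a notice.

## The exact worst-case bound

For fixed topologies, every internal edge contributes at most one
bipartition, and the two edges flanking a unifurcation contribute the
same one, so $d \le (m_1 - k_1) + (m_2 - k_2)$, and likewise for $d_r$.
The package's central result is that this bound is *strict* for TPD and
CD: labelings attaining it always exist, and `construct_unrooted()` /
`construct_rooted()` build them.

The construction is inductive on $n$.  Unifurcation chains are first
contracted away (`suppress_degree_two()`), which changes neither the
split/cluster sets nor the leaves, so labels found for the proper tree
transfer back verbatim.  On proper trees, each step removes one leaf
from both trees and assigns it the current largest label:

* if either tree is a star (no internal edge), any labeling works,
  because distinct internal edges of a proper tree always induce
  distinct bipartitions (asserted by the test suite, not assumed);
* if both trees have an internal node with $\ge 3$ leaf neighbours,
  one such leaf is deleted from each ($m$ unchanged);
* otherwise some tree has every internal node touching $\le 2$ leaves;
  it then owns a two-leaf cherry whose parent has exactly one other
  neighbour, and the cherry is contracted ($m$ drops by 1).  When both
  trees are contracted this way, the two kept cherry leaves may carry
  the same label; the collision is repaired by swapping with a second
  leaf under the same anchor when one exists, and otherwise by
  exchanging the labels $n$ and $k$ (the smallest label different from
  the colliding one) in the first tree.

Every "choose a node" step picks the smallest node id, so the output is
deterministic.  Node ids never change during deletion/contraction, which
is what lets labels assigned deep in the recursion land on the correct
original leaves.  The returned object stores the bound, the two labeled
trees, and the distance recomputed from them; a mismatch between the two
would be an internal error, and `verify_worst_case()` re-runs the check
on demand.

In the rooted base case $n = 3$ with a cherry in both trees, the
cherries receive labels $\{1,2\}$ and $\{1,3\}$, giving cluster distance
$2 = m_1 + m_2$.

The brute-force oracle (`brute_force_max()`) certifies all of this
independently: it fixes one tree's labeling (distances are invariant
under relabeling both trees together, a property the suite tests) and
enumerates all $n!$ labelings of the other.  `worst_case_sweep()` runs
the oracle, the formula, and the construction over every ordered pair of
enumerated shapes.  The suite sweeps unrooted pairs for
$n \in \{3,\dots,6\}$ and rooted pairs for $n \in \{3,4,5\}$, plus
shapes with one or two inserted unifurcations at $n \le 5$; these sizes
keep the factorial oracle at desk scale while covering every shape
class the induction distinguishes.

## The unrooted cluster distance is different

One might expect $\max d_{ur} = (m_1 - k_1) + (m_2 - k_2)$ as well,
via the rooted result applied to a rooting of $T_1$.  But rooting on
*any* edge of $T_1$ — internal or leaf edge — creates one additional
internal edge in the rooted copy, so each individual rooting obeys the
*larger* bound $(m_1 + 1 - k_1) + (m_2 - k_2)$, and the minimum over
rootings can also dip below the nominal formula.  Both failure modes are
real.  At $n = 3$:

* unrooted star vs. rooted star: every rooting of the star yields
  exactly one non-trivial cluster while the rooted star has none, so
  $d_{ur} = 1$ for every labeling — one *above* the formula value 0;
* unrooted star vs. rooted cherry: rooting the star on the leaf edge
  of the label missing from the cherry reproduces the cherry's cluster
  set exactly, so $d_{ur} = 0$ for every labeling — one *below* the
  formula value 1.

The exhaustive sweep at $n \in \{3,4,5\}$ finds that the true maximum
of $d_{ur}$ differs from the formula by exactly one on *every* proper
shape pair, in one direction or the other.  `exact_bound(..., "urcd")`
therefore returns the formula as a nominal value, `construct_urcd()`
reports the distance its labeling actually achieves together with an
`achieves_bound` flag (and a warning when they differ), and the oracle
is the arbiter.  Normalized urCD values use the nominal divisor and may
be `NA` when it is 0 but the distance is not.

`construct_urcd()` roots $T_1$ on its lexicographically smallest edge
and reuses the rooted construction; in the sweeps above the resulting
labeling attains the true brute-force maximum on every pair, but no
proof of that is claimed.

## Generators and what they do (not) emulate

`random_topology(n, rooted, resolution, k, seed)` grows a uniform
binary shape by sequential leaf attachment (each new leaf subdivides an
edge chosen uniformly), then contracts a uniformly chosen
$(1 - \text{resolution})$ fraction of internal edges into
multifurcations, then inserts `k` unifurcations by subdividing uniformly
chosen edges, leaf edges included — the bound places no restriction on
where degree-2 nodes sit, so neither does the generator.  Defaults
(`resolution = 1`, `k = 0`) produce the fully resolved proper trees that
dominate practice; test sweeps vary resolution over $[0.3, 1]$ and
$k \in \{0,1,2,3\}$ to cover partially resolved and improper inputs.
The generator emulates tree *shapes* only: it has no model of branch
lengths, no taxon-sampling bias, and no correlation between the two
trees of a pair (real tree pairs from co-phylogenetic studies are
typically much closer than random pairs).  Passing tests therefore
certify combinatorial correctness of the distances and bounds, not any
statement about the distribution of real phylogenies.

`enumerate_topologies()` yields one representative per isomorphism
class (AHU canonical-form deduplication, minimized over rootings for
unrooted shapes), growing shapes recursively by leaf attachment and
edge subdivision; a count argument inserts unifurcations in every
distinct way.  The default cap of $n \le 7$ reflects the factorial
growth of the oracle that consumes these shapes.

## Numerical and interface choices

* All quantities are integer counts; there are no tolerances.  Ratios
  (normalized distances) are exact machine doubles of small integer
  fractions.
* Newick reading is lossless: single-child clauses, including a
  top-level bifurcation read in unrooted mode, become degree-2 nodes
  and are reported in $k$ rather than silently suppressed.  Because
  $m - k$ is invariant under suppression, distances and bounds do not
  depend on this choice; only the reported shape statistics do.
* A bipartition is stored canonically as the side containing label 1
  (sorted, comma-joined); a cluster as its sorted label list.  Sets,
  not multisets: duplicates from unifurcation chains merge, which is
  what makes the $m - k$ counting exact.
* Two trees that both carry taxon names are aligned by name before any
  distance; differing name sets are an error, never silently pruned.
  Trees without names are compared by their numeric labels.
* Ties everywhere (edge choice in `urcd`, node choices in the
  construction, the rooting edge in `construct_urcd`) break towards the
  smallest id, so every output is reproducible.
* The 0/0 case (two star topologies) normalizes to 0 by convention,
  with a notice: the trees are indistinguishable at the split level.
* `randomized_bound()` draws each repetition from a counter-based seed
  (`seed + rep`), so the maximum over `reps` repetitions is a prefix of
  any longer run and is nondecreasing in `reps`.  Only the second
  tree is relabeled.  The suite observes that a single random
  relabeling already falls strictly short of the exact bound on a
  visible fraction of random pairs — the case for computing the bound
  exactly — while the dominance `randomized_bound <= exact_bound` holds
  always.  (Because the divisor can undershoot the observed distance,
  a randomized-scheme normalized value is not guaranteed to stay
  $\le 1$; the exact and classic schemes are.)

## Limitations

* Weighted (branch-length-aware) Robinson-Foulds variants, generalized
  distances for partially overlapping taxon sets, consensus/compatibility
  computations, and tree networks are out of scope.
* The oracle is a plain $n!$ enumeration capped at $n = 8$; it is a
  correctness arbiter, not a tool for large trees.
* The urCD worst case is characterized empirically at small $n$ (always
  one off the nominal formula); the package deliberately reports both
  values rather than hard-coding a corrected formula that has only been
  verified at $n \le 5$.
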