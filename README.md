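# rfbound

Exact worst-case bounds and normalization for Robinson–Foulds-type
distances between phylogenetic trees.

## The problem

The Robinson–Foulds distance is the standard way to compare two
phylogenetic trees on the same taxa: for unrooted trees it is the **tree
partition distance** (TPD), the size of the symmetric difference between
the two sets of non-trivial bipartitions induced by cutting internal
edges; for rooted trees it is the **cluster distance** (CD), the symmetric
difference between the sets of non-trivial clusters (the taxa below each
internal node); and an unrooted tree can be compared with a rooted one by
the **unrooted cluster distance** (urCD), the minimum CD over all rootings
of the unrooted tree.

To compare distances across trees of different sizes the raw value is
normalized by a worst case.  The classical divisor 2*n* − 6 is the worst
case over *all* topologies with *n* leaves, which overstates what two
specific tree shapes can achieve — a star can never be far from anything.
The topology-aware normalization instead divides by

> *w*(*T*₁, *T*₂) = (*m*₁ − *k*₁) + (*m*₂ − *k*₂),

the strict worst case over all joint leaf labelings of the two *fixed*
topologies, where *m*ᵢ is the number of internal edges of tree *i* and
*k*ᵢ its number of degree-2 internal nodes.  Software that uses this
normalization has had to approximate *w* by taking the maximum distance
over many random relabelings.  `rfbound` computes *w* exactly, constructs
a pair of labelings that attains it (the bound is strict for TPD and CD),
and ships a brute-force oracle that certifies both claims exhaustively for
small trees.

For urCD the same expression is the nominal bound, but it is **not**
exact: rooting any edge adds one internal edge to the rooted copy, and the
exhaustive oracle shows that at small *n* the true maximum of the
min-over-rootings distance is always one off the formula, in either
direction.  The package reports both numbers rather than guessing; see the
vignette (`vignettes/worst-case-bounds.Rmd`).

## Worked example

```r
library(rfbound)
t1 <- read_newick(text = "((A,B),C,(D,(E,F)));")
t2 <- read_newick(text = "((A,C),B,(E,(D,F)));")

tpd(t1, t2)
#> [1] 4
normalized_distance(t1, t2, "tpd")
#> Normalized tpd (exact scheme): 4 / 6 = 0.6666667

res <- construct_unrooted(t1, t2)
res
#> Worst-case tpd for fixed topologies (n = 6)
#>   tree 1: m = 3, k = 0
#>   tree 2: m = 3, k = 0
#>   bound = 6, achieved = 6
write_newick(res$tree1)
#> [1] "((t6,t2),t5,(t4,(t1,t3)));"
```

The two input trees disagree on 4 of their 3 + 3 internal-edge
bipartitions, so the raw TPD is 4.  Both shapes are fully resolved with 6
leaves, so the worst case for these topologies is (3 − 0) + (3 − 0) = 6
(here equal to 2*n* − 6 because both trees are binary), and the normalized
distance is 4/6.  `construct_unrooted` returns leaf labelings of the two
shapes whose TPD is exactly the bound, verified by recomputation.

A command-line front end with `distance`, `bound`, `construct`,
`normalize`, `brute` and `simulate` subcommands is installed as
`exec/rfbound`:

```sh
Rscript exec/rfbound bound --mode tpd tree1.nwk tree2.nwk
```

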