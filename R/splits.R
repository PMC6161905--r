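## Leaf-id sets "below" each node when the tree is traversed from `start`.
## Returns a list indexed by node id (NULL for unvisited/inactive).
below_sets <- function(adj, start, value = seq_along(adj)) {
  out <- vector("list", length(adj))
  rec <- function(v, parent) {
    ch <- setdiff(adj[[v]], parent)
    if (!length(ch)) {
      out[[v]] <<- v
      return(v)
    }
    got <- sort(unlist(lapply(ch, function(w) rec(w, v)), use.names = FALSE))
    out[[v]] <<- got
    got
  }
  rec(start, 0L)
  out
}

## canonical key of a bipartition given one side's labels: the side holding
## label 1, sorted and comma-joined
split_key <- function(side, n) {
  if (!(1L %in% side)) side <- setdiff(seq_len(n), side)
  paste(sort(side), collapse = ",")
}

cluster_key <- function(labels) paste(sort(labels), collapse = ",")

## Non-trivial bipartitions as sets of leaf *ids* (one side per partition,
## the side away from the traversal start), duplicates from degree-2 chains
## merged.  Labeling-independent; used by the oracle.
bip_leaf_sides <- function(x) {
  adj <- x$adj
  deg <- lengths(adj)
  leaves <- which(deg == 1L)
  n <- length(leaves)
  start <- which(deg > 1L)[[1L]]
  below <- below_sets(adj, start)
  e <- tree_edges(x)
  sides <- list()
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1L]; b <- e[i, 2L]
    if (deg[a] == 1L || deg[b] == 1L) next
    ## the child side is whichever below-set does not contain `start`'s set
    side <- if (length(below[[a]]) < length(below[[b]])) below[[a]] else below[[b]]
    if (length(side) < 2L || length(side) > n - 2L) next
    sides[[length(sides) + 1L]] <- side
  }
  unique(sides)
}

## Non-trivial clusters as sets of leaf ids (internal nodes only, root and
## leaves excluded), duplicates merged.
cluster_leaf_sets <- function(x) {
  adj <- x$adj
  deg <- lengths(adj)
  n <- sum(deg == 1L)
  below <- below_sets(adj, x$root)
  keep <- which(deg > 1L)
  keep <- setdiff(keep, x$root)
  sets <- lapply(keep, function(v) below[[v]])
  sets <- Filter(function(s) length(s) >= 2L && length(s) <= n - 1L, sets)
  unique(sets)
}

leafset_to_labels <- function(sets, labels) {
  lapply(sets, function(s) labels[s])
}

#' Non-trivial bipartitions of an unrooted phylogenetic tree
#'
#' Cutting an internal edge splits the label set in two; the set of all
#' such non-trivial two-set partitions (both sides of size >= 2) is what
#' the tree partition distance compares.  Partitions repeated along
#' degree-2 chains are merged, so a tree with `m` internal edges and `k`
#' degree-2 internal nodes has exactly `m - k` bipartitions.
#'
#' @param x an unrooted, labeled [rftree].
#' @return A sorted character vector of canonical bipartition keys: each
#'   key is the side containing label 1, sorted and comma-joined.
#' @examples
#' q <- read_newick(text = "((A,B),(C,D));")
#' bipartitions(q)
#' @export
bipartitions <- function(x) {
  if (x$rooted) stop_rf("bipartitions need an unrooted tree", "rf_usage")
  if (!is_labeled(x)) stop_rf("tree has no labels; see label_canonical()",
                              "rf_usage")
  n <- length(tree_leaves(x))
  sides <- leafset_to_labels(bip_leaf_sides(x), x$labels)
  sort(unique(vapply(sides, split_key, "", n = n)))
}

#' Non-trivial clusters of a rooted phylogenetic tree
#'
#' The cluster of a node is the set of labels below it.  Leaves give
#' singletons and the root gives the whole label set; the non-trivial
#' clusters are those of the internal nodes, with sizes in `[2, n - 1]`.
#' Clusters repeated along degree-2 chains are merged.
#'
#' @param x a rooted, labeled [rftree].
#' @return A sorted character vector of canonical cluster keys (sorted
#'   labels, comma-joined).
#' @export
clusters <- function(x) {
  if (!x$rooted) stop_rf("clusters need a rooted tree", "rf_usage")
  if (!is_labeled(x)) stop_rf("tree has no labels; see label_canonical()",
                              "rf_usage")
  sets <- leafset_to_labels(cluster_leaf_sets(x), x$labels)
  sort(unique(vapply(sets, cluster_key, "")))
}
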