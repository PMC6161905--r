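#' Structural statistics of a tree
#'
#' Computes the quantities the worst-case bound is built from: the leaf
#' count `n`, the number `m` of internal edges (edges incident to no leaf),
#' the number `k` of internal nodes of degree exactly 2, and whether the
#' tree is *proper* (`k == 0`, i.e. every internal node has degree >= 3).
#' The root of a rooted tree is not an internal node: it is excluded from
#' `k` and only needs degree >= 2, but edges between the root and other
#' non-leaf nodes do count as internal edges.
#'
#' @param x an [rftree].
#' @return A list with components `n`, `m`, `k`, `proper`.
#' @export
shape_stats <- function(x) {
  deg <- lengths(x$adj)
  leaf <- deg == 1L
  e <- tree_edges(x)
  m <- sum(!leaf[e[, 1L]] & !leaf[e[, 2L]])
  internal <- !leaf
  if (x$rooted) internal[x$root] <- FALSE
  k <- sum(deg[internal] == 2L)
  structure(list(n = sum(leaf), m = as.integer(m), k = as.integer(k),
                 proper = k == 0L),
            class = "rf_shape_stats")
}

#' @export
print.rf_shape_stats <- function(x, ...) {
  cat(sprintf("n = %d, m = %d, k = %d, proper = %s\n",
              x$n, x$m, x$k, x$proper))
  invisible(x)
}

## Mask-based suppression used inside the worst-case construction: node ids
## stay stable, removed nodes are deactivated.  The root of a rooted tree is
## never suppressed.
suppress_mask <- function(adj, act, root = NA_integer_) {
  repeat {
    deg <- lengths(adj)
    cand <- which(act & deg == 2L)
    if (!is.na(root)) cand <- setdiff(cand, root)
    if (!length(cand)) break
    v <- cand[[1L]]
    ab <- adj[[v]]
    adj[[ab[1L]]] <- c(setdiff(adj[[ab[1L]]], v), ab[2L])
    adj[[ab[2L]]] <- c(setdiff(adj[[ab[2L]]], v), ab[1L])
    adj[[v]] <- integer(0)
    act[v] <- FALSE
  }
  list(adj = adj, act = act)
}

## Drop inactive nodes and renumber; returns the compacted rftree plus the
## map from new ids to the original ids.
compact_tree <- function(adj, act, rooted, root, labels, taxa) {
  keep <- which(act)
  newid <- integer(length(act))
  newid[keep] <- seq_along(keep)
  new_adj <- lapply(adj[keep], function(nb) sort(newid[nb]))
  tree <- rftree(new_adj, rooted = rooted,
                 root = if (rooted) newid[root] else NA_integer_,
                 labels = if (is.null(labels)) NULL else labels[keep],
                 taxa = taxa)
  list(tree = tree, node_map = stats::setNames(keep, seq_along(keep)))
}

#' Suppress degree-2 internal nodes
#'
#' Replaces every maximal path of degree-2 internal nodes by a single edge
#' between its two anchor nodes.  Leaves (and their labels) are untouched,
#' and a degree-2 root is kept: the root is not an internal node.  The
#' bipartition set of an unrooted tree and the cluster set of a rooted tree
#' are invariant under this operation.
#'
#' @param x an [rftree].
#' @return A list with `tree` (the suppressed tree, `k = 0`) and
#'   `node_map`, a named integer vector mapping each surviving node's new
#'   id to its id in the input tree.
#' @export
suppress_degree_two <- function(x) {
  s <- suppress_mask(x$adj, rep(TRUE, length(x$adj)),
                     if (x$rooted) x$root else NA_integer_)
  compact_tree(s$adj, s$act, x$rooted, x$root, x$labels, x$taxa)
}

#' Root an unrooted tree on an edge
#'
#' Subdivides the edge `e = {u, v}` with a new node that becomes the root:
#' `e` is removed and the new root is connected to both former endpoints,
#' so the root has degree 2.  Leaf labels are unchanged.
#'
#' @param x an unrooted [rftree].
#' @param edge integer vector of length 2, an edge of `x`.
#' @return A rooted [rftree] with one more node and one more edge.
#' @export
root_on_edge <- function(x, edge) {
  if (x$rooted) stop_rf("tree is already rooted", "rf_usage")
  edge <- as.integer(edge)
  u <- edge[1L]; v <- edge[2L]
  if (length(edge) != 2L || u < 1L || v < 1L || u > length(x$adj) ||
      v > length(x$adj) || !(v %in% x$adj[[u]])) {
    stop_rf("not an edge of the tree", "rf_usage")
  }
  r <- length(x$adj) + 1L
  adj <- x$adj
  adj[[u]] <- c(setdiff(adj[[u]], v), r)
  adj[[v]] <- c(setdiff(adj[[v]], u), r)
  adj[[r]] <- c(u, v)
  rftree(adj, rooted = TRUE, root = r,
         labels = if (is.null(x$labels)) NULL else c(x$labels, NA_integer_),
         taxa = x$taxa)
}

#' Subdivide an edge with a new degree-2 node
#'
#' Inserts a new node of degree 2 in the middle of `edge`.  Used to build
#' improper trees (trees with unifurcations) from proper ones; the
#' bipartition/cluster sets are unchanged while `m` and `k` each grow by 1.
#'
#' @param x an [rftree].
#' @param edge integer vector of length 2, an edge of `x`.
#' @return The tree with one more node.
#' @export
subdivide_edge <- function(x, edge) {
  edge <- as.integer(edge)
  u <- edge[1L]; v <- edge[2L]
  if (length(edge) != 2L || !(v %in% x$adj[[u]])) {
    stop_rf("not an edge of the tree", "rf_usage")
  }
  w <- length(x$adj) + 1L
  adj <- x$adj
  adj[[u]] <- c(setdiff(adj[[u]], v), w)
  adj[[v]] <- c(setdiff(adj[[v]], u), w)
  adj[[w]] <- c(u, v)
  rftree(adj, rooted = x$rooted, root = x$root,
         labels = if (is.null(x$labels)) NULL else c(x$labels, NA_integer_),
         taxa = x$taxa)
}
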