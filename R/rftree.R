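#' Phylogenetic and topological trees
#'
#' `rftree()` builds the tree object used throughout the package: an
#' undirected tree stored as an adjacency list, optionally rooted, and
#' optionally carrying a bijective leaf labeling over `{1, ..., n}`.  A tree
#' without labels is a *topological* tree (a shape); a tree with labels is a
#' *phylogenetic* tree.  Multifurcations and degree-2 internal nodes
#' (unifurcations) are both allowed; a rooted tree's root must have degree
#' at least 2 and is never counted as an internal node.
#'
#' @param adj list of integer vectors; `adj[[v]]` are the neighbours of node
#'   `v`.  Must describe a connected acyclic graph with at least 3 leaves.
#' @param rooted logical; is the tree rooted?
#' @param root integer node id of the root (required when `rooted = TRUE`).
#' @param labels optional integer vector of length `length(adj)`; `NA` for
#'   non-leaf nodes, and the leaf entries must be a permutation of
#'   `1:n` where `n` is the number of leaves.
#' @param taxa optional character vector of length `n`; `taxa[l]` is the
#'   taxon name attached to label `l`.
#' @return An object of class `"rftree"`.
#' @examples
#' # the unrooted star on 3 leaves: leaves 1..3 around centre node 4
#' star <- rftree(list(4L, 4L, 4L, c(1L, 2L, 3L)))
#' shape_stats(star)
#' @export
rftree <- function(adj, rooted = FALSE, root = NA_integer_,
                   labels = NULL, taxa = NULL) {
  x <- structure(
    list(adj = lapply(adj, as.integer), rooted = isTRUE(rooted),
         root = as.integer(root), labels = labels, taxa = taxa),
    class = "rftree"
  )
  validate_rftree(x)
  x
}

validate_rftree <- function(x) {
  adj <- x$adj
  nn <- length(adj)
  if (nn < 4L) stop_rf("a tree needs at least 4 nodes (3 leaves)", "rf_invalid")
  deg <- lengths(adj)
  for (v in seq_len(nn)) {
    nb <- adj[[v]]
    if (anyNA(nb) || any(nb < 1L) || any(nb > nn) || any(nb == v) ||
        anyDuplicated(nb)) {
      stop_rf("malformed adjacency list", "rf_invalid")
    }
    for (w in nb) {
      if (!(v %in% adj[[w]])) stop_rf("adjacency is not symmetric", "rf_invalid")
    }
  }
  if (sum(deg) != 2L * (nn - 1L)) {
    stop_rf("edge count must equal node count minus one", "rf_invalid")
  }
  ## connectivity (acyclicity then follows from the edge count)
  seen <- logical(nn)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  if (!all(seen)) stop_rf("tree is not connected", "rf_invalid")
  leaves <- which(deg == 1L)
  n <- length(leaves)
  if (n < 3L) stop_rf("a tree needs at least 3 leaves", "rf_invalid")
  if (x$rooted) {
    if (is.na(x$root) || x$root < 1L || x$root > nn) {
      stop_rf("rooted tree needs a valid root id", "rf_invalid")
    }
    if (deg[x$root] < 2L) stop_rf("root must have degree >= 2", "rf_invalid")
  } else if (!is.na(x$root)) {
    stop_rf("unrooted tree must not carry a root", "rf_invalid")
  }
  if (!is.null(x$labels)) {
    lab <- x$labels
    if (length(lab) != nn) stop_rf("labels must cover every node", "rf_invalid")
    if (any(!is.na(lab[-leaves]) & deg[-leaves] > 1L) ||
        !identical(sort(as.integer(lab[leaves])), seq_len(n))) {
      stop_rf("labels must be a bijection between leaves and 1..n", "rf_invalid")
    }
  }
  if (!is.null(x$taxa)) {
    if (is.null(x$labels)) stop_rf("taxa require labels", "rf_invalid")
    if (length(x$taxa) != n || anyDuplicated(x$taxa)) {
      stop_rf("taxa must be n unique names", "rf_invalid")
    }
  }
  invisible(x)
}

node_degrees <- function(x) lengths(x$adj)

#' Leaf node ids of a tree
#'
#' @param x an [rftree].
#' @return Sorted integer vector of the ids of the degree-1 nodes.
#' @export
tree_leaves <- function(x) which(lengths(x$adj) == 1L)

#' Edge list of a tree
#'
#' @param x an [rftree].
#' @return Two-column integer matrix, one row per edge, each row sorted so
#'   the smaller node id comes first; rows in lexicographic order.
#' @export
tree_edges <- function(x) {
  adj <- x$adj
  us <- rep.int(seq_along(adj), lengths(adj))
  vs <- unlist(adj, use.names = FALSE)
  keep <- us < vs
  e <- cbind(us[keep], vs[keep])
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

is_labeled <- function(x) !is.null(x$labels)

#' Assign the canonical leaf labeling
#'
#' Labels the leaves `1..n` in increasing order of node id.  Used to turn a
#' topological tree into a phylogenetic tree deterministically; existing
#' labels are overwritten.
#'
#' @param x an [rftree].
#' @param taxa optional character vector of `n` taxon names for labels
#'   `1..n`.
#' @return The labeled tree.
#' @export
label_canonical <- function(x, taxa = NULL) {
  leaves <- tree_leaves(x)
  lab <- rep(NA_integer_, length(x$adj))
  lab[leaves] <- seq_along(leaves)
  x$labels <- lab
  x$taxa <- taxa
  validate_rftree(x)
  x
}

#' Permute the leaf labels of a tree
#'
#' Relabels the leaves: the leaf currently labeled `l` receives label
#' `perm[l]`.  Taxon names follow their labels.  Distances are invariant
#' under applying the same permutation to both trees of a pair.
#'
#' @param x a labeled [rftree].
#' @param perm an integer permutation of `1:n`.
#' @return The relabeled tree.
#' @export
apply_label_permutation <- function(x, perm) {
  stopifnot(is_labeled(x))
  leaves <- tree_leaves(x)
  x$labels[leaves] <- as.integer(perm[x$labels[leaves]])
  if (!is.null(x$taxa)) x$taxa[perm] <- x$taxa
  x
}

#' @export
print.rftree <- function(x, ...) {
  st <- shape_stats(x)
  cat(sprintf(
    "%s %s tree: %d leaves, %d nodes, m = %d internal edge(s), k = %d degree-2 node(s)%s\n",
    if (x$rooted) "Rooted" else "Unrooted",
    if (is_labeled(x)) "phylogenetic" else "topological",
    st$n, length(x$adj), st$m, st$k,
    if (st$proper) "" else " [not proper]"
  ))
  invisible(x)
}

#' Canonical form string of a tree
#'
#' Computes an AHU-style canonical string: bottom-up from sorted child
#' canonical strings for rooted trees, minimized over all node rootings for
#' unrooted trees.  Two trees are isomorphic (as rooted/unrooted shapes, or
#' as labeled trees when `labeled = TRUE`) exactly when their canonical
#' strings are equal.
#'
#' @param x an [rftree].
#' @param labeled logical; include leaf labels in the form (requires a
#'   labeled tree).
#' @return A character scalar.
#' @export
tree_canonical <- function(x, labeled = FALSE) {
  if (labeled && !is_labeled(x)) stop_rf("tree has no labels", "rf_invalid")
  adj <- x$adj
  deg <- lengths(adj)
  lab <- if (labeled) x$labels else NULL
  canon_from <- function(v, parent) {
    ch <- setdiff(adj[[v]], parent)
    if (!length(ch)) {
      if (labeled) return(sprintf("[%d]", lab[v]))
      return("()")
    }
    paste0("(", paste(sort(vapply(ch, canon_from, "", parent = v)),
                      collapse = ""), ")")
  }
  if (x$rooted) return(canon_from(x$root, 0L))
  min(vapply(seq_along(adj), canon_from, "", parent = 0L))
}
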