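## Align t2's labels to t1 via taxon names when both carry them; otherwise
## both trees must be label-compatible (same n, labels 1..n).
align_pair <- function(t1, t2) {
  if (!is_labeled(t1) || !is_labeled(t2)) {
    stop_rf("both trees must be labeled", "rf_usage")
  }
  n1 <- length(tree_leaves(t1))
  n2 <- length(tree_leaves(t2))
  if (n1 != n2) stop_rf("trees have different numbers of leaves", "rf_label")
  if (!is.null(t1$taxa) && !is.null(t2$taxa)) {
    if (!setequal(t1$taxa, t2$taxa)) {
      stop_rf("trees have different taxon-name sets", "rf_label")
    }
    ## leaf with taxon name s gets the label s has in t1
    remap <- match(t2$taxa, t1$taxa)
    t2 <- apply_label_permutation(t2, remap)
    t2$taxa <- t1$taxa
  } else if (xor(is.null(t1$taxa), is.null(t2$taxa))) {
    stop_rf("taxon names present in only one tree", "rf_label")
  }
  t2
}

#' Tree partition distance (Robinson-Foulds distance, unrooted)
#'
#' The size of the symmetric difference between the non-trivial
#' bipartition sets of two unrooted phylogenetic trees on the same label
#' set.  When both trees carry taxon names the labels are aligned by name
#' first; the taxon-name sets must then be identical.
#'
#' @param t1,t2 unrooted, labeled [rftree] objects with the same leaf set.
#' @return A non-negative integer.
#' @examples
#' a <- read_newick(text = "((A,B),C,D);")
#' b <- read_newick(text = "((A,C),B,D);")
#' tpd(a, b)
#' @export
tpd <- function(t1, t2) {
  if (t1$rooted || t2$rooted) {
    stop_rf("tpd is defined for two unrooted trees", "rf_usage")
  }
  t2 <- align_pair(t1, t2)
  as.integer(symdiff_size(bipartitions(t1), bipartitions(t2)))
}

#' Cluster distance (Robinson-Foulds distance, rooted)
#'
#' The size of the symmetric difference between the non-trivial cluster
#' sets of two rooted phylogenetic trees on the same label set.
#'
#' @param t1,t2 rooted, labeled [rftree] objects with the same leaf set.
#' @return A non-negative integer.
#' @export
cd <- function(t1, t2) {
  if (!t1$rooted || !t2$rooted) {
    stop_rf("cd is defined for two rooted trees", "rf_usage")
  }
  t2 <- align_pair(t1, t2)
  as.integer(symdiff_size(clusters(t1), clusters(t2)))
}

#' Unrooted cluster distance
#'
#' Compares an unrooted tree `t1` with a rooted tree `t2` by rooting `t1`
#' optimally: the minimum, over every edge `e` of `t1` (leaf edges
#' included), of the cluster distance between the rooting of `t1` on `e`
#' and `t2`.  Ties are broken towards the lexicographically smallest edge.
#'
#' @param t1 an unrooted, labeled [rftree].
#' @param t2 a rooted, labeled [rftree] with the same leaf set.
#' @return A list with `distance` (non-negative integer) and `edge` (the
#'   minimizing edge of `t1`, an integer pair).
#' @export
urcd <- function(t1, t2) {
  if (t1$rooted || !t2$rooted) {
    stop_rf("urcd needs an unrooted first tree and a rooted second tree",
            "rf_usage")
  }
  t2 <- align_pair(t1, t2)
  cl2 <- clusters(t2)
  e <- tree_edges(t1)
  best <- NULL
  best_edge <- NULL
  for (i in seq_len(nrow(e))) {
    d <- symdiff_size(clusters(root_on_edge(t1, e[i, ])), cl2)
    if (is.null(best) || d < best) {
      best <- d
      best_edge <- e[i, ]
    }
  }
  list(distance = as.integer(best), edge = as.integer(best_edge))
}
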