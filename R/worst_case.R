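#' Exact worst-case distance for a fixed pair of topologies
#'
#' For two tree shapes with the same number of leaves, the largest
#' Robinson-Foulds-type distance over all joint leaf labelings is
#' `(m1 - k1) + (m2 - k2)`, where `m` counts internal edges and `k` counts
#' degree-2 internal nodes.  For `tpd` and `cd` this bound is strict:
#' [construct_unrooted()] and [construct_rooted()] build labelings that
#' attain it.  For `urcd` the same expression is returned as the nominal
#' bound, but the true maximum of the min-over-rootings distance can
#' differ from it by one in either direction; see the package vignette and
#' [construct_urcd()].
#'
#' @param t1,t2 [rftree] objects with equal leaf counts and rootedness
#'   matching `mode` (`tpd`: both unrooted; `cd`: both rooted; `urcd`:
#'   `t1` unrooted, `t2` rooted).
#' @param mode one of `"tpd"`, `"cd"`, `"urcd"`.
#' @return A non-negative integer.
#' @examples
#' a <- random_topology(10, seed = 1)
#' b <- random_topology(10, seed = 2)
#' exact_bound(a, b, "tpd")  # 2n - 6 = 14 for fully resolved pairs
#' @export
exact_bound <- function(t1, t2, mode = c("tpd", "cd", "urcd")) {
  mode <- match.arg(mode)
  check_mode_pair(t1, t2, mode)
  s1 <- shape_stats(t1)
  s2 <- shape_stats(t2)
  as.integer((s1$m - s1$k) + (s2$m - s2$k))
}

check_mode_pair <- function(t1, t2, mode) {
  ok <- switch(mode,
    tpd  = !t1$rooted && !t2$rooted,
    cd   = t1$rooted && t2$rooted,
    urcd = !t1$rooted && t2$rooted
  )
  if (!ok) stop_rf(sprintf("tree rootedness does not match mode '%s'", mode),
                   "rf_usage")
  if (length(tree_leaves(t1)) != length(tree_leaves(t2))) {
    stop_rf("trees must have the same number of leaves", "rf_label")
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## The inductive construction.  One recursion serves both the unrooted
## (bipartition) and rooted (cluster) cases; the trees are proper, passed as
## adjacency lists with an activity mask so node ids stay stable and the
## labels returned deep in the recursion land on the original leaves.
## Labelings are named integer vectors: names are leaf ids, values labels.

cx_leaves <- function(adj, act) sort(which(act & lengths(adj) == 1L))

cx_is_internal <- function(adj, act, root) {
  act & lengths(adj) > 1L & (if (is.na(root)) TRUE else seq_along(adj) != root)
}

cx_m <- function(adj, act) {
  deg <- lengths(adj)
  e <- edge_matrix(adj, act)
  sum(deg[e[, 1L]] > 1L & deg[e[, 2L]] > 1L)
}

cx_leaf_nbrs <- function(adj, v) {
  nb <- adj[[v]]
  sort(nb[lengths(adj[nb]) == 1L])
}

## smallest internal node with >= 3 leaf neighbours, or NA
cx_find_big <- function(adj, act, root) {
  for (v in which(cx_is_internal(adj, act, root))) {
    if (length(cx_leaf_nbrs(adj, v)) >= 3L) return(v)
  }
  NA_integer_
}

## smallest internal node with exactly two leaf neighbours and exactly one
## other neighbour (the anchor v, an internal node or the root)
cx_find_cherry <- function(adj, act, root) {
  for (v in which(cx_is_internal(adj, act, root))) {
    if (length(adj[[v]]) == 3L && length(cx_leaf_nbrs(adj, v)) == 2L) {
      return(v)
    }
  }
  stop("internal error: no contractible cherry found")  # nocov
}

cx_drop_leaf <- function(adj, act, l) {
  nb <- adj[[l]]
  adj[[nb]] <- setdiff(adj[[nb]], l)
  adj[[l]] <- integer(0)
  act[l] <- FALSE
  list(adj = adj, act = act)
}

## remove leaf u1 and cherry node u, reconnect the kept leaf u2 to anchor v
cx_contract <- function(adj, act, u, u1, u2, v) {
  adj[[v]] <- c(setdiff(adj[[v]], u), u2)
  adj[[u2]] <- v
  adj[[u1]] <- integer(0)
  adj[[u]] <- integer(0)
  act[c(u, u1)] <- FALSE
  list(adj = adj, act = act)
}

cx_canonical_labels <- function(adj, act) {
  lv <- cx_leaves(adj, act)
  stats::setNames(seq_along(lv), lv)
}

construct_recurse <- function(a1, act1, r1, a2, act2, r2) {
  lv1 <- cx_leaves(a1, act1)
  n <- length(lv1)
  m1 <- cx_m(a1, act1)
  m2 <- cx_m(a2, act2)
  rooted <- !is.na(r1)

  if (n == 3L) {
    if (rooted && m1 > 0L && m2 > 0L) {
      ## both trees are a cherry below the root: cherry leaves get {1,2} in
      ## the first tree and {1,3} in the second
      ch1 <- which(cx_is_internal(a1, act1, r1))[[1L]]
      ch2 <- which(cx_is_internal(a2, act2, r2))[[1L]]
      c1 <- cx_leaf_nbrs(a1, ch1)
      c2 <- cx_leaf_nbrs(a2, ch2)
      lab1 <- stats::setNames(c(1L, 2L, 3L),
                              c(c1, setdiff(cx_leaves(a1, act1), c1)))
      lab2 <- stats::setNames(c(1L, 3L, 2L),
                              c(c2, setdiff(cx_leaves(a2, act2), c2)))
      return(list(lab1 = lab1, lab2 = lab2))
    }
    return(list(lab1 = cx_canonical_labels(a1, act1),
                lab2 = cx_canonical_labels(a2, act2)))
  }

  ## case 1: a tree with no internal edge contributes nothing; any labeling
  if (m1 == 0L || m2 == 0L) {
    return(list(lab1 = cx_canonical_labels(a1, act1),
                lab2 = cx_canonical_labels(a2, act2)))
  }

  big1 <- cx_find_big(a1, act1, r1)
  big2 <- cx_find_big(a2, act2, r2)

  ## case 2: both trees own an internal node with >= 3 leaf neighbours;
  ## drop one such leaf from each, recurse, give both the label n
  if (!is.na(big1) && !is.na(big2)) {
    l1 <- cx_leaf_nbrs(a1, big1)[[1L]]
    l2 <- cx_leaf_nbrs(a2, big2)[[1L]]
    d1 <- cx_drop_leaf(a1, act1, l1)
    d2 <- cx_drop_leaf(a2, act2, l2)
    sub <- construct_recurse(d1$adj, d1$act, r1, d2$adj, d2$act, r2)
    return(list(
      lab1 = c(sub$lab1, stats::setNames(n, l1)),
      lab2 = c(sub$lab2, stats::setNames(n, l2))
    ))
  }

  ## case 3: the tree whose internal nodes all touch <= 2 leaves plays the
  ## first role; swap if needed and swap the labelings back afterwards
  if (!is.na(big1)) {
    res <- construct_recurse(a2, act2, r2, a1, act1, r1)
    return(list(lab1 = res$lab2, lab2 = res$lab1))
  }

  u <- cx_find_cherry(a1, act1, r1)
  un <- cx_leaf_nbrs(a1, u)
  u1 <- un[[1L]]; u2 <- un[[2L]]
  v <- setdiff(a1[[u]], un)
  c1 <- cx_contract(a1, act1, u, u1, u2, v)

  if (!is.na(big2)) {
    ## the second tree loses one leaf of a >= 3-leaf node instead
    x1 <- cx_leaf_nbrs(a2, big2)[[1L]]
    d2 <- cx_drop_leaf(a2, act2, x1)
    sub <- construct_recurse(c1$adj, c1$act, r1, d2$adj, d2$act, r2)
    return(list(
      lab1 = c(sub$lab1, stats::setNames(n, u1)),
      lab2 = c(sub$lab2, stats::setNames(n, x1))
    ))
  }

  ## both trees are contracted at a cherry
  x <- cx_find_cherry(a2, act2, r2)
  xn <- cx_leaf_nbrs(a2, x)
  x1 <- xn[[1L]]; x2 <- xn[[2L]]
  y <- setdiff(a2[[x]], xn)
  c2 <- cx_contract(a2, act2, x, x1, x2, y)

  sub <- construct_recurse(c1$adj, c1$act, r1, c2$adj, c2$act, r2)
  lab1 <- sub$lab1
  lab2 <- sub$lab2
  i <- lab1[[as.character(u2)]]
  j <- lab2[[as.character(x2)]]
  lv <- cx_leaf_nbrs(c1$adj, v)   # leaf neighbours of the anchors after
  ly <- cx_leaf_nbrs(c2$adj, y)   # contraction; contain u2 resp. x2

  if (i == j) {
    if (length(lv) >= 2L) {
      ## anchor v has a second leaf: swapping u2 with it makes the labels
      ## at u2 and x2 differ (subcases a and b)
      w <- setdiff(lv, u2)[[1L]]
      tmp <- lab1[[as.character(u2)]]
      lab1[[as.character(u2)]] <- lab1[[as.character(w)]]
      lab1[[as.character(w)]] <- tmp
    } else if (length(ly) >= 2L) {
      ## mirror image on the second tree (subcase c)
      w <- setdiff(ly, x2)[[1L]]
      tmp <- lab2[[as.character(x2)]]
      lab2[[as.character(x2)]] <- lab2[[as.character(w)]]
      lab2[[as.character(w)]] <- tmp
    }
  }
  i <- lab1[[as.character(u2)]]
  j <- lab2[[as.character(x2)]]
  lab1 <- c(lab1, stats::setNames(n, u1))
  lab2 <- c(lab2, stats::setNames(n, x1))
  if (i == j) {
    ## subcase d with equal labels: exchange labels k and n in the first
    ## tree, k the smallest label different from i
    kk <- setdiff(seq_len(n - 1L), i)[[1L]]
    id_k <- names(lab1)[[match(kk, lab1)]]
    lab1[[id_k]] <- n
    lab1[[as.character(u1)]] <- kk
  }
  list(lab1 = lab1, lab2 = lab2)
}

## suppress unifurcations (mask form), run the construction, and return
## labeled copies of the *original* trees (leaves survive suppression)
construct_core <- function(t1, t2) {
  s1 <- suppress_mask(t1$adj, rep(TRUE, length(t1$adj)),
                      if (t1$rooted) t1$root else NA_integer_)
  s2 <- suppress_mask(t2$adj, rep(TRUE, length(t2$adj)),
                      if (t2$rooted) t2$root else NA_integer_)
  labs <- construct_recurse(
    s1$adj, s1$act, if (t1$rooted) t1$root else NA_integer_,
    s2$adj, s2$act, if (t2$rooted) t2$root else NA_integer_
  )
  lt1 <- set_leaf_labels(t1, labs$lab1)
  lt2 <- set_leaf_labels(t2, labs$lab2)
  list(tree1 = lt1, tree2 = lt2, labeling1 = sort_labeling(labs$lab1),
       labeling2 = sort_labeling(labs$lab2))
}

set_leaf_labels <- function(x, labeling) {
  labels <- rep(NA_integer_, length(x$adj))
  labels[as.integer(names(labeling))] <- as.integer(labeling)
  x$labels <- labels
  x$taxa <- NULL
  validate_rftree(x)
  x
}

sort_labeling <- function(lab) {
  lab <- lab[order(as.integer(names(lab)))]
  stats::setNames(as.integer(lab), names(lab))
}

new_worst_case <- function(mode, t1, t2, core, bound, achieved, min_edge = NULL) {
  structure(list(
    mode = mode,
    n = length(tree_leaves(t1)),
    stats1 = shape_stats(t1),
    stats2 = shape_stats(t2),
    bound = as.integer(bound),
    achieved = as.integer(achieved),
    achieves_bound = achieved == bound,
    tree1 = core$tree1,
    tree2 = core$tree2,
    labeling1 = core$labeling1,
    labeling2 = core$labeling2,
    min_edge = min_edge
  ), class = "rf_worst_case")
}

#' Worst-case labelings for the tree partition distance
#'
#' Builds leaf labelings of two unrooted topologies that make the tree
#' partition distance equal to its strict upper bound
#' `(m1 - k1) + (m2 - k2)`.  Degree-2 chains are suppressed first (this
#' changes neither the bipartition sets nor the leaves), then the
#' inductive construction runs on the proper trees: each step either
#' removes a leaf from a node with three or more leaf neighbours, or
#' contracts a two-leaf cherry, assigning the largest label to the removed
#' leaves and repairing label collisions exactly as the case analysis
#' requires.  The result is verified by recomputing the distance; a
#' mismatch would be an internal error.
#'
#' @param t1,t2 unrooted [rftree] objects with the same number of leaves
#'   (labels, if present, are ignored).
#' @return An object of class `"rf_worst_case"`: bound, achieved distance,
#'   the two labeled trees, and the labelings as named vectors
#'   (leaf id -> label).
#' @examples
#' a <- random_topology(6, seed = 1)
#' b <- random_topology(6, seed = 2)
#' construct_unrooted(a, b)  # achieves 2n - 6 = 6
#' @export
construct_unrooted <- function(t1, t2) {
  check_mode_pair(t1, t2, "tpd")
  bound <- exact_bound(t1, t2, "tpd")
  core <- construct_core(t1, t2)
  achieved <- tpd(core$tree1, core$tree2)
  if (achieved != bound) {
    stop(sprintf("internal error: constructed tpd %d != bound %d",
                 achieved, bound))
  }
  new_worst_case("tpd", t1, t2, core, bound, achieved)
}

#' Worst-case labelings for the cluster distance
#'
#' Rooted counterpart of [construct_unrooted()]: builds labelings of two
#' rooted topologies whose cluster distance equals
#' `(m1 - k1) + (m2 - k2)`.  The base case with three leaves labels the
#' two cherries `{1,2}` and `{1,3}`; a degree-2 root is never suppressed
#' (the root is not an internal node).
#'
#' @param t1,t2 rooted [rftree] objects with the same number of leaves.
#' @return An `"rf_worst_case"` object; see [construct_unrooted()].
#' @export
construct_rooted <- function(t1, t2) {
  check_mode_pair(t1, t2, "cd")
  bound <- exact_bound(t1, t2, "cd")
  core <- construct_core(t1, t2)
  achieved <- cd(core$tree1, core$tree2)
  if (achieved != bound) {
    stop(sprintf("internal error: constructed cd %d != bound %d",
                 achieved, bound))
  }
  new_worst_case("cd", t1, t2, core, bound, achieved)
}

#' Worst-case labelings for the unrooted cluster distance
#'
#' Roots `t1` on its lexicographically smallest edge, runs
#' [construct_rooted()] against `t2`, transfers the labeling back to `t1`
#' (rooting does not touch the leaves), and then recomputes the unrooted
#' cluster distance -- the minimum over *all* rootings -- as the achieved
#' value.  Unlike the `tpd`/`cd` cases the nominal bound
#' `(m1 - k1) + (m2 - k2)` is not always attained: the minimum over
#' rootings can fall short of it, and for star-like pairs it can even
#' exceed it, because rooting any edge of `t1` adds one internal edge to
#' the rooted copy.  When the achieved value differs from the nominal
#' bound the result carries `achieves_bound = FALSE` and a warning is
#' emitted; the brute-force oracle ([brute_force_max()],
#' [worst_case_sweep()]) is the arbiter for small `n`.
#'
#' @param t1 an unrooted [rftree]; `t2` a rooted [rftree] with the same
#'   number of leaves.
#' @param t2 see `t1`.
#' @return An `"rf_worst_case"` object with `mode = "urcd"` and the
#'   minimizing edge in `min_edge`.
#' @export
construct_urcd <- function(t1, t2) {
  check_mode_pair(t1, t2, "urcd")
  bound <- exact_bound(t1, t2, "urcd")
  e <- tree_edges(t1)[1L, ]
  tr <- root_on_edge(t1, e)
  res <- construct_rooted(tr, t2)
  ## transfer: the rooting added one node (the root) after all of t1's
  ## nodes, so the labeling restricts to t1 unchanged
  lt1 <- set_leaf_labels(t1, res$labeling1)
  core <- list(tree1 = lt1, tree2 = res$tree2,
               labeling1 = res$labeling1, labeling2 = res$labeling2)
  u <- urcd(lt1, res$tree2)
  out <- new_worst_case("urcd", t1, t2, core, bound, u$distance,
                        min_edge = u$edge)
  if (!out$achieves_bound) {
    warning(sprintf(
      "urcd worst-case construction achieved %d, nominal bound %d; the bound formula is not exact for min-over-rootings (see vignette)",
      out$achieved, out$bound))
  }
  out
}

#' Verify a worst-case result
#'
#' Recomputes the mode's distance from the labeled trees stored in an
#' `"rf_worst_case"` object and compares it with the stored bound.
#'
#' @param result an object returned by one of the `construct_*`
#'   functions.
#' @return `TRUE` when the recomputed distance equals the bound.
#' @export
verify_worst_case <- function(result) {
  d <- switch(result$mode,
    tpd  = tpd(result$tree1, result$tree2),
    cd   = cd(result$tree1, result$tree2),
    urcd = urcd(result$tree1, result$tree2)$distance
  )
  identical(as.integer(d), result$bound)
}

#' @export
print.rf_worst_case <- function(x, ...) {
  cat(sprintf("Worst-case %s for fixed topologies (n = %d)\n", x$mode, x$n))
  cat(sprintf("  tree 1: m = %d, k = %d%s\n", x$stats1$m, x$stats1$k,
              if (x$stats1$proper) "" else " (improper)"))
  cat(sprintf("  tree 2: m = %d, k = %d%s\n", x$stats2$m, x$stats2$k,
              if (x$stats2$proper) "" else " (improper)"))
  cat(sprintf("  bound = %d, achieved = %d%s\n", x$bound, x$achieved,
              if (x$achieves_bound) "" else "  [bound not attained]"))
  invisible(x)
}
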