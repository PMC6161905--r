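## all permutations of the integer vector v as a matrix (one per row)
perm_matrix <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], perm_matrix(v[-i]), deparse.level = 0L)
  }))
}

## label-set keys of id-sets under labeling `lab` (lab indexed by node id)
map_keys_clusters <- function(sets, lab) {
  unique(vapply(sets, function(s) paste(sort(lab[s]), collapse = ","), ""))
}

map_keys_splits <- function(sets, lab, n) {
  unique(vapply(sets, function(s) split_key(lab[s], n), ""))
}

#' Exhaustive maximum distance over all labelings
#'
#' Ground truth for the worst-case bound on small trees: fixes the first
#' tree's labeling canonically (valid because the distances are invariant
#' under relabeling both trees with the same permutation) and enumerates
#' all `n!` labelings of the second tree, returning the maximum distance
#' and one maximizing labeling pair.
#'
#' @param t1,t2 [rftree] objects with rootedness matching `mode`;
#'   existing labels are ignored.
#' @param mode one of `"tpd"`, `"cd"`, `"urcd"` (for `"urcd"` the distance
#'   maximized is the min-over-rootings cluster distance).
#' @param cap refuse `n` above this (the enumeration has `n!` terms).
#' @return A list with `max` (integer), `labeling1`, `labeling2` (named
#'   vectors, leaf id -> label), `mode`, `n`.
#' @examples
#' star <- enumerate_topologies(3)[[1]]
#' brute_force_max(star, star, "tpd")$max  # 0: both split sets are empty
#' @export
brute_force_max <- function(t1, t2, mode = c("tpd", "cd", "urcd"), cap = 8L) {
  mode <- match.arg(mode)
  check_mode_pair(t1, t2, mode)
  n <- length(tree_leaves(t1))
  if (n > cap) stop_rf(sprintf("n = %d above oracle cap %d", n, cap), "rf_cap")

  lt1 <- label_canonical(t1)
  leaves2 <- tree_leaves(t2)
  perms <- perm_matrix(seq_len(n))
  lab <- rep(NA_integer_, length(t2$adj))

  if (mode == "tpd") {
    ref <- bipartitions(lt1)
    sets2 <- bip_leaf_sides(t2)
    score <- function(lab) symdiff_size(ref, map_keys_splits(sets2, lab, n))
  } else if (mode == "cd") {
    ref <- clusters(lt1)
    sets2 <- cluster_leaf_sets(t2)
    score <- function(lab) symdiff_size(ref, map_keys_clusters(sets2, lab))
  } else {
    e1 <- tree_edges(lt1)
    ref_by_edge <- lapply(seq_len(nrow(e1)), function(i) {
      clusters(root_on_edge(lt1, e1[i, ]))
    })
    sets2 <- cluster_leaf_sets(t2)
    score <- function(lab) {
      keys2 <- map_keys_clusters(sets2, lab)
      min(vapply(ref_by_edge, symdiff_size, 0L, b = keys2))
    }
  }

  best <- -1L
  best_perm <- NULL
  for (r in seq_len(nrow(perms))) {
    lab[leaves2] <- perms[r, ]
    d <- score(lab)
    if (d > best) {
      best <- d
      best_perm <- perms[r, ]
    }
  }
  list(
    max = as.integer(best),
    labeling1 = stats::setNames(seq_len(n), tree_leaves(lt1)),
    labeling2 = stats::setNames(as.integer(best_perm), leaves2),
    mode = mode, n = n
  )
}

#' Sweep all small shape pairs against the bound formula
#'
#' For every ordered pair of shapes with `n <= n_max` leaves (enumerated
#' by [enumerate_topologies()], optionally with inserted degree-2 nodes),
#' records the brute-force maximum distance, the bound formula
#' `(m1 - k1) + (m2 - k2)`, and the distance achieved by the constructive
#' algorithm, and flags disagreements.  For `tpd` and `cd` the three
#' numbers agree; for `urcd` the `deviation` column documents where the
#' min-over-rootings maximum departs from the formula.
#'
#' @param n_max largest leaf count to sweep (from 3).
#' @param mode one of `"tpd"`, `"cd"`, `"urcd"`.
#' @param degree2 number of degree-2 nodes to insert into every shape.
#' @param cap oracle cap forwarded to [brute_force_max()].
#' @return A data frame with one row per ordered shape pair: `n`,
#'   `shape1`, `shape2`, `m1`, `k1`, `m2`, `k2`, `brute`, `bound`,
#'   `achieved`, `deviation` (`brute - bound`), `bound_ok`
#'   (`brute == bound`), `construct_ok` (`achieved == brute`).
#' @export
worst_case_sweep <- function(n_max, mode = c("tpd", "cd", "urcd"),
                             degree2 = 0L, cap = 8L) {
  mode <- match.arg(mode)
  rows <- list()
  for (n in 3:n_max) {
    shapes1 <- enumerate_topologies(n, rooted = mode == "cd",
                                    degree2 = degree2, cap = cap)
    shapes2 <- if (mode == "tpd") {
      shapes1
    } else {
      enumerate_topologies(n, rooted = TRUE, degree2 = degree2, cap = cap)
    }
    for (i in seq_along(shapes1)) {
      for (j in seq_along(shapes2)) {
        t1 <- shapes1[[i]]
        t2 <- shapes2[[j]]
        s1 <- shape_stats(t1)
        s2 <- shape_stats(t2)
        brute <- brute_force_max(t1, t2, mode, cap = cap)$max
        bound <- exact_bound(t1, t2, mode)
        res <- switch(mode,
          tpd  = construct_unrooted(t1, t2),
          cd   = construct_rooted(t1, t2),
          urcd = suppressWarnings(construct_urcd(t1, t2))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, shape1 = i, shape2 = j,
          m1 = s1$m, k1 = s1$k, m2 = s2$m, k2 = s2$k,
          brute = brute, bound = bound, achieved = res$achieved,
          deviation = brute - bound,
          bound_ok = brute == bound,
          construct_ok = res$achieved == brute
        )
      }
    }
  }
  do.call(rbind, rows)
}
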