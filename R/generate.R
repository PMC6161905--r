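## adjacency-level helpers shared by the generators -------------------------

edge_matrix <- function(adj, act) {
  us <- rep.int(seq_along(adj), lengths(adj))
  vs <- unlist(adj, use.names = FALSE)
  keep <- us < vs & act[us] & act[vs]
  cbind(us[keep], vs[keep])
}

## subdivide edge (u,v); the new node id is length(adj)+1
adj_subdivide <- function(adj, u, v) {
  w <- length(adj) + 1L
  adj[[u]] <- c(setdiff(adj[[u]], v), w)
  adj[[v]] <- c(setdiff(adj[[v]], u), w)
  adj[[w]] <- c(u, v)
  adj
}

adj_attach_leaf <- function(adj, v) {
  l <- length(adj) + 1L
  adj[[v]] <- c(adj[[v]], l)
  adj[[l]] <- v
  adj
}

#' Random topological tree
#'
#' Draws a random tree shape: a binary shape is grown by sequential leaf
#' attachment to a uniformly chosen edge, then a `(1 - resolution)`
#' fraction of the internal edges is contracted to create multifurcations,
#' and finally `k` degree-2 nodes are inserted by subdividing uniformly
#' chosen edges (leaf edges included).  Deterministic given `seed`.
#'
#' @param n number of leaves, `>= 3`.
#' @param rooted logical; grow a rooted shape (root of degree 2 in the
#'   binary phase) or an unrooted one.
#' @param resolution fraction in `[0, 1]`; 1 keeps the tree fully
#'   resolved, 0 contracts every internal edge (a star).
#' @param k number of degree-2 nodes to insert.
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit.
#' @return A topological [rftree] (no labels).
#' @export
random_topology <- function(n, rooted = FALSE, resolution = 1, k = 0L,
                            seed = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 3L) stop_rf("n must be at least 3", "rf_usage")
  if (k < 0L || resolution < 0 || resolution > 1) {
    stop_rf("need k >= 0 and resolution in [0, 1]", "rf_usage")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (rooted) {
    ## root (id 3) with two leaf children, then grow
    adj <- list(3L, 3L, c(1L, 2L))
    root <- 3L
    grow <- n - 2L
  } else {
    adj <- list(4L, 4L, 4L, c(1L, 2L, 3L))
    root <- NA_integer_
    grow <- n - 3L
  }
  act <- rep(TRUE, length(adj))
  for (i in seq_len(grow)) {
    e <- edge_matrix(adj, act)
    pick <- e[sample.int(nrow(e), 1L), ]
    adj <- adj_subdivide(adj, pick[1L], pick[2L])
    adj <- adj_attach_leaf(adj, length(adj))
    act <- rep(TRUE, length(adj))
  }
  ## contract internal edges to the requested resolution
  deg <- lengths(adj)
  e <- edge_matrix(adj, act)
  is_int <- deg[e[, 1L]] > 1L & deg[e[, 2L]] > 1L
  n_contract <- round((1 - resolution) * sum(is_int))
  for (i in seq_len(n_contract)) {
    deg <- lengths(adj)
    e <- edge_matrix(adj, act)
    ie <- e[deg[e[, 1L]] > 1L & deg[e[, 2L]] > 1L, , drop = FALSE]
    if (!nrow(ie)) break
    pick <- ie[sample.int(nrow(ie), 1L), ]
    a <- pick[1L]; b <- pick[2L]
    if (!is.na(root) && b == root) { tmp <- a; a <- b; b <- tmp }
    ## merge b into a
    for (w in setdiff(adj[[b]], a)) {
      adj[[w]] <- c(setdiff(adj[[w]], b), a)
      adj[[a]] <- c(adj[[a]], w)
    }
    adj[[a]] <- setdiff(adj[[a]], b)
    adj[[b]] <- integer(0)
    act[b] <- FALSE
  }
  ## insert the requested unifurcations
  for (i in seq_len(k)) {
    e <- edge_matrix(adj, act)
    pick <- e[sample.int(nrow(e), 1L), ]
    adj <- adj_subdivide(adj, pick[1L], pick[2L])
    act <- c(act, TRUE)
  }
  compact_tree(adj, act, rooted, root, NULL, NULL)$tree
}

## raw canonical form for the enumerator (adj list, optional root)
canon_adj <- function(adj, root = NA_integer_) {
  rec <- function(v, parent) {
    ch <- setdiff(adj[[v]], parent)
    if (!length(ch)) return("()")
    paste0("(", paste(sort(vapply(ch, rec, "", parent = v)), collapse = ""),
           ")")
  }
  if (!is.na(root)) return(rec(root, 0L))
  min(vapply(seq_along(adj), rec, "", parent = 0L))
}

#' Enumerate tree shapes
#'
#' Yields exactly one representative per isomorphism class of proper tree
#' shapes with `n` leaves (unrooted or rooted), optionally with `degree2`
#' degree-2 nodes inserted in every distinct way.  Proper shapes are built
#' by recursive leaf attachment (attach to an internal node, subdivide an
#' edge, or -- rooted only -- place a new root above the old one), with
#' AHU canonical-form deduplication at every step.
#'
#' @param n number of leaves, at most `cap`.
#' @param rooted logical.
#' @param degree2 number of degree-2 nodes to insert (0 = proper shapes).
#' @param cap safety cap on `n` (the enumeration is exponential).
#' @return A list of topological [rftree] objects.
#' @examples
#' length(enumerate_topologies(4))          # star and quartet
#' length(enumerate_topologies(4, rooted = TRUE))
#' @export
enumerate_topologies <- function(n, rooted = FALSE, degree2 = 0L, cap = 7L) {
  n <- as.integer(n)
  if (n > cap) stop_rf(sprintf("n = %d above enumeration cap %d", n, cap),
                       "rf_cap")
  if (n < 3L) stop_rf("n must be at least 3", "rf_usage")
  if (rooted) {
    shapes <- list(list(adj = list(3L, 3L, c(1L, 2L)), root = 3L))
    from <- 2L
  } else {
    shapes <- list(list(adj = list(4L, 4L, 4L, c(1L, 2L, 3L)),
                        root = NA_integer_))
    from <- 3L
  }
  for (size in seq_len(n - from) + from) {
    nxt <- list()
    seen <- character(0)
    add <- function(adj, root) {
      key <- canon_adj(adj, root)
      if (!(key %in% seen)) {
        seen[[length(seen) + 1L]] <<- key
        nxt[[length(nxt) + 1L]] <<- list(adj = adj, root = root)
      }
    }
    for (s in shapes) {
      deg <- lengths(s$adj)
      for (v in which(deg >= 2L)) {           # attach to internal node/root
        add(adj_attach_leaf(s$adj, v), s$root)
      }
      e <- edge_matrix(s$adj, rep(TRUE, length(s$adj)))
      for (i in seq_len(nrow(e))) {           # subdivide edge, attach there
        adj2 <- adj_subdivide(s$adj, e[i, 1L], e[i, 2L])
        add(adj_attach_leaf(adj2, length(adj2)), s$root)
      }
      if (rooted) {                           # new root above the old one
        r <- length(s$adj) + 1L
        adj2 <- s$adj
        adj2[[s$root]] <- c(adj2[[s$root]], r)
        adj2[[r]] <- s$root
        add(adj_attach_leaf(adj2, r), r)
      }
    }
    shapes <- nxt
  }
  ## insert degree-2 nodes in all distinct ways
  for (i in seq_len(degree2)) {
    nxt <- list()
    seen <- character(0)
    for (s in shapes) {
      e <- edge_matrix(s$adj, rep(TRUE, length(s$adj)))
      for (j in seq_len(nrow(e))) {
        adj2 <- adj_subdivide(s$adj, e[j, 1L], e[j, 2L])
        key <- canon_adj(adj2, s$root)
        if (!(key %in% seen)) {
          seen[[length(seen) + 1L]] <- key
          nxt[[length(nxt) + 1L]] <- list(adj = adj2, root = s$root)
        }
      }
    }
    shapes <- nxt
  }
  lapply(shapes, function(s) {
    rftree(s$adj, rooted = rooted, root = s$root)
  })
}
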