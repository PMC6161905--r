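test_that("Newick parsing keeps the full structure, including unifurcations", {
  # a top-level bifurcation read unrooted introduces a degree-2 node that
  # is kept, not silently suppressed
  q <- read_newick(text = "((A,B),(C,D));")
  s <- shape_stats(q)
  expect_equal(s$n, 4L)
  expect_equal(s$m, 2L)
  expect_equal(s$k, 1L)
  expect_false(s$proper)
  # written with a trifurcation at the top it parses as the proper quartet
  q2 <- read_newick(text = "(A,B,(C,D));")
  expect_equal(unclass(shape_stats(q2))[c("n", "m", "k")],
               list(n = 4L, m = 1L, k = 0L))

  st <- read_newick(text = "(A,B,C);")
  expect_equal(shape_stats(st)$m, 0L)
  expect_equal(shape_stats(st)$n, 3L)

  d2 <- read_newick(text = "((A)X,B,C);")
  expect_equal(shape_stats(d2)$k, 1L)

  expect_error(read_newick(text = "(A,B);"), class = "rf_parse")
  expect_error(read_newick(text = "(A,B,A);"), class = "rf_parse")
  expect_error(read_newick(text = "((A,B,C));", rooted = TRUE),
               class = "rf_parse")
  expect_error(read_newick(text = "not newick ["), class = "rf_parse")
})

test_that("labels are assigned by lexicographic taxon order", {
  tr <- read_newick(text = "((Zebra,Ant),Moth,(Bee,Cat));")
  expect_equal(tr$taxa, sort(c("Zebra", "Ant", "Moth", "Bee", "Cat")))
  leaves <- tree_leaves(tr)
  expect_setequal(tr$labels[leaves], 1:5)
})

test_that("branch lengths are discarded with a notice", {
  expect_message(tr <- read_newick(text = "((A:1,B:2):0.5,C:1,D:3);"),
                 "branch lengths")
  expect_equal(shape_stats(tr)$m, 1L)
})

test_that("read/write round-trips preserve labeled isomorphism", {
  for (seed in 1:50) {
    n <- 3L + (seed %% 10L)
    tr <- label_canonical(random_topology(
      n, rooted = FALSE, resolution = 0.5 + (seed %% 3L) / 4, k = seed %% 3L,
      seed = seed))
    back <- read_newick(text = write_newick(tr))
    expect_identical(tree_canonical(back, labeled = TRUE),
                     tree_canonical(tr, labeled = TRUE))
    expect_identical(unclass(shape_stats(back)), unclass(shape_stats(tr)))
  }
  # degree-2 single-child clause survives the round trip
  d2 <- read_newick(text = "((A)X,B,C);")
  expect_equal(shape_stats(read_newick(text = write_newick(d2)))$k, 1L)
})

test_that("shape statistics count internal edges and unifurcations", {
  expect_equal(shape_stats(star_tree(3))$m, 0L)
  s <- shape_stats(random_topology(6, seed = 1))
  expect_equal(s$m, 3L)  # fully resolved unrooted: m = n - 3
  q <- subdivide_edge(quartet_tree(), c(5L, 6L))
  expect_equal(unclass(shape_stats(q))[c("n", "m", "k")],
               list(n = 4L, m = 2L, k = 1L))
  expect_false(shape_stats(q)$proper)
  # a degree-2 root is not internal and not counted in k
  rt <- rooted_cherry_tree()
  expect_equal(shape_stats(rt)$k, 0L)
  expect_true(shape_stats(rt)$proper)
})

test_that("degree-2 suppression contracts chains and preserves leaves", {
  q <- quartet_tree()
  expect_identical(suppress_degree_two(q)$tree$adj, q$adj)  # k = 0: identity

  q1 <- subdivide_edge(q, c(5L, 6L))
  sup <- suppress_degree_two(q1)
  expect_equal(shape_stats(sup$tree)$m, 1L)
  expect_equal(shape_stats(sup$tree)$k, 0L)

  # a path of 3 consecutive degree-2 nodes collapses to one edge
  q3 <- subdivide_edge(subdivide_edge(subdivide_edge(q, c(5L, 6L)), c(5L, 7L)),
                       c(5L, 8L))
  expect_equal(shape_stats(q3)$k, 3L)
  sup3 <- suppress_degree_two(q3)
  expect_equal(shape_stats(sup3$tree)$n, 4L)
  expect_equal(shape_stats(sup3$tree)$k, 0L)
  expect_equal(shape_stats(sup3$tree)$m,
               shape_stats(q3)$m - shape_stats(q3)$k)
  # node correspondence points back at original ids
  expect_true(all(sup3$node_map %in% seq_along(q3$adj)))

  # rooted: a degree-2 root survives suppression
  rt <- root_on_edge(label_canonical(quartet_tree()), c(5L, 6L))
  rs <- suppress_degree_two(rt)$tree
  expect_equal(length(rs$adj[[rs$root]]), 2L)
})

test_that("rooting on an edge adds one node and one edge", {
  q <- label_canonical(quartet_tree())
  r <- root_on_edge(q, c(5L, 6L))
  expect_true(r$rooted)
  expect_equal(length(r$adj), length(q$adj) + 1L)
  expect_equal(nrow(tree_edges(r)), nrow(tree_edges(q)) + 1L)
  expect_setequal(clusters(r), c("1,2", "3,4"))
  # rooting an internal edge of a proper tree adds one internal edge
  expect_equal(shape_stats(r)$m, shape_stats(q)$m + 1L)

  st <- label_canonical(star_tree(3))
  r2 <- root_on_edge(st, c(1L, 4L))
  expect_setequal(clusters(r2), "2,3")
  expect_error(root_on_edge(q, c(1L, 3L)), class = "rf_usage")
})

test_that("random topologies honour their shape requests deterministically", {
  t1 <- random_topology(5, seed = 3)
  expect_equal(shape_stats(t1)$m, 2L)
  expect_identical(random_topology(5, seed = 3)$adj, t1$adj)
  expect_equal(shape_stats(random_topology(3, resolution = 0.2, seed = 1))$m, 0L)
  t2 <- random_topology(12, rooted = TRUE, resolution = 0, k = 2, seed = 9)
  s2 <- shape_stats(t2)
  expect_equal(s2$k, 2L)
  # resolution 0 contracts every internal edge of the binary shape; only the
  # two inserted unifurcation edges remain internal
  expect_equal(s2$m, 2L)
  for (seed in 1:20) {
    tr <- random_topology(4L + seed, rooted = seed %% 2L == 0L,
                          resolution = (seed %% 4L) / 4, k = seed %% 3L,
                          seed = seed)
    deg <- lengths(tr$adj)
    expect_equal(sum(deg) / 2L, length(tr$adj) - 1L)  # |E| = |V| - 1
    expect_equal(shape_stats(tr)$k, seed %% 3L)
  }
})

test_that("topology enumeration matches brute-force isomorphism counts", {
  expect_length(enumerate_topologies(3), 1L)
  expect_length(enumerate_topologies(4), 2L)
  expect_length(enumerate_topologies(5), 3L)
  expect_length(enumerate_topologies(4, rooted = TRUE), 5L)
  expect_error(enumerate_topologies(9), class = "rf_cap")

  # independent check at n = 4 rooted: distinct canonical forms among many
  # random rooted shapes of every resolution
  seen <- character(0)
  for (seed in 1:200) {
    tr <- random_topology(4, rooted = TRUE, resolution = (seed %% 5) / 4,
                          seed = seed)
    seen <- union(seen, tree_canonical(tr))
  }
  expect_setequal(seen,
                  vapply(enumerate_topologies(4, rooted = TRUE),
                         tree_canonical, ""))

  # fully resolved shapes in the enumeration satisfy m = n - 3 / n - 2
  for (n in 4:6) {
    for (tr in enumerate_topologies(n)) {
      s <- shape_stats(tr)
      if (all(lengths(tr$adj)[lengths(tr$adj) > 1L] == 3L)) {
        expect_equal(s$m, n - 3L)
      }
    }
  }
})
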