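test_that("the bound formula is (m1 - k1) + (m2 - k2)", {
  a <- random_topology(10, seed = 1)
  b <- random_topology(10, seed = 2)
  expect_equal(exact_bound(a, b, "tpd"), 14L)  # 2n - 6 for resolved pairs

  expect_equal(exact_bound(star_tree(5), random_topology(5, seed = 3), "tpd"),
               2L)

  a2 <- subdivide_edge(quartet_tree(), c(5L, 6L))     # m = 2, k = 1
  b2 <- random_topology(4, seed = 4)                  # m = 1, k = 0
  expect_equal(exact_bound(a2, b2, "tpd"), 2L)

  expect_error(exact_bound(a, root_on_edge(b, tree_edges(b)[1, ]), "tpd"),
               class = "rf_usage")
  expect_error(exact_bound(a, random_topology(9, seed = 5), "tpd"),
               class = "rf_label")
  # the bound ignores suppressible structure entirely
  expect_equal(exact_bound(suppress_degree_two(a2)$tree, b2, "tpd"),
               exact_bound(a2, b2, "tpd"))
})

test_that("unrooted construction achieves the bound on small named cases", {
  r <- construct_unrooted(star_tree(3), star_tree(3))
  expect_equal(r$bound, 0L)
  expect_equal(r$achieved, 0L)

  r2 <- construct_unrooted(random_topology(6, seed = 10),
                           random_topology(6, seed = 11))
  expect_equal(r2$achieved, 6L)  # 2n - 6 at n = 6
  expect_true(verify_worst_case(r2))

  r3 <- construct_unrooted(star_tree(5), random_topology(5, seed = 12))
  expect_equal(r3$achieved, 2L)
})

test_that("rooted construction reproduces the three-leaf cherry labelings", {
  r <- construct_rooted(rooted_cherry_tree(), rooted_cherry_tree())
  expect_equal(r$achieved, 2L)
  expect_setequal(c(clusters(r$tree1), clusters(r$tree2)), c("1,2", "1,3"))

  r2 <- construct_rooted(rooted_star_tree(3), rooted_cherry_tree())
  expect_equal(r2$achieved, 1L)

  r3 <- construct_rooted(random_topology(5, rooted = TRUE, seed = 13),
                         random_topology(5, rooted = TRUE, seed = 14))
  expect_equal(r3$achieved, 6L)  # m = n - 2 = 3 in both trees
  expect_true(verify_worst_case(r3))
})

test_that("construction transfers labels correctly through suppression", {
  for (seed in 1:15) {
    n <- 5L + (seed %% 20L)
    a <- random_topology(n, resolution = 0.5, k = 1L + seed %% 2L, seed = seed)
    b <- random_topology(n, resolution = 0.8, k = seed %% 3L,
                         seed = seed + 100L)
    r <- construct_unrooted(a, b)
    expect_equal(r$achieved, r$bound)
    expect_true(verify_worst_case(r))
    # labelings cover exactly the leaves
    expect_setequal(as.integer(names(r$labeling1)), tree_leaves(a))
    expect_setequal(unname(r$labeling1), seq_len(n))

    ar <- random_topology(n, rooted = TRUE, resolution = 0.5, k = seed %% 2L,
                          seed = seed + 200L)
    br <- random_topology(n, rooted = TRUE, resolution = 0.7,
                          seed = seed + 300L)
    rr <- construct_rooted(ar, br)
    expect_equal(rr$achieved, rr$bound)
  }
})

test_that("tampering with a verified labeling is detected", {
  r <- construct_unrooted(random_topology(6, seed = 20),
                          random_topology(6, seed = 21))
  expect_true(verify_worst_case(r))
  # swap two labels in tree1 only: the distance changes away from the bound
  swapped <- apply_label_permutation(r$tree1, c(2L, 1L, 3:6))
  tampered <- r
  tampered$tree1 <- swapped
  expect_false(verify_worst_case(tampered))
})

test_that("urcd construction reports honestly when the bound is off by one", {
  # every rooting of a star yields one non-trivial cluster, so against a
  # rooted star (empty cluster set) the min over rootings is 1, above the
  # nominal bound 0
  expect_warning(
    r <- construct_urcd(star_tree(3), rooted_star_tree(3)),
    "not exact"
  )
  expect_equal(r$bound, 0L)
  expect_equal(r$achieved, 1L)
  expect_false(r$achieves_bound)

  # and rooting the star on the right leaf edge can cancel a cluster, so
  # against a cherry the min over rootings is 0, below the nominal bound 1
  expect_warning(r2 <- construct_urcd(star_tree(3), rooted_cherry_tree()))
  expect_equal(r2$bound, 1L)
  expect_equal(r2$achieved, 0L)

  # the reported achieved value always matches a fresh urcd computation
  u <- urcd(r2$tree1, r2$tree2)
  expect_equal(u$distance, r2$achieved)
})

test_that("distinct internal edges of a proper tree induce distinct splits", {
  # the 'any labelings' base cases of the construction rely on this
  for (n in 4:6) {
    for (tr in enumerate_topologies(n)) {
      lt <- label_canonical(tr)
      expect_length(bipartitions(lt), shape_stats(tr)$m)
    }
    for (tr in enumerate_topologies(n, rooted = TRUE)) {
      lt <- label_canonical(tr)
      expect_length(clusters(lt), shape_stats(tr)$m)
    }
  }
})
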