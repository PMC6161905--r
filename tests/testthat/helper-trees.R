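# hand-built fixture trees used across the test files

# unrooted star: leaves 1..n around a single centre node n+1
star_tree <- function(n = 3L) {
  adj <- c(as.list(rep(n + 1L, n)), list(seq_len(n)))
  rftree(adj)
}

# proper unrooted quartet with cherries {1,2} and {3,4}:
# internal nodes 5 (1,2) and 6 (3,4), internal edge 5-6
quartet_tree <- function() {
  rftree(list(5L, 5L, 6L, 6L, c(1L, 2L, 5L + 1L), c(3L, 4L, 5L)))
}

# unrooted caterpillar on 5 leaves, cherries (1,2) and (4,5):
# internal nodes 6 (1,2), 7 (3), 8 (4,5); edges 6-7, 7-8
caterpillar5_tree <- function() {
  rftree(list(6L, 6L, 7L, 8L, 8L, c(1L, 2L, 7L), c(3L, 6L, 8L), c(4L, 5L, 7L)))
}

# rooted cherry tree ((a,b),c): root 5, internal 4 holding leaves 1,2
rooted_cherry_tree <- function() {
  rftree(list(4L, 4L, 5L, c(1L, 2L, 5L), c(3L, 4L)), rooted = TRUE, root = 5L)
}

# rooted star on n leaves
rooted_star_tree <- function(n = 3L) {
  adj <- c(as.list(rep(n + 1L, n)), list(seq_len(n)))
  rftree(adj, rooted = TRUE, root = n + 1L)
}

canonical_pair <- function(t1, t2) {
  list(t1 = label_canonical(t1), t2 = label_canonical(t2))
}
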