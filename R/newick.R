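#' Read a tree in Newick format
#'
#' Parses a (possibly multifurcating) Newick tree and returns an [rftree].
#' Leaf labels `1..n` are assigned by lexicographic order of the leaf
#' names, which are kept as the taxon map.  Single-child Newick clauses
#' become degree-2 nodes and are kept as such (suppression is an explicit,
#' separate operation, see [suppress_degree_two()]); in particular a
#' top-level bifurcation read in unrooted mode yields a degree-2 node that
#' is reported in `k`.  Branch lengths are parsed and discarded with a
#' notice: all distances in this package are purely topological.  Internal
#' node names are ignored.
#'
#' @param file path to a file whose first line holds one Newick tree.
#' @param text a Newick string (used instead of `file` when given).
#' @param rooted logical; read as a rooted tree (the top-level node becomes
#'   the root and must have degree >= 2) or as an unrooted tree (the
#'   top-level node is an ordinary node).
#' @return An [rftree] with labels and taxa set.
#' @examples
#' tr <- read_newick(text = "((A,B),(C,D));")
#' shape_stats(tr)
#' @export
read_newick <- function(file = NULL, text = NULL, rooted = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop_rf("supply `file` or `text`", "rf_usage")
    text <- readLines(file, warn = FALSE)
    text <- text[nzchar(trimws(text))]
    if (!length(text)) stop_rf("empty Newick file", "rf_parse")
    text <- text[[1L]]
  }
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (inherits(ph, "multiPhylo")) ph <- ph[[1L]]
  if (is.null(ph) || !inherits(ph, "phylo")) {
    stop_rf("could not parse Newick input", "rf_parse")
  }
  if (!is.null(ph$edge.length)) {
    message("branch lengths present in Newick input are ignored")
  }
  ntip <- length(ph$tip.label)
  if (ntip < 3L) stop_rf("fewer than 3 leaves", "rf_parse")
  if (anyDuplicated(ph$tip.label)) {
    stop_rf("duplicate leaf names", "rf_parse")
  }
  nn <- ntip + ph$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(ph$edge))) {
    a <- ph$edge[i, 1L]; b <- ph$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  top <- ntip + 1L  # ape's top-level node
  if (length(adj[[top]]) < 2L) {
    stop_rf(if (rooted) "top-level node of a rooted tree must have degree >= 2"
            else "top-level node has a single child; not a valid unrooted tree",
            "rf_parse")
  }
  taxa <- sort(ph$tip.label)
  labels <- rep(NA_integer_, nn)
  labels[seq_len(ntip)] <- match(ph$tip.label, taxa)
  rftree(adj, rooted = rooted,
         root = if (rooted) top else NA_integer_,
         labels = labels, taxa = taxa)
}

quote_taxon <- function(s) {
  if (grepl("[ ()\\[\\]:;,']", s)) {
    paste0("'", gsub("'", "''", s), "'")
  } else s
}

#' Write a tree in Newick format
#'
#' Serializes an [rftree] to Newick.  Rooted trees are written from the
#' root; unrooted trees are written from an internal node of degree >= 3
#' when one exists, so that the top level is a multifurcation.  Degree-2
#' nodes appear as single-child clauses, and `read_newick(write_newick(x))`
#' reproduces the tree up to labeled isomorphism.  Topological trees are
#' labeled canonically first and written with zero-padded placeholder
#' names (`t01`, `t02`, ...) whose lexicographic order matches the labels.
#'
#' @param x an [rftree].
#' @param file optional path; when given the string is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(x, file = NULL) {
  if (!is_labeled(x)) {
    x <- label_canonical(x)
  }
  n <- length(tree_leaves(x))
  taxa <- x$taxa
  if (is.null(taxa)) {
    taxa <- sprintf(paste0("t%0", nchar(n), "d"), seq_len(n))
  }
  adj <- x$adj
  deg <- lengths(adj)
  nwk <- function(v, parent) {
    ch <- setdiff(adj[[v]], parent)
    if (!length(ch)) return(quote_taxon(taxa[x$labels[v]]))
    paste0("(", paste(vapply(ch, nwk, "", parent = v), collapse = ","), ")")
  }
  start <- if (x$rooted) x$root else {
    cand <- which(deg >= 3L)
    if (length(cand)) cand[[1L]] else which(deg >= 2L)[[1L]]
  }
  out <- paste0(nwk(start, 0L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
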