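#' Normalized tree distances
#'
#' Divides the raw distance by a worst-case divisor so trees of different
#' sizes and shapes become comparable.  Three schemes are available:
#' `"exact"` divides by the strict worst case for the two fixed topologies
#' (`(m1 - k1) + (m2 - k2)`, see [exact_bound()]); `"classic"` divides the
#' tree partition distance by `2n - 6`, the worst case over *all*
#' topologies with `n` leaves; `"randomized"` divides by the randomized
#' approximation of the topology-fixed worst case ([randomized_bound()]),
#' kept for comparison with software that estimates the divisor by
#' relabeling.
#'
#' When both raw distance and divisor are 0 (two star topologies) the
#' normalized value is 0 by convention, with a notice.  For `mode =
#' "urcd"` the exact divisor is nominal (see [construct_urcd()]) and the
#' value can be `NA` when the divisor is 0 but the distance is not.
#'
#' @param t1,t2 labeled [rftree] objects, rootedness matching `mode`.
#' @param mode one of `"tpd"`, `"cd"`, `"urcd"`.
#' @param scheme `"exact"`, `"classic"` or `"randomized"`.
#' @param reps,seed randomized scheme only: number of relabelings and RNG
#'   seed.
#' @return An object of class `"rf_norm"`: `raw`, `bound`, `value`,
#'   `scheme`, `mode`, `n` (plus `reps`, `seed` for the randomized
#'   scheme).
#' @examples
#' a <- read_newick(text = "((A,B),C,(D,E));")
#' b <- read_newick(text = "((A,C),B,(D,E));")
#' normalized_distance(a, b, "tpd")
#' @export
normalized_distance <- function(t1, t2, mode = c("tpd", "cd", "urcd"),
                                scheme = c("exact", "classic", "randomized"),
                                reps = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  check_mode_pair(t1, t2, mode)
  n <- length(tree_leaves(t1))
  raw <- switch(mode,
    tpd  = tpd(t1, t2),
    cd   = cd(t1, t2),
    urcd = urcd(t1, t2)$distance
  )
  bound <- switch(scheme,
    exact = exact_bound(t1, t2, mode),
    classic = {
      if (mode != "tpd") stop_rf("the classic 2n - 6 divisor applies to tpd only",
                                 "rf_usage")
      if (n < 4L) stop_rf("classic divisor 2n - 6 is 0 at n = 3; use the exact scheme",
                          "rf_usage")
      2L * n - 6L
    },
    randomized = randomized_bound(t1, t2, mode, reps = reps, seed = seed)
  )
  value <- if (bound > 0L) {
    raw / bound
  } else if (raw == 0L) {
    message("raw distance and worst-case divisor are both 0; normalized value set to 0")
    0
  } else {
    warning("worst-case divisor is 0 but the distance is not; normalized value is NA")
    NA_real_
  }
  out <- list(raw = as.integer(raw), bound = as.integer(bound),
              value = value, scheme = scheme, mode = mode, n = n)
  if (scheme == "randomized") {
    out$reps <- as.integer(reps)
    out$seed <- as.integer(seed)
  }
  structure(out, class = "rf_norm")
}

#' @export
print.rf_norm <- function(x, ...) {
  cat(sprintf("Normalized %s (%s scheme): %d / %d = %s\n",
              x$mode, x$scheme, x$raw, x$bound, format(x$value)))
  invisible(x)
}

#' Classic normalization by 2n - 6
#'
#' Divides the tree partition distance by `2n - 6`, the worst case over
#' all topologies with `n` leaves (attained by fully resolved pairs).
#' Errors at `n = 3`, where the divisor is 0; the exact scheme of
#' [normalized_distance()] handles that case.
#'
#' @param t1,t2 unrooted, labeled [rftree] objects, `n >= 4`.
#' @return An `"rf_norm"` object.
#' @export
classic_normalized <- function(t1, t2) {
  normalized_distance(t1, t2, mode = "tpd", scheme = "classic")
}

#' Randomized approximation of the worst-case bound
#'
#' The approximation used before the exact formula was available:
#' relabels the leaves of `t2` uniformly at random `reps` times (with `t1`
#' fixed) and returns the maximum distance observed.  Each repetition
#' draws from a counter-based seed (`seed + rep`), so results for `reps`
#' repetitions are a prefix of results for more repetitions with the same
#' `seed` and the maximum is nondecreasing in `reps`.  The value never
#' exceeds [exact_bound()], and falls strictly short of it whenever no
#' sampled relabeling happens to attain the worst case.
#'
#' @param t1,t2 labeled [rftree] objects, both unrooted (`mode = "tpd"`)
#'   or both rooted (`mode = "cd"`).
#' @param mode `"tpd"` or `"cd"`.
#' @param reps number of random relabelings, `>= 1`.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return The maximum distance observed (integer).
#' @export
randomized_bound <- function(t1, t2, mode = c("tpd", "cd"), reps = 1000L,
                             seed = 1L) {
  mode <- match.arg(mode)
  check_mode_pair(t1, t2, mode)
  reps <- as.integer(reps)
  if (reps < 1L) stop_rf("reps must be at least 1", "rf_usage")
  t2 <- align_pair(t1, t2)
  ## compare by bare labels from here on, so the relabeling is not undone
  ## by taxon-name re-alignment inside the distance
  t1$taxa <- NULL
  t2$taxa <- NULL
  n <- length(tree_leaves(t1))
  dist_fun <- if (mode == "tpd") tpd else cd
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  best <- 0L
  for (r in seq_len(reps)) {
    set.seed((as.integer(seed) + r) %% .Machine$integer.max)
    relab <- apply_label_permutation(t2, sample.int(n))
    d <- dist_fun(t1, relab)
    if (d > best) best <- d
  }
  as.integer(best)
}
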