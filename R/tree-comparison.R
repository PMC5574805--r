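# Direct topology/branch-length comparison of two trees on the same taxa.

check_same_tips <- function(t1, t2) {
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    stop("tip sets differ; only in first: ",
         paste(setdiff(l1, l2), collapse = ", "),
         "; only in second: ", paste(setdiff(l2, l1), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Topological difference between two trees
#'
#' The number of branches that differ: the size of the symmetric difference
#' of the two unrooted non-trivial bipartition sets (the Robinson-Foulds /
#' Penny-Hendy symmetric-difference count).
#'
#' @param t1,t2 `"phylo"` objects on identical tip sets, n >= 4.
#' @return Integer count; 0 for identical topologies, at most 2n-6 for
#'   binary trees.
#' @export
topological_difference <- function(t1, t2) {
  check_same_tips(t1, t2)
  if (length(t1$tip.label) < 4) stop("need at least 4 shared tips", call. = FALSE)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Relative topological difference
#'
#' The topological difference scaled by its maximum for binary trees,
#' `RTD = TD / (2n - 6)`, ranging from 0 (identical) to 1 (completely
#' different). The denominator is kept as 2n-6 even for trees with
#' polytomies, where TD counts only the splits actually present.
#'
#' @param t1,t2 `"phylo"` objects on identical tip sets, n >= 4.
#' @return A number in \[0, 1\] for binary trees.
#' @export
rtd <- function(t1, t2) {
  n <- length(t1$tip.label)
  if (n < 4) stop("RTD undefined for fewer than 4 tips", call. = FALSE)
  topological_difference(t1, t2) / (2 * n - 6)
}

#' Branch-length score between two trees
#'
#' The Kuhner-Felsenstein branch score: over the union of bipartitions of
#' both trees (including trivial tip branches), the square root of the sum
#' of squared branch-length differences, with length 0 where a split is
#' absent from one tree. Both the square-root value and the plain squared
#' sum are returned. With `normalize = TRUE` (the default) both trees are
#' first rescaled to total length 1 so trees in different units are
#' comparable.
#'
#' @param t1,t2 `"phylo"` objects on identical tip sets.
#' @param normalize Rescale both trees to total length 1 first?
#' @return A list with `bls` (sqrt convention) and `bls_squared`.
#' @export
branch_length_score <- function(t1, t2, normalize = TRUE) {
  check_same_tips(t1, t2)
  if (normalize) {
    t1 <- normalize_tree(t1)
    t2 <- normalize_tree(t2)
  }
  s1 <- split_lengths(t1, include_trivial = TRUE)
  s2 <- split_lengths(t2, include_trivial = TRUE)
  keys <- union(names(s1), names(s2))
  l1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  l2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sq <- sum((l1 - l2)^2)
  list(bls = sqrt(sq), bls_squared = sq)
}

#' All pairwise tree-comparison statistics
#'
#' @param t1,t2 `"phylo"` objects on identical tip sets, n >= 4.
#' @param normalize Passed to [branch_length_score()].
#' @return A list: `td`, `rtd`, `bls`, `bls_squared`, `n`.
#' @export
compare_trees <- function(t1, t2, normalize = TRUE) {
  td <- topological_difference(t1, t2)
  n <- length(t1$tip.label)
  bls <- branch_length_score(t1, t2, normalize = normalize)
  list(td = td, rtd = td / (2 * n - 6), bls = bls$bls,
       bls_squared = bls$bls_squared, n = n)
}
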