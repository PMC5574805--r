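# Phylogenetic signal of a Brownian "functional identity": Moran's I with
# inverse-patristic weights and Abouheif's Cmean (Moran's I with the
# Abouheif topology-only proximity).

#' Simulate Brownian motion along a tree
#'
#' Pre-order traversal: each child state is the parent state plus a
#' Normal(0, sigma2 x branch length) increment. With `n_rep > 1` the
#' replicates share one traversal (a matrix of independent draws per edge).
#'
#' @param tree A `"phylo"` object.
#' @param sigma2 Brownian rate (variance per unit branch length), > 0.
#' @param root_state State at the root.
#' @param seed Optional integer seed.
#' @param n_rep Number of independent replicates.
#' @return Named numeric vector of tip states, or an n_tips x n_rep matrix
#'   when `n_rep > 1`.
#' @export
brownian_simulate <- function(tree, sigma2 = 1, root_state = 0, seed = NULL,
                              n_rep = 1) {
  tree <- validate_tree(tree)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  states <- matrix(NA_real_, nnode, n_rep)
  states[ntip + 1L, ] <- root_state
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    states[ch, ] <- states[p, ] +
      stats::rnorm(n_rep, 0, sqrt(sigma2 * tree$edge.length[e]))
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  if (n_rep == 1) out[, 1] else out
}

#' Tip proximity matrix for phylogenetic signal statistics
#'
#' `patristic_inverse`: w_ij = 1 / patristic distance, the weighting paired
#' with Moran's I. `abouheif`: a_ij = 1 / product, over the internal nodes
#' on the path from i to j, of the number of direct descendants of each
#' node — a topology-only proximity invariant to branch lengths. Both have
#' zero diagonal and are row-normalized (rows sum to 1) unless
#' `row_normalize = FALSE`.
#'
#' @param tree A `"phylo"` object with >= 3 tips.
#' @param kind `"patristic_inverse"` or `"abouheif"`.
#' @param row_normalize Row-normalize the proximity (default `TRUE`).
#' @return A labeled square matrix with attribute `"kind"`.
#' @export
proximity_matrix <- function(tree, kind = c("patristic_inverse", "abouheif"),
                             row_normalize = TRUE) {
  kind <- match.arg(kind)
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 3) stop("need at least 3 tips", call. = FALSE)
  if (kind == "patristic_inverse") {
    d <- cophenetic_matrix(tree)
    if (any(d[upper.tri(d)] == 0)) {
      stop("tips at zero patristic distance; inverse-distance weights undefined",
           call. = FALSE)
    }
    w <- 1 / d
    diag(w) <- 0
  } else {
    n_children <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
    w <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
    for (i in seq_len(ntip - 1L)) {
      for (j in (i + 1L):ntip) {
        path <- ape::nodepath(tree, i, j)
        internal <- path[path > ntip]
        w[i, j] <- w[j, i] <- 1 / prod(n_children[internal])
      }
    }
  }
  if (row_normalize) w <- w / rowSums(w)
  attr(w, "kind") <- kind
  attr(w, "row_normalized") <- row_normalize
  w
}

#' Moran's I autocorrelation of tip values under a proximity matrix
#'
#' `I = (n / S0) * sum_{i != j} w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` with `S0 = sum_{i != j} w_ij`. With the Abouheif
#' proximity this is Abouheif's Cmean. Values are invariant to affine
#' transformation of `x`; with equal off-diagonal weights I equals the null
#' expectation -1/(n-1) exactly.
#'
#' @param values Named numeric vector of tip values (non-constant).
#' @param w A proximity matrix from [proximity_matrix()] (or any labeled
#'   non-negative matrix with zero diagonal).
#' @return The autocorrelation (a single number).
#' @export
morans_i <- function(values, w) {
  if (is.null(names(values))) stop("values must be named by species", call. = FALSE)
  if (!setequal(names(values), rownames(w))) {
    stop("species of values and proximity matrix differ", call. = FALSE)
  }
  x <- values[rownames(w)]
  n <- length(x)
  if (n < 3) stop("need at least 3 tips", call. = FALSE)
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("constant values; Moran's I undefined", call. = FALSE)
  (n / sum(w)) * drop(z %*% w %*% z) / ss
}

#' Permutation test of phylogenetic signal
#'
#' Moran's I (or Cmean, depending on the proximity) of the observed values
#' against a null built by shuffling values over tips; one-sided (greater)
#' with the add-one p-value convention.
#'
#' @param values Named numeric vector of tip values.
#' @param w Proximity matrix.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all n! assignments (n <= 7 only); exact p.
#' @return A `"phylofunc_test"` whose `method` names the proximity kind.
#' @export
signal_test <- function(values, w, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  obs <- morans_i(values, w)
  x <- values[rownames(w)]
  n <- length(x)
  method <- paste0("signal_", attr(w, "kind") %||% "custom")
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_null <- vapply(perms, function(p) morans_i(setNames(x[p], names(x)), w),
                         numeric(1))
    pval <- mean(stats_null >= obs - 1e-12)
    return(new_test_result(method, obs, pval, length(perms), NA_integer_,
                           "greater", n))
  }
  if (!is.null(seed)) set.seed(seed)
  stats_null <- permuted_moran_stats(x, w, n_perm)
  pval <- (1 + sum(stats_null >= obs)) / (1 + n_perm)
  new_test_result(method, obs, pval, as.integer(n_perm),
                  if (is.null(seed)) NA_integer_ else as.integer(seed),
                  "greater", n)
}

# Vectorized Moran's I over n_perm random permutations of x (columns of Z).
permuted_moran_stats <- function(x, w, n_perm) {
  n <- length(x)
  z <- x - mean(x)
  ss <- sum(z^2)
  Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  (n / sum(w)) * colSums(Z * (w %*% Z)) / ss
}

#' Phylogenetic signal of functional identity
#'
#' Functional identity is a quantitative stand-in for a species' place in
#' the functional tree: a Brownian simulation along the functional
#' dendrogram assigns each tip a value, and the phylogenetic signal of those
#' values is then measured on the phylogeny — Moran's I with
#' inverse-patristic weights, and Abouheif's Cmean with the Abouheif
#' proximity. Because one Brownian draw is a random realization, the
#' procedure is replicated and per-replicate statistics and permutation
#' p-values are reported along with their mean.
#'
#' @param phylo The phylogenetic tree.
#' @param functree The functional tree (same tip set).
#' @param n_replicates Brownian replicates (default 100).
#' @param n_perm Permutations per replicate test (default 999).
#' @param seed Integer seed governing all randomness.
#' @param sigma2 Brownian rate; Moran's I is scale-invariant so the value
#'   is immaterial (kept as a parameter for transparency).
#' @return A list with elements `moran_i` and `abouheif_cmean`, each a list
#'   with `observed` (mean over replicates), `per_replicate` (data.frame of
#'   statistic and p_value), `p_median`, `n_replicates`, `n_permutations`,
#'   `seed`.
#' @export
functional_identity_signal <- function(phylo, functree, n_replicates = 100,
                                       n_perm = 999, seed = 1, sigma2 = 1) {
  check_same_tips(phylo, functree)
  w_pat <- proximity_matrix(phylo, "patristic_inverse")
  w_ab <- proximity_matrix(phylo, "abouheif")
  set.seed(seed)
  tips <- brownian_simulate(functree, sigma2 = sigma2, root_state = 0,
                            n_rep = n_replicates)
  if (n_replicates == 1) tips <- matrix(tips, ncol = 1, dimnames = list(names(tips), NULL))
  one_stat <- function(w) {
    res <- lapply(seq_len(n_replicates), function(r) {
      x <- tips[, r]
      obs <- morans_i(x, w)
      null <- permuted_moran_stats(x[rownames(w)], w, n_perm)
      c(statistic = obs, p_value = (1 + sum(null >= obs)) / (1 + n_perm))
    })
    df <- as.data.frame(do.call(rbind, res))
    list(observed = mean(df$statistic), per_replicate = df,
         p_median = stats::median(df$p_value),
         n_replicates = n_replicates, n_permutations = as.integer(n_perm),
         seed = as.integer(seed))
  }
  list(moran_i = one_stat(w_pat), abouheif_cmean = one_stat(w_ab))
}
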