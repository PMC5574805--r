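# Independent oracles used across tests. These re-derive quantities by
# brute force (graph walks, exhaustive enumeration, naive agglomeration)
# and never call the package code paths they check.

# --- tree as an undirected weighted graph -------------------------------

tree_graph <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  adj
}

# All-pairs tip path lengths by per-tip BFS over the tree graph.
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  adj <- tree_graph(tree)
  n_nodes <- ntip + tree$Nnode
  out <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(ntip)) {
    dist <- rep(NA_real_, n_nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    out[s, ] <- dist[seq_len(ntip)]
  }
  out
}

# Unrooted splits by edge deletion: for every internal edge, the tips
# reachable from the child side. Canonicalized as sorted label strings of
# the side not containing the alphabetically first tip.
oracle_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  adj <- tree_graph(tree)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    # tips reachable from b without crossing edge (a, b)
    seen <- c(b); queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (u == a && v == b) next
        if (!u %in% seen) { seen <- c(seen, u); queue <- c(queue, u) }
      }
    }
    side <- tree$tip.label[seen[seen <= ntip]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= ntip - 2) {
      keys <- c(keys, paste(sort(side), collapse = "\u001f"))
    }
  }
  unique(keys)
}

oracle_td <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# --- naive UPGMA with lowest-index tie-break ----------------------------

# Returns the cophenetic matrix implied by naive O(n^3) average-linkage
# agglomeration (merge height = d/2, cophenetic distance = d).
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- seq_len(n)
  dm <- d
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (dm[i, j] < bestd) { bestd <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bestd
    }
    # UPGMA update into slot i
    for (kk in active) {
      if (kk == i || kk == j) next
      dm[i, kk] <- dm[kk, i] <-
        (sizes[i] * dm[i, kk] + sizes[j] * dm[j, kk]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  coph
}

# --- exhaustive enumerations --------------------------------------------

oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in oracle_permutations(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

oracle_mantel_exact_p <- function(d1, d2) {
  lt <- function(m) m[lower.tri(m)]
  obs <- cor(lt(d1), lt(d2))
  perms <- oracle_permutations(nrow(d1))
  stats <- vapply(perms, function(p) cor(lt(d1), lt(d2[p, p])), numeric(1))
  mean(stats >= obs - 1e-12)
}

oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(w)) * sum(outer(z, z) * w) / sum(z^2)
}

oracle_signal_exact_p <- function(x, w) {
  obs <- oracle_moran(x, w)
  perms <- oracle_permutations(length(x))
  stats <- vapply(perms, function(p) oracle_moran(x[p], w), numeric(1))
  mean(stats >= obs - 1e-12)
}

# Minimum changes of one binary character on a tree by exhaustive
# enumeration of internal-node state assignments; "?" tips are free.
oracle_parsimony_char <- function(tree, states) {
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  best <- Inf
  grid <- expand.grid(rep(list(c(0, 1)), length(internal)))
  tipst <- states[tree$tip.label]
  for (g in seq_len(nrow(grid))) {
    assign_ <- numeric(ntip + tree$Nnode)
    assign_[internal] <- as.numeric(grid[g, ])
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      sa <- assign_[a]
      sb <- if (b <= ntip) tipst[b] else assign_[b]
      if (is.na(sb)) next  # "?": free, matches parent
      if (sa != sb) cost <- cost + 1
    }
    best <- min(best, cost)
  }
  best
}

# Random binary tree on given labels with branch lengths.
random_tree <- function(n, labels = NULL) {
  tr <- ape::rtree(n, tip.label = labels)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr
}

# Random labeled symmetric distance matrix with zero diagonal.
random_dist <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.2, 2)
  m <- m + t(m)
  labs <- sprintf("t%02d", seq_len(n))
  dimnames(m) <- list(labs, labs)
  m
}
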