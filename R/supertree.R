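# Matrix representation with parsimony (MRP): Baum-Ragan encoding of source
# trees into binary characters, Fitch/Hartigan parsimony scoring, and a
# heuristic maximum-parsimony search for the supertree.

#' Encode source trees as an MRP matrix (Baum-Ragan coding)
#'
#' Each internal clade (excluding the root) of each source tree becomes one
#' binary character: clade members are 1, other taxa of that tree are 0,
#' and taxa absent from that tree are `?`. Characters that end up with
#' fewer than two 1s or no 0 (the root-spanning clade of a rooted tree)
#' carry no grouping information and are dropped.
#'
#' @param trees A list of `"phylo"` source trees with overlapping taxa.
#' @return An object of class `"mrp_matrix"`: a character matrix
#'   (taxa x characters) over `"0"`, `"1"`, `"?"`, with a `source`
#'   attribute mapping each character to its source tree index.
#' @export
mrp_encode <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one source tree", call. = FALSE)
  trees <- lapply(trees, validate_tree)
  taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  cols <- list()
  src <- integer(0)
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    ntip <- length(tree$tip.label)
    if (ntip < 3) {
      warning("source tree ", ti, " has fewer than 3 tips; contributes no characters",
              call. = FALSE)
      next
    }
    pp <- ape::prop.part(tree)
    root <- ntip + 1L
    for (node in (ntip + 1L):(ntip + tree$Nnode)) {
      if (node == root) next
      clade <- tree$tip.label[pp[[node - ntip]]]
      if (length(clade) < 2 || length(clade) >= ntip) next
      col <- setNames(rep("?", length(taxa)), taxa)
      col[tree$tip.label] <- "0"
      col[clade] <- "1"
      cols[[length(cols) + 1L]] <- col
      src <- c(src, ti)
    }
  }
  if (!length(cols)) stop("no informative characters in the source trees", call. = FALSE)
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  colnames(m) <- paste0("char", seq_len(ncol(m)))
  structure(m, class = c("mrp_matrix", class(m)), source = src)
}

#' Parsimony score of a binary character matrix on a tree
#'
#' Minimum number of state changes summed over characters, by Hartigan's
#' generalization of the Fitch pass (exact for any multifurcation and for
#' the two-state characters MRP produces). `?` is an unconstrained state:
#' it can take whichever value is cheapest, contributing no changes of its
#' own — the standard missing-data convention. The score does not depend on
#' where the tree is rooted.
#'
#' @param matrix An `"mrp_matrix"` (or character matrix over "0"/"1"/"?",
#'   rows named by taxa).
#' @param tree A `"phylo"` whose tips include every matrix taxon; tips
#'   absent from the matrix are treated as all-`?`.
#' @return Integer parsimony score >= 0.
#' @export
fitch_score <- function(matrix, tree) {
  tree <- validate_tree(tree)
  taxa <- rownames(matrix)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("matrix taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nchar_ <- ncol(matrix)
  # state sets as two logical matrices: does the node's set contain 0 / 1
  has0 <- base::matrix(TRUE, nnode, nchar_)
  has1 <- base::matrix(TRUE, nnode, nchar_)
  idx <- match(taxa, tree$tip.label)
  has0[idx, ] <- matrix != "1"   # "0" or "?"
  has1[idx, ] <- matrix != "0"
  count0 <- base::matrix(0L, nnode, nchar_)
  count1 <- base::matrix(0L, nnode, nchar_)
  nchild <- integer(nnode)
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode - ntip))
  cost <- numeric(nchar_)
  po <- ape::reorder.phylo(tree, "postorder")
  finalize <- function(node) {
    mx <- pmax(count0[node, ], count1[node, ])
    cost <<- cost + nchild[node] - mx
    has0[node, ] <<- count0[node, ] == mx
    has1[node, ] <<- count1[node, ] == mx
    done[node] <<- TRUE
  }
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    if (!done[ch]) finalize(ch)
    count0[p, ] <- count0[p, ] + has0[ch, ]
    count1[p, ] <- count1[p, ] + has1[ch, ]
    nchild[p] <- nchild[p] + 1L
  }
  finalize(po$edge[nrow(po$edge), 1])  # root
  as.integer(round(sum(cost)))
}

# Insert a new tip into the middle of edge `e` of a rooted tree, keeping
# ape's numbering conventions (tips 1..n, root = n+1). Unit branch lengths.
insert_tip <- function(tree, e, label) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  internal_shift <- function(x) ifelse(x > ntip, x + 1L, x)
  edge <- apply(edge, 2, internal_shift)
  new_tip <- ntip + 1L
  new_node <- ntip + 1L + tree$Nnode + 1L
  p <- edge[e, 1]; ch <- edge[e, 2]
  edge[e, ] <- c(p, new_node)
  edge <- rbind(edge, c(new_node, ch), c(new_node, new_tip))
  tree2 <- structure(list(edge = edge, edge.length = rep(1, nrow(edge)),
                          tip.label = c(tree$tip.label, label),
                          Nnode = tree$Nnode + 1L),
                     class = "phylo")
  ape::reorder.phylo(tree2, "cladewise")
}

# Stepwise random-addition starting tree: taxa are inserted in random order,
# each on the edge where the parsimony score of the grown tree is lowest
# (first edge on ties). Scores are computed against the matrix restricted to
# the taxa inserted so far.
random_addition_tree <- function(matrix, taxa_order) {
  first3 <- taxa_order[1:3]
  tree <- structure(list(edge = cbind(4L, 1:3), edge.length = rep(1, 3),
                         tip.label = first3, Nnode = 1L),
                    class = "phylo")
  for (k in 4:length(taxa_order)) {
    label <- taxa_order[k]
    sub <- matrix[intersect(rownames(matrix), c(tree$tip.label, label)), ,
                  drop = FALSE]
    scores <- vapply(seq_len(nrow(tree$edge)), function(e) {
      fitch_score(sub, insert_tip(tree, e, label))
    }, integer(1))
    tree <- insert_tip(tree, which.min(scores), label)
  }
  tree
}

#' Heuristic maximum-parsimony MRP supertree
#'
#' Follows the standard Baum-Ragan analysis: a hypothetical all-zero
#' ancestor is appended to the matrix (without it, clade characters with
#' missing taxa lose their grouping power), and the search runs over
#' stepwise random-addition starting trees (taxa inserted in random order
#' at the most parsimonious position) refined by
#' nearest-neighbor-interchange hill-climbing on the parsimony score. The
#' best tree over `restarts` independent starts is rooted on the
#' hypothetical ancestor, which is then removed. The search is
#' deterministic given `seed`. MRP recovers topology only, so the returned
#' tree carries unit branch lengths.
#'
#' @param matrix An `"mrp_matrix"` with >= 4 taxa.
#' @param restarts Number of random restarts (default 10).
#' @param seed Integer seed.
#' @return A list: `tree` (the best `"phylo"`, unit branch lengths, rooted
#'   via the hypothetical ancestor), `score` (its parsimony score on the
#'   input matrix), `restart_scores` (best augmented-matrix score per
#'   restart).
#' @export
mrp_supertree <- function(matrix, restarts = 10, seed = 1) {
  taxa <- rownames(matrix)
  n <- length(taxa)
  if (n < 4) stop("supertree search needs at least 4 taxa", call. = FALSE)
  anc <- ".mrp_ancestor"
  if (anc %in% taxa) stop("taxon name '", anc, "' is reserved", call. = FALSE)
  aug <- rbind(matrix, rep("0", ncol(matrix)))
  rownames(aug) <- c(taxa, anc)
  set.seed(seed)
  best_tree <- NULL
  best_score <- Inf
  restart_scores <- numeric(restarts)
  for (r in seq_len(restarts)) {
    t0 <- ape::unroot(random_addition_tree(aug, sample(rownames(aug))))
    t0$edge.length <- rep(1, nrow(t0$edge))
    s0 <- fitch_score(aug, t0)
    repeat {
      neighbors <- phangorn::nni(t0)
      scores <- vapply(neighbors, function(tr) {
        tr$edge.length <- rep(1, nrow(tr$edge))
        fitch_score(aug, tr)
      }, integer(1))
      if (min(scores) < s0) {
        t0 <- neighbors[[which.min(scores)]]
        t0$edge.length <- rep(1, nrow(t0$edge))
        s0 <- min(scores)
      } else break
    }
    restart_scores[r] <- s0
    if (s0 < best_score) {
      best_score <- s0
      best_tree <- t0
    }
  }
  rooted <- ape::root(best_tree, outgroup = anc, resolve.root = TRUE)
  final <- ape::drop.tip(rooted, anc)
  final$edge.length <- rep(1, nrow(final$edge))
  list(tree = final, score = fitch_score(matrix, final),
       restart_scores = restart_scores)
}

#' Export an MRP matrix as relaxed PHYLIP
#'
#' @param matrix An `"mrp_matrix"`.
#' @param path Output file path.
#' @export
write_mrp_phylip <- function(matrix, path) {
  lines <- c(paste(nrow(matrix), ncol(matrix)),
             paste(rownames(matrix),
                   apply(matrix, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
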