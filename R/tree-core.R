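#' Read a phylogenetic tree from newick text or a file
#'
#' Trees are held as `ape` `"phylo"` objects throughout the package. On top
#' of `ape`'s parser this adds the validation every downstream statistic
#' relies on: unique non-empty tip labels, non-negative branch lengths, and a
#' defaulting rule for absent branch lengths (set to 1 with a warning, so
#' topology-only newicks such as MRP supertrees remain usable).
#'
#' @param text A newick string (exactly one tree), or `NULL`.
#' @param file Path to a newick file; exactly one of `text`/`file` is given.
#' @return A validated `"phylo"` object.
#' @export
#' @examples
#' tr <- read_newick("((a:1,b:1):1,c:2);")
#' total_tree_length(tr)
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  }
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file)
  if (is.null(tree)) stop("could not parse newick input", call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("input contains more than one tree; use read_newick_set()", call. = FALSE)
  }
  validate_tree(tree)
}

#' Read a set of trees from a multi-newick file
#'
#' @param file Path to a file holding one newick string per line.
#' @return A list of validated `"phylo"` objects.
#' @export
read_newick_set <- function(file) {
  trees <- ape::read.tree(file = file)
  if (is.null(trees)) stop("could not parse newick input", call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, validate_tree)
}

#' Write a tree as newick
#'
#' @param tree A `"phylo"` object.
#' @param file Output path, or `NULL` to return the newick string.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Enforce the tree invariants shared by every module.
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label", call. = FALSE)
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 1", call. = FALSE)
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 1", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tree
}

#' Total branch length of a tree
#'
#' @param tree A `"phylo"` object.
#' @return Sum of all branch lengths.
#' @export
total_tree_length <- function(tree) {
  tree <- validate_tree(tree)
  sum(tree$edge.length)
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and
#' j.
#'
#' @param tree A `"phylo"` object with at least two tips.
#' @return A symmetric labeled matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < 2) {
    stop("cophenetic distances need at least 2 tips", call. = FALSE)
  }
  m <- as.matrix(stats::cophenetic(tree))
  check_dist_matrix(m, "cophenetic matrix")
}

#' Rescale a tree to total branch length 1
#'
#' Tree-distance statistics that mix trees in different units (substitutions
#' vs. Gower merge heights) are computed on normalized trees; topology is
#' unchanged.
#'
#' @param tree A `"phylo"` object with positive total length.
#' @return The tree with every branch length divided by the total length.
#' @export
normalize_tree <- function(tree) {
  tree <- validate_tree(tree)
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("cannot normalize a tree with total length 0", call. = FALSE)
  tree$edge.length <- tree$edge.length / tot
  tree
}

# Canonical key of one unrooted split: the side not containing the reference
# tip (first label in sort order), sorted, joined on a non-printing
# separator. Returns NA for trivial splits (a side with < 2 tips).
split_key <- function(side, all_labels, ref) {
  if (ref %in% side) side <- setdiff(all_labels, side)
  if (length(side) < 2 || length(side) > length(all_labels) - 2) return(NA_character_)
  paste(sort(side), collapse = "\u001f")
}

#' Non-trivial bipartitions of a tree, unrooted interpretation
#'
#' One split per internal branch of the unrooted tree; the root's artificial
#' split is not duplicated. Splits are canonicalized against a fixed
#' reference tip so sets from different trees on the same taxa are
#' comparable. Trees with fewer than 4 tips have no non-trivial splits and
#' return an empty set.
#'
#' @param tree A `"phylo"` object.
#' @return Character vector of canonical split keys (a set: no duplicates).
#' @export
tree_bipartitions <- function(tree) {
  tree <- validate_tree(tree)
  labs <- sort(tree$tip.label)
  if (length(labs) < 4) return(character(0))
  ref <- labs[1]
  pp <- ape::prop.part(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  keys <- character(0)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    if (node == root) next
    side <- tree$tip.label[pp[[node - ntip]]]
    k <- split_key(side, labs, ref)
    if (!is.na(k)) keys <- c(keys, k)
  }
  unique(keys)
}

# Split -> branch length map under the unrooted interpretation, optionally
# including trivial (tip) branches keyed "tip:<label>". Lengths of edges
# mapping to the same unrooted split (the two root-adjacent edges of a
# rooted tree) are summed, matching the usual unrooted branch-score
# convention.
split_lengths <- function(tree, include_trivial = TRUE) {
  tree <- validate_tree(tree)
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  acc <- new.env(parent = emptyenv())
  add <- function(key, len) {
    prev <- if (exists(key, envir = acc, inherits = FALSE)) get(key, envir = acc) else 0
    assign(key, prev + len, envir = acc)
  }
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    if (child <= ntip) {
      if (include_trivial) add(paste0("tip:", tree$tip.label[child]), len)
      next
    }
    side <- tree$tip.label[pp[[child - ntip]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) == 1) {
      # unrooted-trivial internal edge (complement is one tip): part of
      # that tip's pendant branch
      if (include_trivial) add(paste0("tip:", side), len)
    } else if (length(side) == length(labs) - 1) {
      # complement is the reference tip alone: also a pendant branch
      if (include_trivial) add(paste0("tip:", ref), len)
    } else if (length(side) >= 2) {
      add(paste(sort(side), collapse = "\u001f"), len)
    }
  }
  keys <- ls(acc)
  setNames(vapply(keys, get, numeric(1), envir = acc), keys)
}
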