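#' Agglomerative clustering of a distance matrix into an ultrametric tree
#'
#' Wraps `stats::hclust` (Lance-Williams updates) and converts the result to
#' a rooted ultrametric `"phylo"` whose node heights are merge heights:
#' each merge at distance d sits at height d/2, so the tip-to-tip
#' cophenetic distance of the output tree equals the cophenetic distance of
#' the clustering (2 x merge height). Ward is the squared-distance
#' convention (`ward.D2`).
#'
#' @param dist A symmetric labeled distance matrix.
#' @param method One of `"single"`, `"complete"`, `"upgma"`, `"wpgma"`,
#'   `"ward"`.
#' @return An ultrametric rooted `"phylo"` object.
#' @export
linkage <- function(dist, method = "upgma") {
  dist <- check_dist_matrix(dist)
  if (nrow(dist) < 2) stop("need at least two species", call. = FALSE)
  hmethod <- switch(method,
    single = "single", complete = "complete", upgma = "average",
    wpgma = "mcquitty", ward = "ward.D2",
    stop("unknown clustering method '", method, "'", call. = FALSE)
  )
  hc <- stats::hclust(stats::as.dist(dist), method = hmethod)
  hclust_as_phylo(hc)
}

# hclust -> rooted phylo with node height = merge height / 2 and branch
# length = parent height - child height. Internal nodes are numbered so the
# root (last merge) is ntip + 1, as ape requires.
hclust_as_phylo <- function(hc) {
  n <- length(hc$labels)
  if (n == 1) stop("cannot build a tree from one element", call. = FALSE)
  nmerge <- nrow(hc$merge)
  node_of_merge <- function(i) n + (nmerge - i) + 1L  # last merge -> n+1
  heights <- hc$height / 2
  edge <- matrix(0L, 2L * nmerge, 2)
  elen <- numeric(2L * nmerge)
  k <- 0L
  for (i in seq_len(nmerge)) {
    parent <- node_of_merge(i)
    for (child_code in hc$merge[i, ]) {
      k <- k + 1L
      if (child_code < 0) {
        edge[k, ] <- c(parent, -child_code)
        elen[k] <- heights[i]
      } else {
        edge[k, ] <- c(parent, node_of_merge(child_code))
        elen[k] <- heights[i] - heights[child_code]
      }
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = hc$labels, Nnode = nmerge),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_tree(tree)
}

#' Cophenetic correlation between a distance matrix and a tree
#'
#' Pearson correlation over the n(n-1)/2 unordered species pairs of the
#' input distance against the tree's cophenetic distance; the criterion by
#' which a clustering method is judged to represent the original distances.
#'
#' @param dist A symmetric labeled distance matrix.
#' @param tree A `"phylo"` on the same species set.
#' @return The correlation (a single number in \[-1, 1\]).
#' @export
cophenetic_correlation <- function(dist, tree) {
  dist <- check_dist_matrix(dist)
  cm <- align_dist_matrices(dist, cophenetic_matrix(tree))
  x <- lower_tri(dist)
  y <- lower_tri(cm)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in distances; cophenetic correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Choose the clustering method that best preserves the input distances
#'
#' Runs every candidate linkage and retains the one with the highest
#' cophenetic correlation; ties go to the earliest method in the supplied
#' order.
#'
#' @param dist A symmetric labeled distance matrix.
#' @param methods Candidate methods, tried in order.
#' @return A list: `method` (the winner), `tree` (its dendrogram as a
#'   `"phylo"`), and `correlations` (a data.frame of method, r).
#' @export
select_clustering <- function(dist,
                              methods = c("single", "complete", "upgma",
                                          "wpgma", "ward")) {
  if (!length(methods)) stop("need at least one method", call. = FALSE)
  trees <- lapply(methods, function(m) linkage(dist, m))
  r <- vapply(trees, function(tr) cophenetic_correlation(dist, tr), numeric(1))
  # first method within float tolerance of the maximum wins ties
  best <- which(r >= max(r) - 1e-12)[1]
  list(method = methods[best], tree = trees[[best]],
       correlations = data.frame(method = methods, r = r, stringsAsFactors = FALSE))
}
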