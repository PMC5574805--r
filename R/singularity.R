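# Species singularity: fair-proportion evolutionary distinctiveness on the
# phylogeny (PS) and on the functional tree (FS), and their correlation.

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch contributes its length divided by the number of tip species
#' descending from it; a species' score is the sum of those contributions
#' over all branches on its root-to-tip path (including its own pendant
#' branch). Scores therefore sum exactly to the total tree length.
#' Computed on the rooted tree as stored; polytomies are handled natively.
#'
#' @param tree A `"phylo"` object with >= 2 tips and positive total length.
#' @param exclude_root_edge Drop a root edge (`tree$root.edge`) if present
#'   rather than adding it to every species (default `TRUE`; an arbitrary
#'   rooting of a supertree should not shift all scores equally).
#' @return Named numeric vector of ED values, one per species.
#' @export
#' @examples
#' tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' evolutionary_distinctiveness(tr)  # each tip: 1 + 1/2 = 1.5
evolutionary_distinctiveness <- function(tree, exclude_root_edge = TRUE) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("need at least 2 tips", call. = FALSE)
  if (sum(tree$edge.length) <= 0) stop("tree has zero total length", call. = FALSE)
  ed <- setNames(numeric(ntip), tree$tip.label)
  pp <- ape::prop.part(tree)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) child else pp[[child - ntip]]
    ed[tips] <- ed[tips] + tree$edge.length[e] / length(tips)
  }
  if (!exclude_root_edge && !is.null(tree$root.edge)) {
    ed <- ed + tree$root.edge / ntip
  }
  ed
}

#' Correlation between phylogenetic and functional singularity
#'
#' Pearson correlation between per-species ED on the phylogeny (PS) and on
#' the functional tree (FS), aligned by species label.
#'
#' @param ps,fs Named ED vectors from [evolutionary_distinctiveness()] on
#'   the same species set.
#' @return A `"phylofunc_test"` (two-sided Pearson test).
#' @export
singularity_correlation <- function(ps, fs) {
  if (is.null(names(ps)) || is.null(names(fs))) {
    stop("ED vectors must be named by species", call. = FALSE)
  }
  pearson_correlation_test(ps, fs)
}

#' Quartile bins of singularity scores
#'
#' Bins species by the empirical quartiles of their scores (bin 1 = lowest
#' 25%); values tied with a quartile boundary go to the lower bin, so a
#' constant vector is all bin 1.
#'
#' @param scores Named numeric vector with >= 4 species.
#' @return Named integer vector of bins in 1..4.
#' @export
quartile_bins <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 species", call. = FALSE)
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  bins <- 1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
  setNames(as.integer(bins), names(scores))
}
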