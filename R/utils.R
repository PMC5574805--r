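# Internal helpers shared across modules.

#' @importFrom stats cor cor.test cophenetic hclust as.dist quantile median
#'   rnorm rexp runif chisq.test kruskal.test setNames complete.cases sd
#' @importFrom utils read.table write.table combn
NULL

# Validate a square labeled distance matrix: symmetric, zero diagonal,
# non-negative, unique labels. Returns the matrix with dimnames intact.
check_dist_matrix <- function(m, name = "distance matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(name, " must be a square matrix", call. = FALSE)
  }
  labels <- rownames(m)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop(name, " must carry unique non-empty row/column labels", call. = FALSE)
  }
  if (!identical(labels, colnames(m))) {
    stop(name, " row and column labels differ", call. = FALSE)
  }
  if (anyNA(m)) stop(name, " contains NA", call. = FALSE)
  if (any(m < 0)) stop(name, " contains negative entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop(name, " is not symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop(name, " has a nonzero diagonal", call. = FALSE)
  m
}

# Lower-triangle vector of a square matrix (unordered off-diagonal pairs).
lower_tri <- function(m) m[lower.tri(m)]

# Reorder d2 to the label order of d1; labels must match as sets.
align_dist_matrices <- function(d1, d2) {
  l1 <- rownames(d1)
  l2 <- rownames(d2)
  if (!setequal(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    stop("species sets differ: ",
         if (length(only1)) paste0("only in first: ", paste(only1, collapse = ", "), "; ") else "",
         if (length(only2)) paste0("only in second: ", paste(only2, collapse = ", ")) else "",
         call. = FALSE)
  }
  d2[l1, l1, drop = FALSE]
}

# All permutations of 1..n as a list (n! entries); used by exhaustive
# permutation tests at small n.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

# Derive a bounded child seed from a master seed (keeps within 32-bit range).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}
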