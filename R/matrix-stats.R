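# Inferential machinery: Mantel permutation test and Pearson correlation.

new_test_result <- function(method, statistic, p_value, n_permutations = 0L,
                            seed = NA_integer_, alternative, n) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed,
                 alternative = alternative, n = n),
            class = "phylofunc_test")
}

#' @export
print.phylofunc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s", x$method, x$statistic,
              x$p_value, x$alternative))
  if (x$n_permutations > 0) cat(sprintf(", %d permutations", x$n_permutations))
  cat(sprintf(", n = %d)\n", x$n))
  invisible(x)
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation over the unordered off-diagonal
#' pairs; the null distribution is built by simultaneously permuting the
#' rows and columns of the second matrix. The alternative is one-sided
#' (greater), matching the concordance question, and the p-value uses the
#' add-one convention `(1 + #\{perm >= obs\}) / (1 + n_perm)`. Matrices are
#' aligned by species label, never by position.
#'
#' @param d1,d2 Symmetric labeled distance matrices on the same species.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for reproducible permutations.
#' @param exhaustive Enumerate all n! label permutations instead of
#'   sampling (only sensible for n <= 7); the p-value is then the exact
#'   proportion of permutations with statistic >= observed.
#' @return A `"phylofunc_test"` with statistic, p-value, permutation count
#'   and seed.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  d1 <- check_dist_matrix(d1, "d1")
  d2 <- check_dist_matrix(d2, "d2")
  d2 <- align_dist_matrices(d1, d2)
  n <- nrow(d1)
  if (n < 4) stop("Mantel test needs at least 4 species", call. = FALSE)
  x <- lower_tri(d1)
  if (stats::sd(x) == 0 || stats::sd(lower_tri(d2)) == 0) {
    stop("zero variance in off-diagonal distances", call. = FALSE)
  }
  obs <- stats::cor(x, lower_tri(d2))
  stat_for <- function(perm) stats::cor(x, lower_tri(d2[perm, perm]))
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_null <- vapply(perms, stat_for, numeric(1))
    p <- mean(stats_null >= obs - 1e-12)
    return(new_test_result("mantel", obs, p, length(perms), NA_integer_,
                           "greater", n))
  }
  if (!is.null(seed)) set.seed(seed)
  stats_null <- vapply(seq_len(n_perm), function(i) stat_for(sample.int(n)),
                       numeric(1))
  p <- (1 + sum(stats_null >= obs)) / (1 + n_perm)
  new_test_result("mantel", obs, p, as.integer(n_perm),
                  if (is.null(seed)) NA_integer_ else as.integer(seed),
                  "greater", n)
}

#' Pearson correlation test between two aligned vectors
#'
#' Product-moment correlation with the two-sided t-distribution p-value on
#' n - 2 degrees of freedom. If both vectors are named they are aligned by
#' name first; mismatching name sets are an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `"phylofunc_test"`.
#' @export
pearson_correlation_test <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) {
      stop("name sets differ; only in x: ",
           paste(setdiff(names(x), names(y)), collapse = ", "),
           "; only in y: ", paste(setdiff(names(y), names(x)), collapse = ", "),
           call. = FALSE)
    }
    y <- y[names(x)]
  }
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  new_test_result("pearson", unname(ct$estimate), ct$p.value, 0L, NA_integer_,
                  "two.sided", length(x))
}
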