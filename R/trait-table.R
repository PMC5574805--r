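#' Construct a typed species-by-trait table
#'
#' The table couples trait values with a schema declaring, for every trait,
#' its measurement kind (`quantitative`, `categorical` or `binary`) and the
#' trait group it belongs to (habitat / trophic / behavior in the shark
#' application). Missingness is explicit: `NA` cells are tracked and
#' propagate into Gower weights rather than being imputed.
#'
#' @param data A data.frame with species as row names and one column per
#'   trait. Quantitative columns must be numeric; categorical/binary columns
#'   are coerced to character.
#' @param kind Named character vector mapping every trait to its kind.
#' @param group Named character vector mapping every trait to its group.
#' @return An object of class `"trait_table"`.
#' @export
trait_table <- function(data, kind, group) {
  stopifnot(is.data.frame(data))
  species <- rownames(data)
  if (is.null(species) || anyDuplicated(species)) {
    stop("species labels (row names) must be present and unique", call. = FALSE)
  }
  traits <- colnames(data)
  missing_kind <- setdiff(traits, names(kind))
  if (length(missing_kind)) {
    stop("schema does not cover trait(s): ", paste(missing_kind, collapse = ", "),
         call. = FALSE)
  }
  missing_group <- setdiff(traits, names(group))
  if (length(missing_group)) {
    stop("schema gives no group for trait(s): ", paste(missing_group, collapse = ", "),
         call. = FALSE)
  }
  kind <- kind[traits]
  group <- group[traits]
  bad <- !kind %in% c("quantitative", "categorical", "binary")
  if (any(bad)) {
    stop("unknown trait kind(s): ", paste(unique(kind[bad]), collapse = ", "),
         call. = FALSE)
  }
  for (tr in traits) {
    if (kind[[tr]] == "quantitative") {
      v <- data[[tr]]
      if (!is.numeric(v)) {
        vv <- suppressWarnings(as.numeric(as.character(v)))
        broken <- !is.na(as.character(v)) & nzchar(trimws(as.character(v))) & is.na(vv)
        if (any(broken)) {
          stop("trait '", tr, "': non-numeric value(s) under a quantitative trait (",
               paste(unique(as.character(v)[broken]), collapse = ", "), ")",
               call. = FALSE)
        }
        data[[tr]] <- vv
      }
      if (any(is.infinite(data[[tr]]))) {
        stop("trait '", tr, "': non-finite value", call. = FALSE)
      }
    } else {
      data[[tr]] <- as.character(data[[tr]])
      data[[tr]][!is.na(data[[tr]]) & !nzchar(trimws(data[[tr]]))] <- NA
      if (kind[[tr]] == "binary") {
        lev <- unique(data[[tr]][!is.na(data[[tr]])])
        if (length(lev) > 2) {
          stop("trait '", tr, "': binary trait with ", length(lev),
               " observed levels", call. = FALSE)
        }
      }
    }
  }
  structure(list(data = data, kind = kind, group = group), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$data), "species x", ncol(x$data), "traits\n")
  cat("  kinds: ", paste(sprintf("%s=%d", names(table(x$kind)), table(x$kind)),
                         collapse = ", "), "\n", sep = "")
  cat("  groups: ", paste(sprintf("%s=%d", names(table(x$group)), table(x$group)),
                          collapse = ", "), "\n", sep = "")
  cat("  missing cells:", sum(is.na(as.matrix(x$data))), "\n")
  invisible(x)
}

#' Species labels of a trait table
#' @param table A `"trait_table"`.
#' @return Character vector of species labels.
#' @export
species_labels <- function(table) rownames(table$data)

#' Read a trait schema from YAML
#'
#' The schema file maps each trait name to `{kind, group}`, e.g.
#' `trophic_level: {kind: quantitative, group: trophic}`.
#'
#' @param path YAML file path.
#' @return List with named character vectors `kind` and `group`.
#' @export
read_trait_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty schema", call. = FALSE)
  kind <- vapply(raw, function(x) x$kind %||% NA_character_, character(1))
  group <- vapply(raw, function(x) x$group %||% NA_character_, character(1))
  if (anyNA(kind) || anyNA(group)) {
    stop("every schema entry needs both `kind` and `group`", call. = FALSE)
  }
  list(kind = kind, group = group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trait schema to YAML
#' @param table A `"trait_table"` whose schema is exported.
#' @param path Output YAML path.
#' @export
write_trait_schema <- function(table, path) {
  entries <- lapply(colnames(table$data), function(tr) {
    list(kind = unname(table$kind[[tr]]), group = unname(table$group[[tr]]))
  })
  names(entries) <- colnames(table$data)
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Read a species-by-trait CSV/TSV file into a typed table
#'
#' The first column holds species labels; remaining columns are traits and
#' must all be covered by the schema. Literal `NA` and empty cells are
#' missing values; any other non-numeric cell under a quantitative trait is
#' an error, never a silent `NA`.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a header row.
#' @param schema A list with `kind` and `group` named vectors, as returned
#'   by [read_trait_schema()].
#' @return A `"trait_table"`.
#' @export
read_trait_table <- function(path, schema) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("NA", ""),
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("expected a species column plus at least one trait", call. = FALSE)
  sp <- df[[1]]
  dup <- sp[duplicated(sp)]
  if (length(dup)) {
    stop("duplicated species row(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df <- df[, -1, drop = FALSE]
  rownames(df) <- sp
  trait_table(df, schema$kind, schema$group)
}

#' Retain only species with complete trait records
#'
#' Produces the "NA-excluded" subdatabase: species with any missing value in
#' any retained trait are removed; the trait set is unchanged.
#'
#' @param table A `"trait_table"`.
#' @return A `"trait_table"` holding only fully observed species.
#' @export
drop_na_species <- function(table) {
  keep <- stats::complete.cases(table$data)
  if (!any(keep)) stop("no species is fully observed", call. = FALSE)
  trait_table(table$data[keep, , drop = FALSE], table$kind, table$group)
}

#' Restrict a trait table to one trait group
#'
#' @param table A `"trait_table"`.
#' @param group A group label present in the schema.
#' @return A `"trait_table"` with the same species and only that group's
#'   traits. Species whose rows become all-missing are retained; their
#'   pairwise Gower distances may then be undefined (see
#'   [gower_distance()]).
#' @export
split_by_group <- function(table, group) {
  if (!group %in% table$group) {
    stop("unknown trait group '", group, "'; available: ",
         paste(unique(table$group), collapse = ", "), call. = FALSE)
  }
  keep <- names(table$group)[table$group == group]
  trait_table(table$data[, keep, drop = FALSE], table$kind[keep], table$group[keep])
}

#' Pairwise trait association screen
#'
#' Before distances are trusted, trait redundancy is screened with the test
#' matched to each pair of measurement kinds: Spearman rank correlation for
#' two quantitative traits, Cramer's V with a chi-squared p-value for two
#' discrete traits, and Kruskal-Wallis for a quantitative/discrete pair.
#' Pairs with too few complete observations (or a constant trait) are
#' reported as untestable rather than erroring.
#'
#' @param table A `"trait_table"` with at least two traits.
#' @param alpha Significance level used to flag associated pairs.
#' @return A data.frame with one row per unordered trait pair: `trait1`,
#'   `trait2`, `test`, `statistic`, `p_value`, `flagged`.
#' @export
trait_correlation_screen <- function(table, alpha = 0.05) {
  traits <- colnames(table$data)
  if (length(traits) < 2) stop("need at least two traits", call. = FALSE)
  pairs <- utils::combn(traits, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    t1 <- pairs[1, k]; t2 <- pairs[2, k]
    x <- table$data[[t1]]; y <- table$data[[t2]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    k1 <- table$kind[[t1]]; k2 <- table$kind[[t2]]
    quant1 <- k1 == "quantitative"; quant2 <- k2 == "quantitative"
    res <- data.frame(trait1 = t1, trait2 = t2, test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_, flagged = FALSE,
                      stringsAsFactors = FALSE)
    n_lev <- function(v) length(unique(v))
    if (sum(ok) < 3 || n_lev(x) < 2 || n_lev(y) < 2) {
      res$test <- "untestable"
      return(res)
    }
    out <- tryCatch({
      if (quant1 && quant2) {
        ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
        list(test = "spearman", statistic = unname(ct$estimate), p = ct$p.value)
      } else if (!quant1 && !quant2) {
        tab <- base::table(x, y)
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        v <- sqrt(unname(ct$statistic) / (sum(tab) * (min(dim(tab)) - 1)))
        list(test = "cramers_v", statistic = v, p = ct$p.value)
      } else {
        quant <- if (quant1) x else y
        fac <- if (quant1) y else x
        if (n_lev(fac) < 2 || n_lev(quant) < 2) return(NULL)
        kt <- stats::kruskal.test(quant, as.factor(fac))
        list(test = "kruskal_wallis", statistic = unname(kt$statistic), p = kt$p.value)
      }
    }, error = function(e) NULL)
    if (is.null(out) || is.na(out$p)) {
      res$test <- "untestable"
      return(res)
    }
    res$test <- out$test
    res$statistic <- out$statistic
    res$p_value <- out$p
    res$flagged <- out$p < alpha
    res
  })
  do.call(rbind, rows)
}

#' Gower distance matrix for mixed-type traits
#'
#' For species i and j, `d(i,j) = sum_k w_ijk d_ijk / sum_k w_ijk` with
#' per-trait contribution `|x_ik - x_jk| / range_k` for quantitative traits
#' (range over the observed values of the table at hand) and 0/1 mismatch
#' for categorical and binary traits; the weight `w_ijk` is 0 when either
#' value is missing, else 1 (all traits weighted equally). Entries lie in
#' \[0, 1\].
#'
#' @param table A `"trait_table"` with at least two species.
#' @return A symmetric labeled distance matrix with zero diagonal.
#' @export
#' @examples
#' tt <- trait_table(
#'   data.frame(size = c(0, 5, 10), row.names = c("s1", "s2", "s3")),
#'   kind = c(size = "quantitative"), group = c(size = "trophic")
#' )
#' gower_distance(tt)["s1", "s2"]  # 0.5
gower_distance <- function(table) {
  n <- nrow(table$data)
  if (n < 2) stop("need at least two species", call. = FALSE)
  sp <- rownames(table$data)
  S <- matrix(0, n, n)
  W <- matrix(0, n, n)
  for (tr in colnames(table$data)) {
    v <- table$data[[tr]]
    obs <- !is.na(v)
    w <- outer(obs, obs, `&`)
    if (table$kind[[tr]] == "quantitative") {
      if (!any(obs)) next
      rng <- diff(range(v[obs]))
      if (rng == 0) {
        warning("quantitative trait '", tr, "' has zero range; dropped from Gower",
                call. = FALSE)
        next
      }
      d <- abs(outer(v, v, `-`)) / rng
    } else {
      d <- outer(v, v, `!=`)
    }
    d[!w] <- 0
    S <- S + d
    W <- W + w
  }
  diag(W) <- 1  # self-distance is 0 by definition
  undef <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
  if (nrow(undef)) {
    pairs <- apply(undef, 1, function(ij) paste0(sp[ij[1]], "/", sp[ij[2]]))
    stop("Gower distance undefined (no shared observed trait) for pair(s): ",
         paste(utils::head(pairs, 10), collapse = ", "),
         if (length(pairs) > 10) " ..." else "", call. = FALSE)
  }
  D <- S / W
  diag(D) <- 0
  D <- (D + t(D)) / 2  # symmetrize away float jitter
  dimnames(D) <- list(sp, sp)
  check_dist_matrix(D, "Gower matrix")
}

# Greedily remove the species involved in the most undefined Gower pairs
# until every remaining pair shares at least one observed trait. Used by the
# pipeline so group subtables with heavy missingness stay analyzable; the
# removed species are reported for the run manifest.
resolve_undefined_pairs <- function(table) {
  repeat {
    obs <- !is.na(as.matrix(table$data))
    shared <- obs %*% t(obs)
    diag(shared) <- 1
    bad <- rowSums(shared == 0)
    if (!any(bad > 0)) break
    drop <- rownames(table$data)[which.max(bad)]
    keep <- setdiff(rownames(table$data), drop)
    table <- trait_table(table$data[keep, , drop = FALSE], table$kind, table$group)
  }
  table
}
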