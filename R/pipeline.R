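# End-to-end orchestration: for each model (full, NA-excluded, and one per
# trait group) run the four analytical steps against the phylogeny and
# collect results shaped like the study's Tables 2-5.

#' Run the full phylogeny-function concordance analysis
#'
#' For each model — `full` (all traits), `na_excluded` (species with
#' complete records only), and one model per trait group — the pipeline:
#' (1) computes the Gower distance and selects the best clustering method
#' by cophenetic correlation to build the functional tree; (2) runs a
#' Mantel test between the phylogenetic cophenetic matrix and the Gower
#' matrix; (3) compares the two trees on normalized branch lengths (TD,
#' RTD, branch score); (4) measures the phylogenetic signal of Brownian
#' functional identity (Moran's I, Abouheif's Cmean); and (5) computes
#' evolutionary distinctiveness on both trees, their Pearson correlation,
#' and functional-singularity quartile bins. Species are pruned to the
#' intersection of tree and table (plus, per model, any species whose
#' remaining trait rows leave Gower undefined); every pruning is recorded
#' in the model's manifest. All randomness derives from `config$seed`, so
#' identical configs reproduce every number exactly.
#'
#' @param phylo The phylogenetic tree (`"phylo"`).
#' @param traits A `"trait_table"`.
#' @param config List of run settings: `seed` (mandatory), `n_perm`
#'   (default 999), `n_replicates` (Brownian replicates, default 100),
#'   `methods` (clustering candidates, default all five).
#' @return A list of class `"phylofunc_report"`: per-model results plus
#'   `config`.
#' @export
run_full_analysis <- function(phylo, traits, config = list()) {
  phylo <- validate_tree(phylo)
  stopifnot(inherits(traits, "trait_table"))
  cfg <- utils::modifyList(list(seed = NULL, n_perm = 999, n_replicates = 100,
                                methods = c("single", "complete", "upgma",
                                            "wpgma", "ward")),
                           config)
  if (is.null(cfg$seed)) stop("config$seed is mandatory", call. = FALSE)
  groups <- unique(unname(traits$group))
  models <- c("full", "na_excluded", groups)
  results <- vector("list", length(models))
  names(results) <- models
  for (mi in seq_along(models)) {
    model <- models[mi]
    results[[model]] <- tryCatch(
      run_one_model(phylo, traits, model, cfg, derive_seed(cfg$seed, mi)),
      error = function(e) {
        stop("model '", model, "': ", conditionMessage(e), call. = FALSE)
      })
  }
  structure(list(models = results, config = cfg), class = "phylofunc_report")
}

run_one_model <- function(phylo, traits, model, cfg, seed) {
  tab <- switch(model,
    full = traits,
    na_excluded = drop_na_species(traits),
    split_by_group(traits, model))
  manifest <- list(model = model, seed = seed)
  # prune to the tree/table intersection
  shared <- intersect(phylo$tip.label, species_labels(tab))
  manifest$dropped_not_in_tree <- setdiff(species_labels(tab), shared)
  manifest$dropped_not_in_table <- setdiff(phylo$tip.label, shared)
  tab <- trait_table(tab$data[shared, , drop = FALSE], tab$kind, tab$group)
  # drop species whose remaining rows leave Gower undefined
  tab2 <- resolve_undefined_pairs(tab)
  manifest$dropped_undefined_gower <- setdiff(species_labels(tab),
                                              species_labels(tab2))
  tab <- tab2
  sp <- species_labels(tab)
  if (length(sp) < 4) stop("fewer than 4 usable species", call. = FALSE)
  tree <- ape::keep.tip(phylo, sp)
  manifest$n_species <- length(sp)

  gower <- suppressWarnings(gower_distance(tab))
  sel <- select_clustering(gower, cfg$methods)
  phylo_d <- cophenetic_matrix(tree)
  mantel <- mantel_test(phylo_d, gower, n_perm = cfg$n_perm,
                        seed = derive_seed(seed, 1))
  comparison <- compare_trees(tree, sel$tree, normalize = TRUE)
  signal <- functional_identity_signal(tree, sel$tree,
                                       n_replicates = cfg$n_replicates,
                                       n_perm = cfg$n_perm,
                                       seed = derive_seed(seed, 2))
  ps <- evolutionary_distinctiveness(tree)
  fs <- evolutionary_distinctiveness(sel$tree)
  singularity <- singularity_correlation(ps, fs)
  list(manifest = manifest,
       clustering = sel[c("method", "correlations")],
       functional_tree = sel$tree,
       mantel = mantel,
       comparison = comparison,
       signal = signal,
       singularity = list(test = singularity, ps = ps, fs = fs,
                          fs_quartile = quartile_bins(fs)))
}

#' @export
print.phylofunc_report <- function(x, ...) {
  cat("phylofunc report:", length(x$models), "models\n")
  for (m in names(x$models)) {
    r <- x$models[[m]]
    cat(sprintf(
      "  %-12s n=%3d  clust=%-8s mantel r=%6.3f (p=%.3g)  RTD=%.3f  I=%.3f  Cmean=%.3f  cor(PS,FS)=%6.3f (p=%.3g)\n",
      m, r$manifest$n_species, r$clustering$method,
      r$mantel$statistic, r$mantel$p_value, r$comparison$rtd,
      r$signal$moran_i$observed, r$signal$abouheif_cmean$observed,
      r$singularity$test$statistic, r$singularity$test$p_value))
  }
  invisible(x)
}

#' Tabulate a report in the shape of the study's result tables
#'
#' @param report A `"phylofunc_report"`.
#' @return A list of four data.frames: `mantel` (model, r, p),
#'   `tree_comparison` (model, td, rtd, bls, bls_squared, n), `signal`
#'   (model, moran_i, cmean, and their median permutation p-values), and
#'   `singularity` (model, cor, p).
#' @export
report_tables <- function(report) {
  ms <- report$models
  model <- names(ms)
  list(
    mantel = data.frame(
      model = model,
      r = vapply(ms, function(r) r$mantel$statistic, numeric(1)),
      p = vapply(ms, function(r) r$mantel$p_value, numeric(1)),
      row.names = NULL),
    tree_comparison = data.frame(
      model = model,
      td = vapply(ms, function(r) r$comparison$td, numeric(1)),
      rtd = vapply(ms, function(r) r$comparison$rtd, numeric(1)),
      bls = vapply(ms, function(r) r$comparison$bls, numeric(1)),
      bls_squared = vapply(ms, function(r) r$comparison$bls_squared, numeric(1)),
      n = vapply(ms, function(r) r$comparison$n, numeric(1)),
      row.names = NULL),
    signal = data.frame(
      model = model,
      moran_i = vapply(ms, function(r) r$signal$moran_i$observed, numeric(1)),
      moran_i_p = vapply(ms, function(r) r$signal$moran_i$p_median, numeric(1)),
      cmean = vapply(ms, function(r) r$signal$abouheif_cmean$observed, numeric(1)),
      cmean_p = vapply(ms, function(r) r$signal$abouheif_cmean$p_median, numeric(1)),
      row.names = NULL),
    singularity = data.frame(
      model = model,
      cor = vapply(ms, function(r) r$singularity$test$statistic, numeric(1)),
      p = vapply(ms, function(r) r$singularity$test$p_value, numeric(1)),
      row.names = NULL)
  )
}

#' Serialize a report to disk
#'
#' Writes the four result tables as TSV, the per-model functional trees as
#' newick, and a machine-readable JSON of every statistic and manifest.
#'
#' @param report A `"phylofunc_report"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(report)
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (m in names(report$models)) {
    write_newick(report$models[[m]]$functional_tree,
                 file.path(dir, paste0("functional_tree_", m, ".nwk")))
  }
  json <- lapply(report$models, function(r) {
    list(manifest = r$manifest,
         clustering = r$clustering,
         mantel = unclass(r$mantel),
         comparison = r$comparison,
         signal = list(
           moran_i = r$signal$moran_i[c("observed", "p_median", "n_replicates",
                                        "n_permutations", "seed")],
           abouheif_cmean = r$signal$abouheif_cmean[c("observed", "p_median",
                                                      "n_replicates",
                                                      "n_permutations", "seed")]),
         singularity = list(test = unclass(r$singularity$test),
                            ps = as.list(r$singularity$ps),
                            fs = as.list(r$singularity$fs),
                            fs_quartile = as.list(r$singularity$fs_quartile)))
  })
  jsonlite::write_json(list(config = report$config, models = json),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
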