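# Synthetic study inputs: Yule trees, mixed-type trait tables whose
# phylogenetic signal is tunable from Brownian-conservative to fully
# shuffled to convergent, and injectable missingness.

#' Default mixed-type trait schema
#'
#' Ten traits mirroring a marine functional-trait database: a habitat block
#' (depth range, migration, shelf/slope, offshore/coastal, water
#' preference), a trophic block (water-column position, trophic level,
#' maximum size) and a behavior block (nocturnal, schooling). Kinds are
#' quantitative for continuously measured traits, binary for yes/no traits
#' and categorical for the rest.
#'
#' @return A list with named character vectors `kind` and `group`, as
#'   [read_trait_schema()] returns.
#' @export
default_trait_schema <- function() {
  kind <- c(
    depth_range = "quantitative", migration = "binary",
    shelf_slope = "categorical", offshore_coastal = "categorical",
    water_preference = "categorical",
    water_column = "categorical", trophic_level = "quantitative",
    max_size = "quantitative",
    nocturnal = "binary", schooling = "binary"
  )
  group <- c(
    depth_range = "habitat", migration = "habitat", shelf_slope = "habitat",
    offshore_coastal = "habitat", water_preference = "habitat",
    water_column = "trophic", trophic_level = "trophic", max_size = "trophic",
    nocturnal = "behavior", schooling = "behavior"
  )
  list(kind = kind, group = group)
}

#' Scenario configuration for synthetic data
#'
#' Bundles every knob of the generator: species count, Yule birth rate,
#' trait schema, signal mode (`conservative` = Brownian trait evolution,
#' `shuffled` = per-trait random permutation across species, `convergent` =
#' trait states set by an environment grouping drawn independently of the
#' tree), Brownian rate, per-cell missingness rate, number of categorical
#' levels and of convergent environments, and the mandatory seed.
#'
#' @param n_species Number of tips (>= 4).
#' @param birth_rate Yule speciation rate (> 0).
#' @param schema Trait schema (default [default_trait_schema()]).
#' @param signal_mode One of `"conservative"`, `"shuffled"`, `"convergent"`.
#' @param sigma2 Brownian rate for latent trait values.
#' @param missing_rate Per-cell missingness probability in \[0, 1).
#' @param n_cat_levels Levels per categorical trait (default 3).
#' @param n_env Environment groups in convergent mode (default 3).
#' @param seed Integer seed (mandatory).
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_species = 50, birth_rate = 1,
                            schema = default_trait_schema(),
                            signal_mode = c("conservative", "shuffled", "convergent"),
                            sigma2 = 1, missing_rate = 0,
                            n_cat_levels = 3, n_env = 3, seed) {
  signal_mode <- match.arg(signal_mode)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_species >= 4, birth_rate > 0, sigma2 > 0,
            missing_rate >= 0, missing_rate < 1, n_cat_levels >= 2)
  if (!length(schema$kind)) stop("schema with zero traits", call. = FALSE)
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 schema = schema, signal_mode = signal_mode, sigma2 = sigma2,
                 missing_rate = missing_rate,
                 n_cat_levels = as.integer(n_cat_levels),
                 n_env = as.integer(n_env), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Forward simulation: starting from the root split (two lineages), with k
#' lineages the waiting time to the next speciation is Exponential(k x
#' birth_rate) and a uniformly chosen lineage splits, until n tips exist;
#' all tips then extend to the present (one further Exponential(n x
#' birth_rate) wait), giving an ultrametric tree. Tips are labeled
#' `sp0001`, `sp0002`, ...
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage (> 0).
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @return An ultrametric `"phylo"` with n tips.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed) {
  stopifnot(n >= 2, birth_rate > 0)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n)
  # lineages: parent internal node id and birth time of the pending edge
  parent <- c(1L, 1L)           # internal node ids, root = 1
  start <- c(0, 0)
  node_time <- 0                # birth time per internal node
  next_node <- 2L
  t_now <- 0
  edges_p <- integer(0); edges_c <- integer(0); edges_len <- numeric(0)
  while (length(parent) < n) {
    k <- length(parent)
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    j <- sample.int(k, 1)
    node_time <- c(node_time, t_now)
    edges_p <- c(edges_p, parent[j]); edges_c <- c(edges_c, next_node)
    edges_len <- c(edges_len, t_now - start[j])
    parent <- c(parent[-j], next_node, next_node)
    start <- c(start[-j], t_now, t_now)
    next_node <- next_node + 1L
  }
  t_present <- t_now + stats::rexp(1, rate = n * birth_rate)
  ntip <- n
  # assemble phylo: tips 1..n, internal node id i -> ntip + i
  tip_edges_p <- parent
  tip_edges_len <- t_present - start
  edge <- rbind(cbind(ntip + edges_p, ntip + edges_c),
                cbind(ntip + tip_edges_p, seq_len(ntip)))
  elen <- c(edges_len, tip_edges_len)
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = sprintf("sp%04d", seq_len(ntip)),
                         Nnode = next_node - 1L),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_tree(tree)
}

#' Simulate a mixed-type trait table on a tree
#'
#' Every trait starts from a latent Brownian simulation along the tree
#' (rate `sigma2`), so a single heritable process controls signal across
#' all trait kinds. Quantitative traits keep the latent values; binary
#' traits threshold them at the median; categorical traits cut them at
#' empirical quantiles into `n_cat_levels` states. `signal_mode` then sets
#' the phylogenetic structure: `conservative` leaves values as simulated;
#' `shuffled` independently permutes each trait across species (no
#' signal); `convergent` replaces the latent values by environment-group
#' means (groups drawn independently of the tree) plus small within-group
#' noise, so phylogenetically distant species share states. Missingness is
#' injected cell-wise at `missing_rate` via [inject_missing()].
#'
#' @param tree A `"phylo"` giving the species.
#' @param config A `"scenario_config"`; its seed drives all randomness.
#' @return A `"trait_table"` (with an `environment` attribute in
#'   convergent mode).
#' @export
simulate_trait_table <- function(tree, config) {
  stopifnot(inherits(config, "scenario_config"))
  tree <- validate_tree(tree)
  sp <- tree$tip.label
  n <- length(sp)
  schema <- config$schema
  traits <- names(schema$kind)
  if (!length(traits)) stop("schema with zero traits", call. = FALSE)
  set.seed(config$seed)
  env <- NULL
  if (config$signal_mode == "convergent") {
    env <- setNames(sample.int(config$n_env, n, replace = TRUE), sp)
  }
  depth <- max(cophenetic_matrix(tree)) / 2
  cols <- vector("list", length(traits))
  names(cols) <- traits
  latents <- brownian_simulate(tree, sigma2 = config$sigma2, n_rep = length(traits))
  if (is.null(dim(latents))) {
    latents <- base::matrix(latents, ncol = 1, dimnames = list(names(latents), NULL))
  }
  for (k in seq_along(traits)) {
    z <- latents[sp, k]
    if (config$signal_mode == "shuffled") {
      z <- setNames(sample(z), sp)
    } else if (config$signal_mode == "convergent") {
      mu <- stats::rnorm(config$n_env, 0, sqrt(config$sigma2 * depth))
      z <- setNames(mu[env] + stats::rnorm(n, 0, 0.15 * sqrt(config$sigma2 * depth)), sp)
    }
    cols[[traits[k]]] <- switch(schema$kind[[traits[k]]],
      quantitative = as.numeric(z),
      binary = ifelse(z > stats::median(z), "yes", "no"),
      categorical = as.character(cut(z,
        breaks = c(-Inf, stats::quantile(z, seq_len(config$n_cat_levels - 1) /
                                              config$n_cat_levels), Inf),
        labels = paste0("state", seq_len(config$n_cat_levels)))),
      stop("unknown kind"))
  }
  data <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(data) <- sp
  tab <- trait_table(data, schema$kind, schema$group)
  if (config$missing_rate > 0) {
    tab <- inject_missing(tab, config$missing_rate,
                          seed = derive_seed(config$seed, 1))
  }
  attr(tab, "environment") <- env
  tab
}

#' Inject missing values into a trait table
#'
#' Masks each cell independently with probability `rate`. At least one
#' fully observed species is guaranteed: if a draw leaves none, the whole
#' mask is redrawn.
#'
#' @param table A `"trait_table"`.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed for a reproducible mask.
#' @return The masked `"trait_table"`.
#' @export
inject_missing <- function(table, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (rate == 0) return(table)
  set.seed(seed)
  n <- nrow(table$data)
  p <- ncol(table$data)
  repeat {
    mask <- base::matrix(stats::runif(n * p) < rate, n, p)
    if (any(rowSums(mask) == 0)) break
  }
  data <- table$data
  for (j in seq_len(p)) data[[j]][mask[, j]] <- NA
  trait_table(data, table$kind, table$group)
}
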