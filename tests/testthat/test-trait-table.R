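make_schema <- function() {
  list(kind = c(q1 = "quantitative", q2 = "quantitative", b1 = "binary",
                c1 = "categorical"),
       group = c(q1 = "habitat", q2 = "trophic", b1 = "behavior",
                 c1 = "habitat"))
}

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("trait-table reader types columns, tracks NAs, rejects bad input", {
  schema <- make_schema()
  path <- write_fixture_csv(c(
    "species,q1,q2,b1,c1",
    "s1,1.5,2,yes,red",
    "s2,NA,3,no,blue",
    "s3,2.5,4,yes,red"))
  tab <- read_trait_table(path, schema)
  expect_s3_class(tab, "trait_table")
  expect_equal(sum(is.na(as.matrix(tab$data))), 1)
  expect_true(is.numeric(tab$data$q1))

  dup <- write_fixture_csv(c("species,q1,q2,b1,c1",
                             "s1,1,2,yes,red", "s1,2,3,no,blue"))
  expect_error(read_trait_table(dup, schema), "duplicated species")

  bad <- write_fixture_csv(c("species,q1,q2,b1,c1",
                             "s1,oops,2,yes,red", "s2,1,3,no,blue"))
  expect_error(read_trait_table(bad, schema), "non-numeric")

  short_schema <- lapply(make_schema(), function(v) v[names(v) != "c1"])
  expect_error(read_trait_table(path, short_schema), "c1")
})

test_that("schema YAML round-trips through write/read", {
  schema <- make_schema()
  df <- data.frame(q1 = c(1, 2), q2 = c(3, 4), b1 = c("y", "n"),
                   c1 = c("r", "b"), row.names = c("s1", "s2"))
  tab <- trait_table(df, schema$kind, schema$group)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trait_schema(tab, path)
  back <- read_trait_schema(path)
  expect_equal(back$kind, schema$kind)
  expect_equal(back$group, schema$group)
})

test_that("NA-excluded subdatabase retains exactly the complete species", {
  schema <- make_schema()
  df <- data.frame(q1 = c(1, NA, 3, 4, 5), q2 = c(1, 2, 3, NA, 5),
                   b1 = c("y", "n", "y", "n", "y"),
                   c1 = c("r", "b", "r", "b", "r"),
                   row.names = paste0("s", 1:5))
  tab <- trait_table(df, schema$kind, schema$group)
  kept <- drop_na_species(tab)
  expect_setequal(species_labels(kept), c("s1", "s3", "s5"))
  expect_equal(colnames(kept$data), colnames(tab$data))
  # no NAs: identity
  expect_equal(drop_na_species(kept)$data, kept$data)
})

test_that("group split partitions the trait set and validates the group", {
  schema <- make_schema()
  df <- data.frame(q1 = 1:3, q2 = 4:6, b1 = c("y", "n", "y"),
                   c1 = c("r", "b", "r"), row.names = paste0("s", 1:3))
  tab <- trait_table(df, schema$kind, schema$group)
  hab <- split_by_group(tab, "habitat")
  expect_setequal(colnames(hab$data), c("q1", "c1"))
  expect_equal(species_labels(hab), species_labels(tab))
  all_traits <- unlist(lapply(unique(tab$group), function(g)
    colnames(split_by_group(tab, g)$data)))
  expect_setequal(all_traits, colnames(tab$data))
  expect_error(split_by_group(tab, "diet"), "unknown trait group")
})

test_that("default shark-like schema has the documented group sizes", {
  schema <- default_trait_schema()
  expect_equal(sum(schema$group == "habitat"), 5)
  expect_equal(sum(schema$group == "behavior"), 2)
  expect_setequal(names(schema$kind)[schema$group == "behavior"],
                  c("nocturnal", "schooling"))
})

test_that("correlation screen picks the right test per kind pair", {
  set.seed(42)
  n <- 200
  q <- rnorm(n)
  df <- data.frame(q1 = q, q2 = rnorm(n),
                   b1 = ifelse(q > 0, "hi", "lo"),
                   c1 = sample(c("x", "y", "z"), n, replace = TRUE),
                   row.names = sprintf("s%03d", 1:n))
  schema <- make_schema()
  tab <- trait_table(df, schema$kind, schema$group)
  scr <- trait_correlation_screen(tab, alpha = 0.05)
  expect_equal(nrow(scr), 6)
  row_of <- function(a, b) scr[(scr$trait1 == a & scr$trait2 == b) |
                               (scr$trait1 == b & scr$trait2 == a), ]
  expect_equal(row_of("q1", "q2")$test, "spearman")
  expect_equal(row_of("b1", "c1")$test, "cramers_v")
  # a quantitative trait vs its own discretization: strongly associated
  kw <- row_of("q1", "b1")
  expect_equal(kw$test, "kruskal_wallis")
  expect_lt(kw$p_value, 0.01)
  expect_true(kw$flagged)

  # a trait against an exact copy of itself maxes the statistic
  df2 <- df
  df2$q2 <- df2$q1
  scr2 <- trait_correlation_screen(trait_table(df2, schema$kind, schema$group))
  self <- scr2[scr2$trait1 == "q1" & scr2$trait2 == "q2", ]
  expect_equal(self$statistic, 1, tolerance = 1e-12)
  expect_lt(self$p_value, 1e-10)
})

test_that("independent shuffled columns are flagged at about the alpha rate", {
  set.seed(99)
  n <- 200
  hits <- 0L
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    x <- rnorm(n)
    y <- sample(rnorm(n))
    p <- suppressWarnings(cor.test(x, y, method = "spearman"))$p.value
    df <- data.frame(q1 = x, q2 = y, row.names = sprintf("s%03d", 1:n))
    tab <- trait_table(df, c(q1 = "quantitative", q2 = "quantitative"),
                       c(q1 = "habitat", q2 = "habitat"))
    scr <- trait_correlation_screen(tab, alpha = 0.05)
    expect_equal(scr$p_value[1], p, tolerance = 1e-10)
    hits <- hits + scr$flagged[1]
  }
  expect_gt(hits / n_sim, 0.02)
  expect_lt(hits / n_sim, 0.09)
})

test_that("Gower distance matches its definition and handles missing weights", {
  # single quantitative trait (0, 5, 10): d(s1,s2) = 0.5
  tt <- trait_table(data.frame(size = c(0, 5, 10),
                               row.names = c("s1", "s2", "s3")),
                    kind = c(size = "quantitative"),
                    group = c(size = "trophic"))
  g <- gower_distance(tt)
  expect_equal(g["s1", "s2"], 0.5)
  expect_equal(g["s1", "s3"], 1)

  # identical rows -> 0; all-4-binary mismatch -> 1
  df <- data.frame(b1 = c("y", "n"), b2 = c("y", "n"), b3 = c("n", "y"),
                   b4 = c("n", "y"), row.names = c("u", "v"))
  kinds <- setNames(rep("binary", 4), names(df))
  groups <- setNames(rep("behavior", 4), names(df))
  expect_equal(gower_distance(trait_table(df, kinds, groups))["u", "v"], 1)
  df_same <- df; df_same["v", ] <- df_same["u", ]
  expect_equal(gower_distance(trait_table(df_same, kinds, groups))["u", "v"], 0)

  # hand-worked mixed case with one NA pair: that trait's weight is zeroed
  mixed <- data.frame(q = c(0, 4, 8), b = c("y", NA, "n"),
                      c = c("r", "b", "r"), row.names = c("x", "y", "z"))
  tt2 <- trait_table(mixed,
                     kind = c(q = "quantitative", b = "binary", c = "categorical"),
                     group = c(q = "habitat", b = "behavior", c = "trophic"))
  g2 <- gower_distance(tt2)
  expect_equal(g2["x", "y"], (4 / 8 + 1) / 2)       # q and c observed
  expect_equal(g2["x", "z"], (8 / 8 + 1 + 0) / 3)   # all three observed
  expect_equal(g2["y", "z"], (4 / 8 + 1) / 2)

  # no shared observed trait -> error naming the pair
  bad <- data.frame(a = c(1, NA, 2), b = c(NA, 3, 4),
                    row.names = c("p", "q", "r"))
  ttb <- trait_table(bad, c(a = "quantitative", b = "quantitative"),
                     c(a = "habitat", b = "habitat"))
  expect_error(gower_distance(ttb), "p/q")

  # zero-range quantitative trait dropped with warning
  zr <- data.frame(q = c(2, 2, 2), b = c("y", "n", "y"),
                   row.names = c("s1", "s2", "s3"))
  ttz <- trait_table(zr, c(q = "quantitative", b = "binary"),
                     c(q = "habitat", b = "behavior"))
  expect_warning(gz <- gower_distance(ttz), "zero range")
  expect_equal(gz["s1", "s2"], 1)
})

test_that("Gower is invariant to affine rescaling and agrees with cluster::daisy", {
  set.seed(5)
  df <- data.frame(q1 = rnorm(12), q2 = runif(12),
                   b = sample(c("y", "n"), 12, TRUE),
                   c = sample(c("a", "b", "c"), 12, TRUE),
                   row.names = sprintf("s%02d", 1:12))
  df$q1[c(2, 5)] <- NA
  df$c[7] <- NA
  kinds <- c(q1 = "quantitative", q2 = "quantitative", b = "binary",
             c = "categorical")
  groups <- c(q1 = "habitat", q2 = "habitat", b = "behavior", c = "trophic")
  tab <- trait_table(df, kinds, groups)
  g <- gower_distance(tab)

  df2 <- df
  df2$q1 <- 100 * df2$q1 - 7
  expect_equal(gower_distance(trait_table(df2, kinds, groups)), g,
               tolerance = 1e-12)

  # independent implementation of the same definition
  dd <- df
  dd$b <- factor(dd$b)
  dd$c <- factor(dd$c)
  daisy_g <- as.matrix(cluster::daisy(dd, metric = "gower"))
  expect_equal(unname(g), unname(daisy_g[rownames(g), colnames(g)]),
               tolerance = 1e-10)

  # NA-excluded table never triggers the undefined-pair error
  expect_silent(gower_distance(drop_na_species(tab)))
})
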