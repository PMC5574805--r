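test_that("Baum-Ragan encoding codes clades, absences, and counts", {
  t1 <- suppressWarnings(read_newick("((a,b),(c,d));"))
  m <- mrp_encode(list(t1))
  expect_equal(ncol(m), 2)
  clades <- apply(unclass(m), 2, function(col) {
    paste(sort(rownames(m)[col == "1"]), collapse = ",")
  })
  expect_setequal(unname(clades), c("a,b", "c,d"))
  expect_true(all(m %in% c("0", "1")))

  # taxa absent from a source tree are '?' on its characters
  t2 <- suppressWarnings(read_newick("((c,d),e);"))
  m2 <- mrp_encode(list(t1, t2))
  src <- attr(m2, "source")
  from2 <- which(src == 2)
  expect_true(all(m2[c("a", "b"), from2] == "?"))
  expect_true(all(m2[c("a", "b"), src == 1] != "?"))

  # column count equals the number of informative internal clades
  set.seed(103)
  trees <- lapply(1:3, function(i) random_tree(7, letters[1:7]))
  m3 <- mrp_encode(trees)
  # a rooted binary tree of n tips has n-1 internal nodes; the root and any
  # root child spanning n-1 tips are uninformative
  expected <- sum(vapply(trees, function(tr) {
    ntip <- length(tr$tip.label)
    pp <- ape::prop.part(tr)
    sum(vapply(2:length(pp), function(k) {
      sz <- length(pp[[k]])
      sz >= 2 && sz < ntip
    }, logical(1)))
  }, numeric(1)))
  expect_equal(ncol(m3), expected)
})

test_that("parsimony score matches exhaustive enumeration on all 5-taxon topologies", {
  set.seed(107)
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
  expect_equal(length(topos), 15)
  chars <- replicate(50, {
    s <- sample(c("0", "1", "?"), 5, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    if (length(unique(s[s != "?"])) < 2) s[1:2] <- c("0", "1")
    s
  })
  rownames(chars) <- letters[1:5]
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]  # [[ expands the shared tip labels of the multiPhylo
    tr$edge.length <- rep(1, nrow(tr$edge))
    mine <- fitch_score(chars, tr)
    oracle <- sum(vapply(seq_len(ncol(chars)), function(j) {
      st <- suppressWarnings(as.numeric(chars[, j]))
      names(st) <- rownames(chars)
      oracle_parsimony_char(tr, st)
    }, numeric(1)))
    expect_equal(mine, oracle)
  }
})

test_that("parsimony score handles compatible matrices, constants, rerooting", {
  set.seed(109)
  tr <- random_tree(8, letters[1:8])
  m <- mrp_encode(list(tr))
  # every clade character fits with exactly one change
  expect_equal(fitch_score(m, tr), ncol(m))
  # constant character costs nothing
  const <- matrix("1", 8, 1, dimnames = list(letters[1:8], "c1"))
  expect_equal(fitch_score(const, tr), 0)
  # invariant to rerooting
  s0 <- fitch_score(m, tr)
  for (k in 1:4) {
    node <- sample(setdiff(unique(tr$edge[, 1]), 9), 1)
    expect_equal(fitch_score(m, ape::root(tr, node = node, resolve.root = TRUE)), s0)
  }
  # agreement with phangorn's Fitch implementation
  t2 <- random_tree(8, letters[1:8])
  pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1"), ambiguity = "?")
  expect_equal(fitch_score(m, t2), as.integer(phangorn::fitch(t2, pd)))
  # matrix taxon missing from tree is an error
  t7 <- random_tree(7, letters[1:7])
  expect_error(fitch_score(m, t7), "absent from tree")
})

test_that("MRP search recovers a single source tree and respects shared clades", {
  set.seed(113)
  src <- random_tree(7, letters[1:7])
  m <- mrp_encode(list(src))
  out <- mrp_supertree(m, restarts = 10, seed = 3)
  expect_equal(out$score, ncol(m))  # perfect fit
  expect_equal(as.numeric(phangorn::RF.dist(out$tree, ape::unroot(src))), 0)
  # two compatible subtrees: supertree must contain clade {a,b}
  s1 <- suppressWarnings(read_newick("((a,b),c);"))
  s2 <- suppressWarnings(read_newick("((a,b),d);"))
  m2 <- mrp_encode(list(s1, s2))
  out2 <- mrp_supertree(m2, restarts = 10, seed = 5)
  # the single split of the 4-taxon supertree must be {a,b} | {c,d}
  # (canonical key: the side without the reference tip "a")
  expect_equal(tree_bipartitions(out2$tree),
               paste(c("c", "d"), collapse = "\u001f"))
  # determinism given seed
  out3 <- mrp_supertree(m2, restarts = 10, seed = 5)
  expect_equal(write_newick(out2$tree), write_newick(out3$tree))
})

test_that("heuristic search reaches the generating tree's score on 8 taxa", {
  set.seed(127)
  wins <- 0L
  for (i in 1:20) {
    truth <- random_tree(8, letters[1:8])
    # three overlapping 6-taxon prunings as source trees
    sources <- lapply(1:3, function(k) {
      keep <- sample(letters[1:8], 6)
      ape::keep.tip(truth, keep)
    })
    m <- mrp_encode(sources)
    out <- mrp_supertree(m, restarts = 5, seed = 1000 + i)
    if (out$score <= fitch_score(m, truth)) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})
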