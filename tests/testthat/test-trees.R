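test_that("topology A builder places the focal branch lengths", {
  tr <- build_topology_a(ltb = 0.1, sib = 0.01, rb = 0.05)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 11)
  expect_length(tree_bipartitions(tr), 8)
  expect_equal(split_edge_length(tr, "t3"), 0.1)
  expect_equal(split_edge_length(tr, "t7"), 0.1)
  expect_equal(split_edge_length(tr, c("t3", "t4")), 0.01)
  expect_equal(split_edge_length(tr, c("t7", "t8")), 0.01)
  expect_equal(split_edge_length(tr, c("t1", "t2")), 0.05)
  # the long leaves are in cherries with their short partners, not together
  expect_true(leaves_adjacent(tr, c("t3", "t4")))
  expect_true(leaves_adjacent(tr, c("t7", "t8")))
  expect_false(leaves_adjacent(tr, c("t3", "t7")))
  # separated by more than one internal edge
  pruned <- prune_taxa(tr, c("t3", "t4", "t7", "t8", "t11"))
  expect_false(leaves_adjacent(pruned, c("t3", "t7")))
})

test_that("uniform-length topology A still has 11 leaves and 8 internal edges", {
  tr <- build_topology_a(ltb = 0.05, sib = 0.05, rb = 0.05)
  expect_length(tr$tip.label, 11)
  expect_length(tree_bipartitions(tr), 8)
  expect_true(all(tr$edge.length == 0.05))
})

test_that("topology B builder separates the focal short pair", {
  tr <- build_topology_b(lib = 1.5, sib = 0.01, rb = 0.05)
  expect_length(tr$tip.label, 11)
  expect_length(tree_bipartitions(tr), 8)
  expect_false(leaves_adjacent(tr, c("t5", "t6")))
  expect_equal(split_edge_length(tr, c("t1", "t2", "t3", "t4")), 1.5)
  expect_equal(split_edge_length(tr, c("t7", "t8", "t9", "t10", "t11")), 1.5)
  # central edge separates {t5, 4-clade} from {t6, 5-clade}
  expect_equal(split_edge_length(tr, c("t1", "t2", "t3", "t4", "t5")), 0.01)
  # lib/sib ratio spans the design range
  tr2 <- build_topology_b(lib = 0.1, sib = 0.5, rb = 0.05)
  expect_equal(split_edge_length(tr2, c("t1", "t2", "t3", "t4")) /
                 split_edge_length(tr2, c("t1", "t2", "t3", "t4", "t5")), 0.2)
})

test_that("builders reject negative branch lengths by name", {
  expect_error(build_topology_a(-0.1, 0.01), "ltb")
  expect_error(build_topology_a(0.1, -1), "sib")
  expect_error(build_topology_b(0.1, 0.01, rb = -2), "rb")
})

test_that("newick round trip preserves splits and lengths", {
  set.seed(11)
  for (i in 1:20) {
    tr <- random_unrooted_tree(sample(4:12, 1))
    txt <- write_newick(tr)
    tr2 <- parse_newick(txt)
    expect_setequal(tr2$tip.label, tr$tip.label)
    expect_identical(tree_bipartitions(tr2), tree_bipartitions(tr))
    b1 <- tree_bipartitions(tr, lengths = TRUE)
    b2 <- tree_bipartitions(tr2, lengths = TRUE)
    expect_equal(attr(b2, "lengths"), attr(b1, "lengths"), tolerance = 1e-9)
  }
})

test_that("parse_newick reports structural errors with positions", {
  expect_error(parse_newick("((a:1,b:2);"), "unbalanced '\\('")
  expect_error(parse_newick("(a:1,b:2)):3;"), "character 10")
  expect_error(parse_newick("(a:1,b:2,(c:3,d:4):5)"), "terminating ';'")
  expect_error(parse_newick("(a:1,a:2,(c:3,d:4):5);"), "duplicate leaf")
  tr <- parse_newick("(a:1,b:2,(c:3,d:4):5);")
  expect_length(tr$tip.label, 4)
  expect_identical(tree_bipartitions(tr), "c|d")
})

test_that("bipartition counts follow n - 3 for resolved trees", {
  expect_length(tree_bipartitions(build_topology_a(0.3, 0.1)), 8)
  expect_length(tree_bipartitions(parse_newick("((a:1,b:1):1,c:1,d:1);")), 1)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  expect_length(tree_bipartitions(star), 0)
})

test_that("rf_distance is a metric and matches an independent implementation", {
  set.seed(21)
  labels <- paste0("t", 1:8)
  for (i in 1:25) {
    a <- random_unrooted_tree(8, labels)
    b <- random_unrooted_tree(8, labels)
    c_ <- random_unrooted_tree(8, labels)
    dab <- rf_distance(a, b)
    expect_identical(dab, rf_distance(b, a))
    expect_identical(rf_distance(a, a), 0L)
    expect_lte(rf_distance(a, c_), dab + rf_distance(b, c_))
    expect_equal(dab, as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("trees one NNI apart have rf distance 2", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1,e:1);")
  nb <- ape::read.tree(text = "(((a:1,c:1):1,b:1):1,d:1,e:1);")
  expect_identical(rf_distance(tr, nb), 2L)
})

test_that("rf_distance rejects mismatched leaf sets informatively", {
  a <- parse_newick("(a:1,b:1,(c:1,d:1):1);")
  b <- parse_newick("(a:1,b:1,(c:1,e:1):1);")
  expect_error(rf_distance(a, b), "only in tree1.*d")
})

test_that("pruning restricts bipartitions and preserves path lengths", {
  set.seed(31)
  # oracle: restriction of the split set, trivial splits dropped
  for (i in 1:15) {
    tr <- random_unrooted_tree(8)
    keep <- sample(tr$tip.label, 5)
    pruned <- prune_taxa(tr, keep)
    expect_setequal(pruned$tip.label, keep)
    restricted <- unique(Filter(
      function(k) k != "",
      vapply(tree_bipartitions(tr), function(key) {
        side <- intersect(strsplit(key, "|", fixed = TRUE)[[1]], keep)
        if (length(side) < 2 || length(side) > 3) return("")
        lbasim:::split_key(side, sort(keep))
      }, character(1))))
    expect_setequal(tree_bipartitions(pruned), restricted)
    # path length between two kept leaves is preserved
    d_full <- ape::cophenetic.phylo(tr)[keep[1], keep[2]]
    d_sub <- ape::cophenetic.phylo(pruned)[keep[1], keep[2]]
    expect_equal(d_sub, d_full, tolerance = 1e-10)
  }
})

test_that("pruning to 3 leaves yields a star and unknown labels error", {
  tr <- build_topology_a(0.3, 0.1)
  st <- prune_taxa(tr, c("t1", "t5", "t11"))
  expect_length(tree_bipartitions(st), 0)
  expect_error(prune_taxa(tr, c("t1", "t2", "zz")), "zz")
  expect_error(prune_taxa(tr, c("t1", "t2")), "at least 3")
})

test_that("builder trees expose parameter lengths on designated edges", {
  for (sib in c(0.01, 0.1, 0.5)) {
    for (lng in c(0.1, 0.7, 1.5)) {
      a <- build_topology_a(lng, sib)
      expect_equal(split_edge_length(a, "t3"), lng)
      expect_equal(split_edge_length(a, c("t7", "t8")), sib)
      b <- build_topology_b(lng, sib)
      expect_equal(split_edge_length(b, c("t1", "t2", "t3", "t4")), lng)
      expect_equal(split_edge_length(b, c("t1", "t2", "t3", "t4", "t5")), sib)
    }
  }
})
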