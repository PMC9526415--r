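# p-distances, neighbor-joining, rooting and the monophyly test.

test_that("p-distance counts mismatches with pairwise gap deletion", {
  d <- p_distance(c(a = "ACGT", b = "ACGT"))
  expect_equal(d["a", "b"], 0)
  d <- p_distance(c(a = "ACGT", b = "ACGA"))
  expect_equal(d["a", "b"], 0.25)
  d <- p_distance(c(a = "AC-A", b = "ACGT"))
  expect_equal(d["a", "b"], 1 / 3)     # gap column deleted pairwise
  expect_error(p_distance(c(a = "ACG", b = "ACGT")), class = "FormatError")
  expect_error(p_distance(c(a = "----", b = "ACGT")), class = "ValueError")
})

test_that("NJ recovers the quartet split and branch lengths exactly", {
  # tree ((A:1,B:1):1,(C:1,D:1):1): d(A,B)=d(C,D)=2, cross pairs 4
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  # reconstructed pairwise distances reproduce the input (additivity)
  expect_equal(tree_distances(tr), D[order(rownames(D)), order(colnames(D))],
               tolerance = 1e-10)
  # AB|CD is a split: rooting on A puts B apart from C and D
  rooted <- root_with_outgroup(tr, "A")
  expect_false(is_monophyletic(rooted, c("B", "C")))
  expect_true(is_monophyletic(rooted, c("C", "D")))
  # internal edge length 2 - 1 - 1 + ... : check via the path A->C minus
  # pendant edges: all pendant edges are 1, so internal = 4 - 1 - 1 = 2
  expect_error(nj_tree(D[1:2, 1:2]), class = "ValueError")
})

test_that("NJ is invariant to label order", {
  set.seed(17)
  tr <- random_additive_tree(8)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(nrow(D))
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_equal(tree_distances(t1), tree_distances(t2), tolerance = 1e-10)
})

test_that("midpoint rooting places the root halfway along the longest
           path and is idempotent", {
  # chain A -1- B -3- C: longest path 4, root 2 from each end
  tr <- ape::read.tree(text = "(A:1,C:3);")
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)
  leaf_depths <- depths[seq_along(rooted$tip.label)]
  names(leaf_depths) <- rooted$tip.label
  expect_equal(unname(leaf_depths[c("A", "C")]), c(2, 2))
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length))

  again <- midpoint_root(rooted)
  d2 <- ape::node.depth.edgelength(again)[seq_along(again$tip.label)]
  expect_equal(sort(d2), sort(unname(leaf_depths)))

  zero <- tr; zero$edge.length <- c(0, 0)
  expect_error(midpoint_root(zero), class = "ValueError")
})

test_that("outgroup rooting validates the split", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  rooted <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rooted))
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length))
  expect_error(root_with_outgroup(tr, c("A", "C")), class = "ValueError")
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")),
               class = "ValueError")
  expect_error(root_with_outgroup(tr, "Z"), class = "ValueError")
})

test_that("monophyly checks exact descendant sets, not complements", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, "nope"), class = "ValueError")
  # a set and its complement need not both be clades
  tr2 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  expect_true(is_monophyletic(tr2, c("D", "E")))
  expect_true(is_monophyletic(tr2, c("A", "B", "C")))
  expect_false(is_monophyletic(tr2, c("B", "C")))
})

test_that("newick round-trip preserves the tree", {
  set.seed(3)
  tr <- random_additive_tree(9)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- read_newick(p)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(tree_distances(tr), tree_distances(back), tolerance = 1e-8)
})
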