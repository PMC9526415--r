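# Organization encoding, similarity, type grouping and presence matrix.

test_that("organization similarity is a normalized edit similarity", {
  a <- org_from_labels(c("alkB", "alkG", "alkH", "alkJ"))
  expect_equal(organization_similarity(a, a), 1)

  b <- org_from_labels(c("alkB", "alkG", "alkJ"))
  expect_equal(organization_similarity(a, b), 0.75)   # one deletion / 4

  # five tokens each, only alkB shared: four substitutions
  x <- org_from_labels(c("alkB", "alkG", "alkH", "alkJ", "alkK"))
  y <- org_from_labels(c("alkB", "alkS", "alkT", "alkN", "alkL"))
  expect_equal(organization_similarity(x, y), 0.2)

  # symmetry and bounds over the templates
  tpl <- lapply(organization_templates(), org_from_labels)
  for (i in seq_along(tpl)) for (j in seq_along(tpl)) {
    s <- organization_similarity(tpl[[i]], tpl[[j]])
    expect_equal(s, organization_similarity(tpl[[j]], tpl[[i]]))
    expect_gte(s, 0); expect_lte(s, 1)
    if (i != j) expect_lt(s, 1)
  }
})

test_that("type grouping separates the four templates and honors the
           threshold", {
  tpl <- lapply(organization_templates(), org_from_labels)
  types <- group_organization_types(tpl, threshold = 0.8)
  expect_equal(length(unique(types$type_id)), 4)

  # two identical + one distinct -> 2 types
  three <- list(f1 = tpl[[1]], f2 = tpl[[1]], f3 = tpl[[4]])
  types <- group_organization_types(three, threshold = 0.8)
  expect_equal(length(unique(types$type_id)), 2)
  expect_equal(types$type_id[1], types$type_id[2])

  # threshold 0 merges everything
  types <- group_organization_types(three, threshold = 0)
  expect_equal(length(unique(types$type_id)), 1)

  # permutation invariance of the grouping (up to relabeling)
  perm <- c(3, 1, 4, 2)
  t1 <- group_organization_types(tpl, threshold = 0.8)
  t2 <- group_organization_types(tpl[perm], threshold = 0.8)
  part1 <- split(t1$fragment_id, t1$type_id)
  part2 <- split(t2$fragment_id, t2$type_id)
  expect_setequal(lapply(unname(part1), sort), lapply(unname(part2), sort))
})

test_that("encoding is strand-normalized on the alkB anchor", {
  fx <- fixture_scan()
  frag <- fx$scan$fragments[[1]]
  org <- encode_organization(frag)
  expect_equal(sum(org$tokens$label == "alkB"), 1)
  expect_equal(org$tokens$label[org$anchor_offset + 1], "alkB")
  # alkB itself always reads forward after normalization
  expect_equal(org$tokens$strand[org$anchor_offset + 1], "+")
  # template order is recovered left-to-right
  expect_equal(org$tokens$label, organization_templates()$pseudomonas_full)

  bad <- frag
  bad$hits <- frag$hits[frag$hits$label != "alkB", ]
  expect_error(encode_organization(bad), class = "ConsistencyError")
})

test_that("plus and minus strand plantings encode identically", {
  fx <- fixture_mini_survey()
  sc <- fx$scan
  # g06 planted on the minus strand, fixture_scan g04 planting is
  # strand-flipped relative to it; organization strings must match the
  # template regardless
  cl <- sc$clusters[sc$clusters$genome_id == "g06", ]
  org <- sc$fragments[[cl$fragment_id]]$organization
  expect_equal(org$tokens$label, organization_templates()$marinobacter)
  expect_true(all(org$tokens$strand == "+"))
})

test_that("presence matrix is tri-state with alkB always present", {
  fx <- fixture_mini_survey()
  pm <- presence_matrix(fx$scan$fragments)
  expect_equal(sort(colnames(pm)),
               sort(c("alkB", "alkF", "alkG", "alkH", "alkJ", "alkK",
                      "alkL", "alkN", "alkS", "alkT")))
  expect_true(all(pm[, "alkB"] == "present"))
  g06 <- rownames(pm)[startsWith(rownames(pm), "g06")]
  expect_equal(unname(pm[g06, "alkK"]), "pseudogene")
  expect_equal(unname(pm[g06, "alkF"]), "absent")
  g15 <- rownames(pm)[startsWith(rownames(pm), "g15")]
  # minimal template: alkS, alkB, alkG, alkJ, alkH present, rest absent
  expect_equal(sum(pm[g15, ] == "present"), 5)
})
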