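# The generator: reproducibility, planted structure, GC control, the alkB
# radiation, and recovery scoring arithmetic.

test_that("generation is bit-reproducible for identical config and seed", {
  plan <- default_survey_plan()[c(4, 15), ]
  s1 <- generate_survey(plan, seed = 5)
  s2 <- generate_survey(plan, seed = 5)
  expect_identical(lapply(s1$assemblies, `[[`, "replicons"),
                   lapply(s2$assemblies, `[[`, "replicons"))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_survey(plan, seed = 6)
  expect_false(identical(s1$assemblies[[1]]$replicons,
                         s3$assemblies[[1]]$replicons))
})

test_that("the planted cluster matches its template and window", {
  fx <- fixture_scan()
  truth <- fx$survey$truth
  genes <- truth[truth$kind %in% c("alk_gene", "pseudogene"), ]
  expect_setequal(genes$label, organization_templates()$pseudomonas_full)
  cl <- truth[truth$kind == "cluster", ]
  expect_equal(cl$end - cl$start, 38000L)
  # every planted gene lies inside the cluster window
  expect_true(all(genes$start >= cl$start & genes$end <= cl$end))
})

test_that("back-translation hits the requested GC and island GC is
           controlled within two points", {
  refs <- load_alk_references()
  set.seed(8)
  for (t in c(0.45, 0.60)) {
    cds <- back_translate(refs$seq[refs$label == "alkJ"], t)
    expect_lt(abs(gc_content(cds) - t), 0.03)
  }
  fx <- fixture_scan()
  truth <- fx$survey$truth
  cl <- truth[truth$kind == "cluster", ][1, ]
  island <- substr(fx$survey$assemblies[[1]]$replicons[[cl$replicon_id]],
                   cl$start + 1, cl$end)
  expect_lt(abs(gc_content(island) - 0.45), 0.02)
})

test_that("decoy plantings map one-to-one to the rejection rules", {
  plan <- default_survey_plan()
  expect_setequal(unique(plan$decoy),
                  c("none", "out_of_window", "no_alkB",
                    "contig_end_truncated"))
  sv <- generate_survey(plan[plan$decoy == "out_of_window", ][1, ],
                        seed = 3)
  d <- sv$truth[sv$truth$kind == "decoy", ]
  expect_false(d$expected_detected)
  # the decoy replicon carries alkB but alkG sits beyond the 10-kb window
  dg <- sv$truth[sv$truth$replicon_id == d$replicon_id &
                   sv$truth$kind == "decoy_gene", ]
  b <- dg[dg$label == "alkB", ]
  g <- dg[dg$label == "alkG", ]
  expect_gt(g$start - b$end, 10000)
})

test_that("alkB radiation yields distances ordered family < background <
           outgroup", {
  fam <- evolve_alkB_families(seed = 2, n_families = 3,
                              tips_per_family = 3, n_cluster = 4)
  expect_equal(length(fam$seqs), 3 * 3 + 4 + 1)
  expect_equal(length(unique(nchar(fam$seqs))), 1)     # gap-free equal length
  D <- p_distance(fam$seqs)
  cl <- fam$cluster_tips
  within <- D[cl, cl][upper.tri(D[cl, cl])]
  bg <- setdiff(names(fam$seqs), c(cl, fam$outgroup))
  across <- as.vector(D[cl, bg])
  to_out <- D[fam$outgroup, setdiff(names(fam$seqs), fam$outgroup)]
  expect_lt(max(within), min(across))
  expect_gt(mean(to_out), mean(across))   # outgroup is the most divergent

  degen <- evolve_alkB_families(seed = 2, n_families = 2,
                                tips_per_family = 2, n_cluster = 2,
                                family_rate = 0, tip_rate = 0,
                                cluster_tip_rate = 0, outgroup_rate = 0)
  expect_equal(length(unique(degen$seqs)), 1)   # degenerate: all identical
})

test_that("recovery scoring arithmetic is exact", {
  fx <- fixture_mini_survey()
  r <- score_recovery(fx$scan, fx$survey$truth)
  expect_equal(r$clusters$precision, 1)
  expect_equal(r$clusters$recall, 1)

  # drop one detected cluster: recall loses 1/n, precision stays 1
  sc2 <- fx$scan
  sc2$clusters <- sc2$clusters[-1, ]
  r2 <- score_recovery(sc2, fx$survey$truth)
  n <- r$clusters$n_truth
  expect_equal(r2$clusters$recall, (n - 1) / n)
  expect_equal(r2$clusters$precision, 1)

  # foreign genome ids are a consistency error
  sc3 <- fx$scan
  sc3$clusters$genome_id[1] <- "not_a_genome"
  expect_error(score_recovery(sc3, fx$survey$truth),
               class = "ConsistencyError")
})

test_that("survey inputs round-trip through FASTA + metadata files", {
  fx <- fixture_mini_survey()
  dir <- withr::local_tempdir()
  write_survey_inputs(fx$survey, dir)
  back <- read_survey_inputs(dir)
  expect_setequal(names(back), names(fx$survey$assemblies))
  for (gid in names(back)) {
    expect_identical(back[[gid]]$replicons,
                     fx$survey$assemblies[[gid]]$replicons)
    expect_identical(back[[gid]]$replicon_class,
                     fx$survey$assemblies[[gid]]$replicon_class)
  }
})
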