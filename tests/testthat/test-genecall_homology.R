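# ORF prediction and the protein homology screen.

test_that("call_orfs finds hand-translatable ORFs on both strands", {
  o <- call_orfs("ATGAAATAA", min_nt = 9)
  expect_equal(nrow(o), 1)
  expect_equal(o$protein, "MK")
  expect_equal(c(o$start, o$end), c(0L, 9L))
  expect_equal(o$strand, "+")

  rc <- call_orfs(revcomp("ATGAAATAA"), min_nt = 9)
  expect_equal(rc$protein, "MK")
  expect_equal(rc$strand, "-")
  expect_equal(c(rc$start, rc$end), c(0L, 9L))   # mapped to forward coords

  # GTG/TTG starts normalize to M
  o <- call_orfs("GTGAAATAA", min_nt = 9)
  expect_equal(o$protein, "MK")
})

test_that("call_orfs matches a brute-force six-frame oracle on random DNA", {
  set.seed(42)
  for (gc in c(0.35, 0.5, 0.65)) {
    seq <- alkscan:::random_dna(10000, gc)
    got <- call_orfs(seq, min_nt = 90)
    want <- orf_oracle(seq, min_nt = 90)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("start", "end", "strand", "protein")],
                 want[, c("start", "end", "strand", "protein")])
  }
})

test_that("call_orfs rejects bad input and respects N runs", {
  expect_error(call_orfs("ACGTXX"), class = "FormatError")
  expect_error(call_orfs("ATGAAATAA", min_nt = 10), class = "ConfigError")
  # an N inside the ORF breaks it
  o <- call_orfs("ATGANATAAATGAAATAA", min_nt = 9)
  expect_true(all(o$start >= 9 | o$strand == "-"))
})

test_that("Smith-Waterman scores match the matrix on identities", {
  al <- align_proteins("MKT", "MKT")
  expect_equal(al$raw_score, 15)    # BLOSUM62 diagonal 5 + 5 + 5
  expect_equal(al$q_start, 1); expect_equal(al$q_end, 3)
  expect_equal(al$aligned_subject_fraction, 1)
  expect_error(align_proteins("", "MKT"), class = "EmptyInput")
})

test_that("self-alignment is optimal among equal-length subjects", {
  set.seed(7)
  x <- random_protein(25)
  sx <- align_proteins(x, x)$raw_score
  for (k in 1:10) {
    y <- random_protein(25)
    expect_gte(sx, align_proteins(x, y)$raw_score)
  }
})

test_that("Smith-Waterman equals the brute-force DP oracle", {
  mat <- alkscan:::blosum62()
  set.seed(99)
  for (k in 1:50) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    expect_equal(align_proteins(a, b)$raw_score, sw_oracle(a, b, mat))
  }
})

test_that("E-value follows the closed form and its monotonicities", {
  p <- scoring_params(lambda = 0.267, K = 0.041)
  expect_equal(estimate_evalue(0, 100, 100, p), 410)
  expect_equal(estimate_evalue(50, 200, 300, p),
               2 * estimate_evalue(50, 100, 300, p))
  e <- estimate_evalue(0:20 * 10, 100, 100, p)
  expect_true(all(diff(e) < 0))
})

test_that("label assignment keeps true homologs and rejects noise", {
  refs <- load_alk_references()
  p <- scoring_params()
  # identical to the alkB reference
  calls <- data.frame(replicon_id = "r", start = 0, end = 3,
                      strand = "+", protein = refs$seq[refs$label == "alkB"],
                      gene_index = 1, stringsAsFactors = FALSE)
  hit <- assign_alk_labels(calls, refs, p)
  expect_equal(hit$label, "alkB")
  expect_lt(hit$evalue, 1e-100)

  # random protein of length 200: no label
  set.seed(123)
  calls$protein <- random_protein(200)
  expect_equal(nrow(assign_alk_labels(calls, refs, p)), 0)

  # alkG with 10% point mutations: still labeled alkG
  set.seed(5)
  calls$protein <- alkscan:::mutate_protein(refs$seq[refs$label == "alkG"],
                                            0.10)
  hit <- assign_alk_labels(calls, refs, p)
  expect_equal(hit$label, "alkG")
  expect_lte(hit$evalue, p$evalue_threshold)   # filter soundness

  expect_error(assign_alk_labels(calls, refs[0, ], p),
               class = "ConfigError")
})

test_that("labeling is invariant under reverse complement of the replicon", {
  fx <- fixture_scan()
  asm <- fx$survey$assemblies[[1]]
  rid <- fx$scan$clusters$replicon_id[1]
  seq <- asm$replicons[[rid]]
  refs <- load_alk_references()
  p <- scoring_params()
  h1 <- assign_alk_labels(call_orfs(seq, replicon_id = rid), refs, p)
  h2 <- assign_alk_labels(call_orfs(revcomp(seq), replicon_id = rid),
                          refs, p)
  expect_equal(sort(h1$label), sort(h2$label))
  n <- nchar(seq)
  m1 <- h1[order(h1$start), ]
  m2 <- h2[order(n - h2$end), ]
  expect_equal(m1$start, n - m2$end)
  expect_equal(m1$end, n - m2$start)
  expect_equal(m1$label, m2$label)
  expect_true(all(m1$strand != m2$strand))
})
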