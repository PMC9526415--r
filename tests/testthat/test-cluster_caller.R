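# Marker co-localization, fragment geometry, multi-copy and GC contrast.

mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(replicon_id = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = "+", label = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("candidate loci require all markers within the flanking window", {
  cfg <- cluster_config()
  hits <- mk_hits(list("c", 50000, 51200, "alkB"),
                  list("c", 52000, 53100, "alkG"),
                  list("c", 53200, 54700, "alkH"),
                  list("c", 54800, 56300, "alkJ"))
  expect_equal(nrow(find_candidate_loci(hits, cfg)), 1)

  # alkJ pushed to 61,300: gap 61,300 - 51,200 = 10,100 > 10,000
  hits2 <- hits
  hits2[hits2$label == "alkJ", c("start", "end")] <- c(61300L, 62800L)
  expect_equal(nrow(find_candidate_loci(hits2, cfg)), 0)

  # markers without alkB never seed a candidate
  expect_equal(nrow(find_candidate_loci(
    hits[hits$label != "alkB", ], cfg)), 0)

  # markers on a different replicon do not count
  hits3 <- hits
  hits3$replicon_id[hits3$label == "alkG"] <- "other"
  expect_equal(nrow(find_candidate_loci(hits3, cfg)), 0)

  expect_equal(nrow(find_candidate_loci(hits[0, ], cfg)), 0)
})

test_that("fragment windows are strand-aware around the start codon", {
  cfg <- cluster_config()
  asm <- genome_assembly("g", c(chr = strrep("A", 100000)))
  plus <- data.frame(replicon_id = "chr", start = 50000L, end = 51203L,
                     strand = "+", label = "alkB", stringsAsFactors = FALSE)
  f <- extract_fragment(asm, plus, cfg)
  expect_equal(c(f$start, f$end), c(40000L, 78000L))
  expect_equal(f$end - f$start, 38000L)
  expect_false(f$truncated)

  minus <- data.frame(replicon_id = "chr", start = 47000L, end = 50003L,
                      strand = "-", label = "alkB", stringsAsFactors = FALSE)
  f <- extract_fragment(asm, minus, cfg)
  expect_equal(c(f$start, f$end), c(22003L, 60003L))

  # naive (non-strand-aware) interpretation is available by flag
  cfg0 <- cluster_config(strand_aware = FALSE)
  f <- extract_fragment(asm, minus, cfg0)
  expect_equal(c(f$start, f$end), c(37000L, 75000L))

  # window underflow at a contig start: truncated, to be excluded
  early <- data.frame(replicon_id = "chr", start = 5000L, end = 6203L,
                      strand = "+", label = "alkB", stringsAsFactors = FALSE)
  f <- extract_fragment(asm, early, cfg)
  expect_true(f$truncated)

  bad <- plus; bad$replicon_id <- "nope"
  expect_error(extract_fragment(asm, bad, cfg), class = "ConsistencyError")
})

test_that("GC contrast is computed in percentage points", {
  asm <- genome_assembly("g", c(chr = "GGCCAATT"))
  frag <- list(sequence = "GGCC")
  gc <- fragment_gc_delta(frag, asm)
  expect_equal(gc$gc_fragment, 100)
  expect_equal(gc$gc_genome, 50)
  expect_equal(gc$delta, 50)

  frag$sequence <- "GGCCAATT"
  expect_equal(fragment_gc_delta(frag, asm)$delta, 0)
})

test_that("multi-copy reports count fragments and same-replicon gaps", {
  one <- data.frame(genome_id = "g", replicon_id = "chr",
                    start = 0L, end = 38000L, stringsAsFactors = FALSE)
  r <- detect_multicopy(one)
  expect_equal(r$n_fragments, 1)
  expect_equal(r$separations, "")

  two <- rbind(one, data.frame(genome_id = "g", replicon_id = "chr",
                               start = 188000L, end = 226000L))
  r <- detect_multicopy(two)
  expect_equal(r$n_fragments, 2)
  expect_equal(r$separations, "150000")

  mixed <- rbind(one, data.frame(genome_id = "g", replicon_id = "plasmid",
                                 start = 1000L, end = 39000L))
  expect_equal(detect_multicopy(mixed)$separations, "")
})

test_that("re-screening annotates planted genes and flags pseudogenes", {
  fx <- fixture_mini_survey()          # g06: marinobacter type, alkK pseudo
  sc <- fx$scan
  cl <- sc$clusters[sc$clusters$genome_id == "g06", ]
  expect_equal(nrow(cl), 1)
  frag <- sc$fragments[[cl$fragment_id]]
  labs <- unique(frag$hits$label)
  expect_true(all(c("alkS", "alkT", "alkB", "alkG", "alkH", "alkJ", "alkK",
                    "alkL") %in% labs))
  expect_true(all(frag$hits$evalue <= 1e-10))
  k <- frag$hits[frag$hits$label == "alkK", ]
  expect_true(all(k$is_pseudogene))
  expect_lt(max(k$aligned_subject_fraction), 0.6)
  # intact genes are not flagged
  b <- frag$hits[frag$hits$label == "alkB", ]
  expect_false(any(b$is_pseudogene))
})

test_that("a random-sequence fragment is never an alkB-anchored cluster", {
  set.seed(31)
  asm <- genome_assembly("g", c(chr = alkscan:::random_dna(60000, 0.5)))
  sc <- scan_survey(list(asm))
  expect_equal(nrow(sc$clusters), 0)
  expect_equal(unname(sc$log["candidates"]), 0L)
})
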