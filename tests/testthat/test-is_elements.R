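# Transposase screening and terminal-inverted-repeat pairing.

test_that("find_tirs recovers a planted exact repeat at its coordinates", {
  set.seed(20)
  tir <- alkscan:::random_dna(25, 0.5)
  left_bg <- alkscan:::random_dna(150, 0.5)
  center <- alkscan:::random_dna(1200, 0.5)
  right_bg <- alkscan:::random_dna(150, 0.5)
  seq <- paste0(left_bg, tir, center, revcomp(tir), right_bg)
  cs <- 150 + 25          # center interval = the 1200-nt middle
  ce <- cs + 1200
  # the planted pair is found; chance-matching flanking bases may extend it
  # outward, so the inner boundaries (pinned against the center) are exact
  r0 <- find_tirs(seq, cs, ce, max_mismatch = 0)
  expect_false(is.null(r0))
  expect_equal(r0$left_end, 175)        # planted left copy ends at center
  expect_equal(r0$right_start, 1375)    # planted right copy starts at center
  expect_lte(r0$left_start, 150)
  expect_gte(r0$right_end, 1400)
  expect_gte(r0$length, 25)
  expect_equal(r0$mismatches, 0)
  # the default graded budget still contains the planted copies
  r <- find_tirs(seq, cs, ce)
  expect_false(is.null(r))
  expect_lte(r$left_start, 150)
  expect_gte(r$right_end, 1400)
  expect_gte(r$length, 25)
  expect_lte(r$mismatches, 2)
})

test_that("find_tirs returns nothing on repeat-free sequence", {
  # poly-A cannot pair with its complement at all
  seq <- strrep("A", 2000)
  expect_null(find_tirs(seq, 900, 1100))
  # random background at the package defaults
  set.seed(77)
  for (k in 1:5) {
    seq <- alkscan:::random_dna(3000, 0.5)
    expect_null(find_tirs(seq, 1400, 1600))
  }
})

test_that("find_tirs agrees with the anti-diagonal oracle", {
  set.seed(55)
  for (k in 1:10) {
    n <- sample(1500:3000, 1)
    seq <- alkscan:::random_dna(n, 0.5)
    if (k %% 2 == 0) {   # plant a repeat with one mismatch in half the cases
      tir <- alkscan:::random_dna(22, 0.5)
      rt <- revcomp(tir)
      substr(seq, 450, 471) <- tir
      substr(seq, n - 400, n - 379) <- rt
    }
    cs <- 700; ce <- n - 700
    got <- find_tirs(seq, cs, ce)
    want <- tir_oracle(seq, cs, ce)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$left_start, unname(want["i"]))
      expect_equal(got$right_start, unname(want["j"]))
      expect_equal(got$length, unname(want["L"]))
      expect_equal(got$mismatches, unname(want["mm"]))
    }
  }
})

test_that("planted IS elements are detected with family and completeness", {
  fx <- fixture_scan()                 # g04: IS3 complete + IS30 partial
  sc <- fx$scan
  truth <- fx$survey$truth
  ti <- truth[truth$kind == "is_element", ]
  expect_equal(nrow(ti), 2)
  frag_id <- sc$clusters$fragment_id[1]
  it <- sc$is_elements
  expect_equal(nrow(it), 2)
  expect_setequal(it$family, ti$label)
  for (i in seq_len(nrow(ti))) {
    d <- it[it$family == ti$label[i], ]
    expect_equal(d$complete, ti$complete[i])
    # fragment-local -> genome coordinates recover the planted interval;
    # complete elements may extend a few nt where the mismatch budget lets
    # the terminal repeats grow into the flanking background
    g_start <- d$start + sc$clusters$start[sc$clusters$fragment_id ==
                                             d$fragment_id]
    g_end <- d$end + sc$clusters$start[sc$clusters$fragment_id ==
                                         d$fragment_id]
    expect_lte(abs(g_start - ti$start[i]), 10)
    expect_lte(abs(g_end - ti$end[i]), 10)
  }
})

test_that("fragments without planted IS yield an empty table", {
  fx <- fixture_mini_survey()
  sc <- fx$scan
  cl15 <- sc$clusters[sc$clusters$genome_id == "g15", ]  # no IS planted
  expect_equal(nrow(cl15), 1)
  expect_false(cl15$fragment_id %in% sc$is_elements$fragment_id)
  expect_equal(cl15$n_is, 0L)
})

test_that("every detected element lies within its fragment", {
  fx <- fixture_scan()
  it <- fx$scan$is_elements
  expect_true(all(it$start >= 0))
  expect_true(all(it$end <= 38000))
  expect_error(
    scan_transposases(fx$scan$fragments[[1]],
                      list(refs = data.frame(label = character(),
                                             seq = character()))),
    class = "ConfigError")
})
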