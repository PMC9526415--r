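# Insertion-sequence detection inside alk-fragments: transposase homology
# (same screen as the alk genes) plus terminal-inverted-repeat (TIR) pairing.
# An element is "complete" when a qualifying TIR pair flanks the transposase
# within the family's expected element length.

#' Load the bundled transposase family exemplars
#'
#' Synthetic exemplar transposase proteins for eleven common IS families
#' (IS3, IS5, IS6, IS21, IS30, IS66, IS110, IS256, IS481, IS630, ISL3),
#' shipped as `transposase_references_synthetic.faa` with a sidecar family
#' table giving expected TIR and element length ranges. Replace with curated
#' profiles for real surveys.
#'
#' @param path Optional FASTA path (headers `family|source`).
#' @param family_table Optional TSV path with columns `family`,
#'   `tir_min`, `tir_max`, `element_min`, `element_max`.
#' @return A list with `refs` (data.frame `label`, `seq`) and `families`
#'   (the family table).
#' @export
load_transposase_references <- function(path = NULL, family_table = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transposase_references_synthetic.faa",
                        package = "alkscan", mustWork = TRUE)
  if (is.null(family_table))
    family_table <- system.file("extdata", "is_families_synthetic.tsv",
                                package = "alkscan", mustWork = TRUE)
  fa <- read_fasta(path)
  parts <- strsplit(fa$id, "|", fixed = TRUE)
  refs <- data.frame(label = vapply(parts, `[`, "", 1), seq = fa$seq,
                     stringsAsFactors = FALSE)
  fams <- utils::read.delim(family_table, stringsAsFactors = FALSE)
  stopifnot(all(refs$label %in% fams$family))
  list(refs = refs, families = fams)
}

#' Screen fragment ORFs for transposases
#'
#' @param fragment A re-screened `alk_fragment` (its ORFs are re-called here
#'   from the fragment sequence).
#' @param is_refs Output of [load_transposase_references()].
#' @param params A [scoring_params()].
#' @param min_orf_nt Minimum ORF length for the scan.
#' @return Labeled transposase hits (fragment-local coordinates, `label` =
#'   IS family), best family per ORF with the same tie-breaking as
#'   [assign_alk_labels()].
#' @export
scan_transposases <- function(fragment, is_refs,
                              params = scoring_params(), min_orf_nt = 300) {
  if (is.null(is_refs$refs) || nrow(is_refs$refs) == 0)
    abort_alkscan("empty transposase reference set", "ConfigError")
  orfs <- call_orfs(fragment$sequence, min_nt = min_orf_nt,
                    replicon_id = fragment$replicon_id)
  assign_alk_labels(orfs, is_refs$refs, params)
}

#' Find the best terminal-inverted-repeat pair flanking an interval
#'
#' Searches for a pair of sequences (left, right) flanking `center` such that
#' the left copy is the reverse complement of the right copy, with repeat
#' length in `[min_len, max_len]` and total span (right end - left start) at
#' most `max_span`. Mismatch tolerance is graded by repeat length so that
#' chance pairs in random sequence stay vanishingly rare: short repeats
#' (< 20 nt) must match exactly, repeats of 20-25 nt may carry one mismatch,
#' and only repeats of 26 nt or more use the full `max_mismatch` budget.
#' Candidates are confined to the `flank_nt` windows immediately adjacent to
#' `center`, reflecting that real IS boundaries sit close to the transposase.
#' Best = longest repeat, then fewest mismatches, then leftmost (smallest
#' left start, then smallest right start).
#'
#' @param sequence DNA string (the fragment).
#' @param center_start,center_end 0-based half-open interval the pair must
#'   flank (e.g. the transposase CDS).
#' @param min_len,max_len Repeat length bounds (nt).
#' @param max_span Maximum element span in nt.
#' @param max_mismatch Mismatch budget for long repeats (see above).
#' @param flank_nt Width of the search windows adjacent to the center.
#' @return `NULL` when no pair qualifies; otherwise a list with 0-based
#'   half-open `left_start`, `left_end`, `right_start`, `right_end`, plus
#'   `length` and `mismatches`.
#' @export
find_tirs <- function(sequence, center_start, center_end, min_len = 15,
                      max_len = 45, max_span = 5000, max_mismatch = 2,
                      flank_nt = 400) {
  n <- nchar(sequence)
  stopifnot(center_start >= 0, center_end <= n, center_start < center_end)
  l0 <- max(0L, center_start - flank_nt)
  r1 <- min(n, center_end + flank_nt)
  lens <- min_len:max_len
  allowed <- ifelse(lens < 20, 0L, ifelse(lens < 26, min(1L, max_mismatch),
                                          as.integer(max_mismatch)))
  r <- tir_scan_cpp(sequence, as.integer(center_start),
                    as.integer(center_end), as.integer(l0),
                    as.integer(center_end), as.integer(r1),
                    as.integer(min_len), as.integer(max_len),
                    as.integer(max_span), as.integer(allowed))
  if (length(r) == 0) return(NULL)
  list(left_start = r[1], left_end = r[1] + r[3],
       right_start = r[2], right_end = r[2] + r[3],
       length = r[3], mismatches = r[4])
}

#' Detect IS elements in an alk-fragment
#'
#' Each transposase hit is extended by a TIR search constrained by its
#' family's expected element length; overlapping elements of the same family
#' are merged, keeping the higher bit score.
#'
#' @param fragment A re-screened `alk_fragment`.
#' @param is_refs Output of [load_transposase_references()].
#' @param params A [scoring_params()].
#' @param tir_min_len,tir_max_len,tir_max_mismatch TIR search parameters
#'   (see [find_tirs()]).
#' @return A data.frame of IS elements with fragment-local 0-based half-open
#'   coordinates: `family`, `start`, `end`, `complete`, `tir_len`,
#'   `tir_mismatches`, `tnp_start`, `tnp_end`, `bit_score`.
#' @export
detect_is_elements <- function(fragment, is_refs,
                               params = scoring_params(),
                               tir_min_len = 15, tir_max_len = 45,
                               tir_max_mismatch = 2) {
  hits <- scan_transposases(fragment, is_refs, params)
  empty <- data.frame(family = character(), start = integer(),
                      end = integer(), complete = logical(),
                      tir_len = integer(), tir_mismatches = integer(),
                      tnp_start = integer(), tnp_end = integer(),
                      bit_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  fams <- is_refs$families
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    fam <- fams[fams$family == h$label, ]
    span <- min(5000L, fam$element_max[1])
    tir <- find_tirs(fragment$sequence, h$start, h$end,
                     min_len = tir_min_len, max_len = tir_max_len,
                     max_span = span, max_mismatch = tir_max_mismatch)
    if (!is.null(tir)) {
      data.frame(family = h$label, start = tir$left_start,
                 end = tir$right_end, complete = TRUE,
                 tir_len = tir$length, tir_mismatches = tir$mismatches,
                 tnp_start = h$start, tnp_end = h$end,
                 bit_score = h$bit_score, stringsAsFactors = FALSE)
    } else {
      data.frame(family = h$label, start = h$start, end = h$end,
                 complete = FALSE, tir_len = NA_integer_,
                 tir_mismatches = NA_integer_, tnp_start = h$start,
                 tnp_end = h$end, bit_score = h$bit_score,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  # merge overlapping same-family elements, keep the higher bit score
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (i == j || !keep[j]) next
      if (out$family[i] == out$family[j] &&
          out$start[i] < out$end[j] && out$start[j] < out$end[i]) {
        drop <- if (out$bit_score[i] >= out$bit_score[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
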