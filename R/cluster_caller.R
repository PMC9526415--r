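# Two-step alk-gene-cluster identification.
#
# Step 1: marker co-localization. Every alkB hit whose alkG, alkH and alkJ
# companions all lie within the flanking window (nearest-boundary distance)
# on the same replicon seeds a candidate locus; the 38-kb window around the
# alkB start codon (10 kb upstream, 28 kb downstream, strand-aware) is
# extracted. Windows clipped by a replicon end are excluded as truncated.
#
# Step 2: each fragment is re-annotated in isolation (ORFs re-called on the
# fragment sequence alone, all ten alk labels screened); fragments that lose
# their alkB anchor or retain fewer than three distinct alk labels are
# rejected — the automated surrogate for the original manual review.

#' Configuration of the cluster caller
#'
#' @param flank_nt Maximum nearest-boundary distance (nt) between the alkB
#'   interval and each required marker.
#' @param upstream_nt,downstream_nt Fragment window relative to the alkB
#'   start codon, in gene orientation.
#' @param required_markers Labels that must co-localize with the anchor.
#' @param anchor Anchor label (alkB).
#' @param pseudogene_min_fraction Hits whose aligned subject fraction falls
#'   below this are flagged as pseudogenes.
#' @param min_distinct_labels Minimum distinct alk labels a fragment must
#'   retain after re-screening.
#' @param min_orf_nt Minimum ORF length (nt) used in ORF calling.
#' @param strand_aware If `FALSE`, the window is laid out left-to-right in
#'   genome coordinates regardless of anchor strand (the naive reading).
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(flank_nt = 10000, upstream_nt = 10000,
                           downstream_nt = 28000,
                           required_markers = c("alkG", "alkH", "alkJ"),
                           anchor = "alkB", pseudogene_min_fraction = 0.6,
                           min_distinct_labels = 3, min_orf_nt = 90,
                           strand_aware = TRUE) {
  stopifnot(flank_nt > 0, upstream_nt > 0, downstream_nt > 0,
            identical(anchor, "alkB"))
  structure(list(flank_nt = flank_nt, upstream_nt = upstream_nt,
                 downstream_nt = downstream_nt,
                 required_markers = required_markers, anchor = anchor,
                 pseudogene_min_fraction = pseudogene_min_fraction,
                 min_distinct_labels = min_distinct_labels,
                 min_orf_nt = min_orf_nt, strand_aware = strand_aware),
            class = "cluster_config")
}

#' Find candidate alkB anchors by marker co-localization
#'
#' @param hits Labeled gene calls of one genome ([assign_alk_labels()] output
#'   with resolved coordinates).
#' @param cfg A [cluster_config()].
#' @return The subset of `hits` rows that are qualifying alkB anchors: each
#'   required marker has at least one hit within `flank_nt` (nearest-boundary
#'   distance, 0 for overlap) on the same replicon.
#' @export
find_candidate_loci <- function(hits, cfg = cluster_config()) {
  if (is.null(hits) || nrow(hits) == 0) return(hits[0, , drop = FALSE])
  anchors <- hits[hits$label == cfg$anchor, , drop = FALSE]
  if (nrow(anchors) == 0) return(anchors)
  keep <- vapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    near <- hits[hits$replicon_id == a$replicon_id, , drop = FALSE]
    gaps <- interval_gap(a$start, a$end, near$start, near$end)
    all(vapply(cfg$required_markers, function(lab)
      any(near$label == lab & gaps <= cfg$flank_nt), logical(1)))
  }, logical(1))
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the alk-fragment window around one anchor
#'
#' The window runs from `upstream_nt` before to `downstream_nt` after the
#' alkB start codon, in gene orientation: for a + strand anchor starting at
#' s the window is `[s - upstream, s + downstream)`; for a - strand anchor
#' ending at e it is `[e - downstream, e + upstream)`. A window clipped by a
#' replicon end is marked truncated and later excluded (but logged).
#'
#' @param assembly A [genome_assembly()].
#' @param anchor One anchor row from [find_candidate_loci()].
#' @param cfg A [cluster_config()].
#' @return An `alk_fragment` list: `genome_id`, `replicon_id`, `start`,
#'   `end`, `sequence` (forward genome strand), `anchor` (the hit row with
#'   fragment-local `local_start`/`local_end`), `truncated`, `replicon_class`.
#' @export
extract_fragment <- function(assembly, anchor, cfg = cluster_config()) {
  seqs <- assembly$replicons
  if (!anchor$replicon_id %in% names(seqs))
    abort_alkscan(paste0("anchor replicon missing from assembly: ",
                         anchor$replicon_id), "ConsistencyError")
  L <- nchar(seqs[[anchor$replicon_id]])
  plus <- !cfg$strand_aware || anchor$strand == "+"
  if (plus) {
    s <- anchor$start
    w0 <- s - cfg$upstream_nt
    w1 <- s + cfg$downstream_nt
  } else {
    e <- anchor$end
    w0 <- e - cfg$downstream_nt
    w1 <- e + cfg$upstream_nt
  }
  truncated <- w0 < 0 || w1 > L
  c0 <- max(0, w0); c1 <- min(L, w1)
  frag_seq <- substr(seqs[[anchor$replicon_id]], c0 + 1, c1)
  anchor$local_start <- anchor$start - c0
  anchor$local_end <- anchor$end - c0
  structure(list(genome_id = assembly$genome_id,
                 replicon_id = anchor$replicon_id,
                 start = c0, end = c1, sequence = frag_seq,
                 anchor = anchor, truncated = truncated,
                 replicon_class =
                   unname(assembly$replicon_class[anchor$replicon_id])),
            class = "alk_fragment")
}

#' Re-annotate a fragment in isolation
#'
#' ORFs are re-called on the fragment sequence alone and screened against all
#' ten alk labels; hits whose aligned subject fraction falls below
#' `cfg$pseudogene_min_fraction` are flagged as pseudogenes. The fragment is
#' accepted only if the anchor retains its alkB label and at least
#' `cfg$min_distinct_labels` distinct alk labels survive.
#'
#' @param fragment An `alk_fragment` from [extract_fragment()].
#' @param references Alk reference proteins ([load_alk_references()]).
#' @param params A [scoring_params()].
#' @param cfg A [cluster_config()].
#' @return The fragment with `hits` (fragment-local labeled gene calls, with
#'   `is_pseudogene`), `accepted` and `reject_reason` fields added.
#' @export
rescreen_fragment <- function(fragment, references,
                              params = scoring_params(),
                              cfg = cluster_config()) {
  orfs <- call_orfs(fragment$sequence, min_nt = cfg$min_orf_nt,
                    replicon_id = fragment$replicon_id)
  hits <- assign_alk_labels(orfs, references, params)
  hits$is_pseudogene <- hits$aligned_subject_fraction <
    cfg$pseudogene_min_fraction
  fragment$hits <- hits
  a <- fragment$anchor
  anchor_kept <- any(
    hits$label == cfg$anchor & hits$strand == a$strand &
      pmin(hits$end, a$local_end) - pmax(hits$start, a$local_start) >=
        0.9 * (a$local_end - a$local_start))
  enough <- length(unique(hits$label)) >= cfg$min_distinct_labels
  fragment$accepted <- anchor_kept && enough
  fragment$reject_reason <- if (fragment$accepted) "" else if (!anchor_kept)
    "anchor_lost_on_rescreen" else "too_few_labels"
  fragment
}

#' Replicon class of the replicon carrying a fragment's anchor
#'
#' @param fragment An `alk_fragment`.
#' @param assembly The [genome_assembly()] it came from.
#' @return `"chromosome"`, `"plasmid"` or `"contig_scaffold"`.
#' @export
classify_fragment_replicon <- function(fragment, assembly) {
  unname(assembly$replicon_class[fragment$replicon_id])
}

#' Multi-copy report: fragment counts and same-replicon separations
#'
#' @param fragments_df A data.frame of final fragments with columns
#'   `genome_id`, `replicon_id`, `start`, `end`.
#' @return A data.frame with one row per genome: `genome_id`, `n_fragments`,
#'   and `separations` (comma-joined nearest-boundary distances in nt between
#'   fragment pairs sharing a replicon; empty when none do).
#' @export
detect_multicopy <- function(fragments_df) {
  if (nrow(fragments_df) == 0)
    return(data.frame(genome_id = character(), n_fragments = integer(),
                      separations = character(), stringsAsFactors = FALSE))
  by_g <- split(fragments_df, fragments_df$genome_id)
  rows <- lapply(by_g, function(g) {
    seps <- integer(0)
    if (nrow(g) > 1) {
      for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
        if (g$replicon_id[i] == g$replicon_id[j])
          seps <- c(seps, interval_gap(g$start[i], g$end[i],
                                       g$start[j], g$end[j]))
      }
    }
    data.frame(genome_id = g$genome_id[1], n_fragments = nrow(g),
               separations = paste(seps, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC contrast between a fragment and its host genome
#'
#' @param fragment An `alk_fragment`.
#' @param assembly The host [genome_assembly()].
#' @return A list with `gc_fragment`, `gc_genome` (all replicons pooled) and
#'   `delta = gc_fragment - gc_genome`, all in percent (points for `delta`).
#' @export
fragment_gc_delta <- function(fragment, assembly) {
  gcf <- 100 * gc_content(fragment$sequence)
  all_seq <- paste(assembly$replicons, collapse = "")
  gcg <- 100 * gc_content(all_seq)
  list(gc_fragment = gcf, gc_genome = gcg, delta = gcf - gcg)
}
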