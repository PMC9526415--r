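# ORF prediction on both strands, bacterial genetic code.
#
# Replaces an external gene caller for the purposes of cluster detection: the
# downstream homology screen only needs maximal protein-coding ORFs.

.start_codons <- c("ATG", "GTG", "TTG")
.stop_codons <- c("TAA", "TAG", "TGA")

.genetic_code <- NULL
genetic_code <- function() {
  # amino-acid assignments of the bacterial table (identical to the standard
  # table; the difference is the wider start-codon set handled above)
  if (is.null(.genetic_code))
    utils::assignInMyNamespace(".genetic_code", Biostrings::GENETIC_CODE)
  .genetic_code
}

# ORFs of one strand of one sequence, 0-based half-open coordinates on that
# strand. Codons containing non-ACGT characters break ORFs.
# Returns a data.frame(start, end, protein).
orfs_one_strand <- function(seq, min_nt) {
  n <- nchar(seq)
  gc_tab <- genetic_code()
  starts <- integer(0); ends <- integer(0); prots <- character(0)
  for (frame in 0:2) {
    if (n - frame < 3) next
    starts_at <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts_at, starts_at + 2L)
    is_stop <- codons %in% .stop_codons
    is_start <- codons %in% .start_codons
    is_bad <- grepl("[^ACGT]", codons)
    # boundaries: positions after which an ORF cannot extend
    brk <- which(is_stop | is_bad)
    seg_start <- c(1L, brk + 1L)     # codon index where each segment begins
    seg_stop <- c(brk, length(codons) + 1L)  # codon index of the terminator
    for (k in seq_along(seg_start)) {
      i0 <- seg_start[k]; i1 <- seg_stop[k]
      if (i1 > length(codons)) next            # runs off the end: not stop-anchored
      if (is_bad[i1]) next                     # broken by ambiguity, no stop
      if (i1 <= i0) next                       # empty segment (adjacent stops)
      cand <- i0 - 1L + which(is_start[i0:(i1 - 1L)])
      if (length(cand) == 0) next
      first <- cand[1]                         # longest ORF for this stop
      len_nt <- (i1 - first + 1L) * 3L         # includes the stop codon
      if (len_nt < min_nt) next
      aa <- unname(gc_tab[codons[first:(i1 - 1L)]])
      aa[1] <- "M"                             # start-codon normalization
      starts <- c(starts, starts_at[first] - 1L)   # 0-based
      ends <- c(ends, starts_at[i1] + 2L)          # incl. the stop codon
      prots <- c(prots, paste(aa, collapse = ""))
    }
  }
  data.frame(start = starts, end = ends, protein = prots,
             stringsAsFactors = FALSE)
}

#' Predict open reading frames on both strands
#'
#' Finds all maximal stop-anchored ORFs under the bacterial genetic code
#' (start codons ATG/GTG/TTG, stops TAA/TAG/TGA): per frame, for each stop
#' codon the longest ORF (first start codon after the previous stop) is
#' reported. GTG/TTG starts translate as M. Codons containing ambiguous bases
#' break ORFs; an ORF never spans an N run.
#'
#' @param seq A nucleotide sequence (character scalar) or a single-row record
#'   from [read_fasta()].
#' @param min_nt Minimum ORF length in nucleotides including the stop codon;
#'   must be >= 6 and divisible by 3.
#' @param replicon_id Replicon name recorded in the output.
#' @return A data.frame with columns `replicon_id`, `start`, `end` (0-based
#'   half-open, on the forward strand), `strand`, `protein` (stop removed) and
#'   `gene_index`, sorted by `start`.
#' @export
call_orfs <- function(seq, min_nt = 90, replicon_id = "seq") {
  if (is.data.frame(seq)) {
    replicon_id <- seq$id[1]
    seq <- seq$seq[1]
  }
  if (min_nt < 6 || min_nt %% 3 != 0)
    abort_alkscan("min_nt must be >= 6 and divisible by 3", "ConfigError")
  seq <- toupper(seq)
  if (grepl("[^ACGTRYSWKMBDHVN]", seq))
    abort_alkscan("sequence contains non-IUPAC characters", "FormatError")
  n <- nchar(seq)
  fwd <- orfs_one_strand(seq, min_nt)
  rev <- orfs_one_strand(revcomp(seq), min_nt)
  out <- rbind(
    data.frame(replicon_id = rep(replicon_id, nrow(fwd)), start = fwd$start,
               end = fwd$end, strand = rep("+", nrow(fwd)),
               protein = fwd$protein, stringsAsFactors = FALSE),
    data.frame(replicon_id = rep(replicon_id, nrow(rev)),
               start = n - rev$end, end = n - rev$start,
               strand = rep("-", nrow(rev)), protein = rev$protein,
               stringsAsFactors = FALSE))
  if (nrow(out) == 0)
    return(data.frame(replicon_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), gene_index = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$gene_index <- seq_len(nrow(out))
  out
}
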