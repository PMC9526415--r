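# Protein homology screening: Smith-Waterman local alignment with affine
# gaps, Karlin-Altschul E-values, and best-hit label assignment against the
# bundled alk-gene reference set. This stands in for a full blastp search;
# the operating threshold (E <= 1e-10) is far from the decision boundary for
# true alk homologs, so no composition-based or length corrections are used.

.aa_alphabet <- NULL

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Scoring parameters for the protein homology screen
#'
#' Defaults are the classic gapped blastp settings: BLOSUM62, gap open 11,
#' gap extend 1, with Karlin-Altschul constants lambda = 0.267, K = 0.041 for
#' that scoring system, and an E-value cutoff of 1e-10.
#'
#' @param matrix Substitution matrix (numeric matrix with residue dimnames).
#' @param gap_open,gap_extend Gap penalties as positive magnitudes; a gap of
#'   length k costs `gap_open + k * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters for the gapped scoring system.
#' @param evalue_threshold Keep hits with E-value at or below this.
#' @param word_size Length of the exact-word seed required before a full
#'   alignment is computed in [assign_alk_labels()] (a blastp-like seeding
#'   heuristic); 0 disables seeding.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041,
                           evalue_threshold = 1e-10, word_size = 5) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 evalue_threshold = evalue_threshold, word_size = word_size),
            class = "scoring_params")
}

encode_protein <- function(x, alphabet) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(codes)) {
    warning("unknown residue(s) scored via the matrix wildcard row")
    codes[is.na(codes)] <- match("X", alphabet)
  }
  codes
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' @param query,subject Amino-acid strings.
#' @param params A [scoring_params()] object.
#' @return A list with `raw_score`, `bit_score`, `evalue`, 1-based aligned
#'   spans `q_start`/`q_end`/`s_start`/`s_end`, and
#'   `aligned_subject_fraction` (aligned subject span / subject length).
#' @export
align_proteins <- function(query, subject, params = scoring_params()) {
  if (!nzchar(query) || !nzchar(subject))
    abort_alkscan("empty sequence", "EmptyInput")
  alphabet <- rownames(params$matrix)
  q <- encode_protein(query, alphabet)
  s <- encode_protein(subject, alphabet)
  r <- sw_align_cpp(q, s, params$matrix, as.integer(params$gap_open),
                    as.integer(params$gap_extend))
  score <- r$score
  m <- nchar(query); n <- nchar(subject)
  list(raw_score = score,
       bit_score = bit_score(score, params),
       evalue = estimate_evalue(score, m, n, params),
       q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end,
       aligned_subject_fraction =
         if (score > 0) (r$s_end - r$s_start + 1) / n else 0)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` with raw search-space size `m * n`
#' (no effective-length adjustment).
#'
#' @param raw_score Raw alignment score S.
#' @param m,n Query and subject lengths.
#' @param params A [scoring_params()] object supplying lambda and K.
#' @return The expected number of chance alignments scoring >= S.
#' @export
estimate_evalue <- function(raw_score, m, n, params = scoring_params()) {
  stopifnot(m > 0, n > 0)
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' @inheritParams estimate_evalue
#' @return `(lambda * S - log(K)) / log(2)`.
#' @export
bit_score <- function(raw_score, params = scoring_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

# exact-word seed filter: does query share any word of length w with subject?
shares_word <- function(query, subject_words, w) {
  nq <- nchar(query)
  if (nq < w) return(FALSE)
  qw <- substring(query, 1:(nq - w + 1), w:nq)
  any(qw %in% subject_words)
}

ref_words <- function(refs, w) {
  lapply(seq_len(nrow(refs)), function(i) {
    s <- refs$seq[i]
    if (nchar(s) < w) return(character(0))
    unique(substring(s, 1:(nchar(s) - w + 1), w:nchar(s)))
  })
}

#' Assign alk-gene (or IS-family) labels to gene calls by best homology hit
#'
#' Every gene call is aligned against every reference protein; hits with
#' E-value at or below the threshold are kept and the best label per gene call
#' wins (highest bit score, ties by lowest E-value, then reference order).
#' A blastp-like exact-word seed (`params$word_size`) skips hopeless pairs;
#' any pair sharing no seed word cannot reach the 1e-10 operating threshold.
#'
#' @param gene_calls Data.frame from [call_orfs()] (needs `protein`).
#' @param references Data.frame with columns `label` and `seq` (one or more
#'   reference proteins per label), e.g. from [load_alk_references()].
#' @param params A [scoring_params()] object.
#' @return The qualifying subset of `gene_calls` with columns `label`,
#'   `raw_score`, `bit_score`, `evalue`, `s_start`, `s_end`, `subject_len`,
#'   `aligned_subject_fraction` appended.
#' @export
assign_alk_labels <- function(gene_calls, references,
                              params = scoring_params()) {
  if (is.null(references) || nrow(references) == 0)
    abort_alkscan("empty reference set", "ConfigError")
  empty <- cbind(gene_calls[0, , drop = FALSE],
                 data.frame(label = character(), raw_score = numeric(),
                            bit_score = numeric(), evalue = numeric(),
                            s_start = integer(), s_end = integer(),
                            subject_len = integer(),
                            aligned_subject_fraction = numeric()))
  if (nrow(gene_calls) == 0) return(empty)
  w <- params$word_size
  words <- if (w > 0) ref_words(references, w) else NULL
  best <- vector("list", nrow(gene_calls))
  for (i in seq_len(nrow(gene_calls))) {
    prot <- gene_calls$protein[i]
    nq <- nchar(prot)
    qw <- if (w > 0 && nq >= w) substring(prot, 1:(nq - w + 1), w:nq) else
      character(0)
    hit <- NULL
    for (j in seq_len(nrow(references))) {
      if (w > 0 && !any(qw %in% words[[j]])) next
      al <- align_proteins(prot, references$seq[j], params)
      if (al$evalue > params$evalue_threshold) next
      better <- is.null(hit) ||
        al$bit_score > hit$bit_score ||
        (al$bit_score == hit$bit_score && al$evalue < hit$evalue)
      if (better) {
        hit <- al
        hit$label <- references$label[j]
        hit$subject_len <- nchar(references$seq[j])
      }
    }
    if (!is.null(hit)) {
      row <- gene_calls[i, , drop = FALSE]
      row$label <- hit$label
      row$raw_score <- hit$raw_score
      row$bit_score <- hit$bit_score
      row$evalue <- hit$evalue
      row$s_start <- hit$s_start
      row$s_end <- hit$s_end
      row$subject_len <- hit$subject_len
      row$aligned_subject_fraction <- hit$aligned_subject_fraction
      best[[i]] <- row
    }
  }
  best <- best[!vapply(best, is.null, logical(1))]
  if (length(best) == 0) return(empty)
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out
}

.alk_labels <- c("alkB", "alkF", "alkG", "alkH", "alkJ", "alkK", "alkL",
                 "alkN", "alkS", "alkT")

#' Load the bundled alk-gene reference proteins
#'
#' The bundled set consists of synthetic exemplar proteins (one per label,
#' deterministic, shipped as `alk_references_synthetic.faa`); supply your own
#' curated FASTA (headers `label|source`) to screen against real references.
#'
#' @param path Optional path to a reference FASTA; default = bundled set.
#' @return A data.frame with columns `label`, `source`, `seq`.
#' @export
load_alk_references <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "alk_references_synthetic.faa",
                        package = "alkscan", mustWork = TRUE)
  fa <- read_fasta(path)
  parts <- strsplit(fa$id, "|", fixed = TRUE)
  refs <- data.frame(label = vapply(parts, `[`, "", 1),
                     source = vapply(parts, function(p)
                       if (length(p) > 1) p[2] else "", ""),
                     seq = fa$seq, stringsAsFactors = FALSE)
  bad <- setdiff(refs$label, .alk_labels)
  if (length(bad))
    abort_alkscan(paste0("unexpected alk reference label: ", bad[1]),
                  "ConfigError")
  refs
}
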