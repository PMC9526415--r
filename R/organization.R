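# Gene-organization encoding and comparison.
#
# Fragments are aligned on the alkB start codon: a fragment whose anchor sits
# on the minus strand is flipped before tokens are emitted, so organization
# strings are comparable across strands. IS elements are tracked separately
# and never appear in the token sequence.

#' Encode the alk-gene organization of a fragment
#'
#' @param fragment A re-screened `alk_fragment` (with `hits`).
#' @return An `organization` list: `tokens` (data.frame `label`, `strand`
#'   relative to alkB, `pseudogene`), `anchor_offset` (0-based index of the
#'   anchor token) and `string` (e.g. `"alkS>,alkB>,alkG>"`, `<` marking
#'   genes antisense to alkB and `*` marking pseudogenes).
#' @export
encode_organization <- function(fragment) {
  hits <- fragment$hits
  if (is.null(hits) || !any(hits$label == "alkB"))
    abort_alkscan("fragment lacks an alkB hit after re-screening",
                  "ConsistencyError")
  a <- fragment$anchor
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  anchor_strand <- a$strand
  if (anchor_strand == "-") {          # flip so alkB reads left-to-right
    hits <- hits[rev(seq_len(nrow(hits))), , drop = FALSE]
    rel_strand <- ifelse(hits$strand == "-", "+", "-")
  } else {
    rel_strand <- hits$strand
  }
  tokens <- data.frame(label = hits$label, strand = rel_strand,
                       pseudogene = hits$is_pseudogene,
                       stringsAsFactors = FALSE)
  anchor_rows <- which(hits$label == "alkB" & hits$strand == anchor_strand &
                         pmin(hits$end, a$local_end) -
                           pmax(hits$start, a$local_start) > 0)
  anchor_offset <- if (length(anchor_rows)) anchor_rows[1] - 1L else
    which(tokens$label == "alkB")[1] - 1L
  str <- paste0(tokens$label,
                ifelse(tokens$strand == "+", ">", "<"),
                ifelse(tokens$pseudogene, "*", ""), collapse = ",")
  structure(list(tokens = tokens, anchor_offset = anchor_offset,
                 string = str),
            class = "organization")
}

#' Similarity between two organization strings
#'
#' One minus the Levenshtein distance between the label sequences, normalized
#' by the longer length. Strand and pseudogene flags are ignored.
#'
#' @param a,b `organization` objects from [encode_organization()].
#' @return A similarity in `[0, 1]`; 1 iff the label sequences are identical.
#' @export
organization_similarity <- function(a, b) {
  la <- a$tokens$label
  lb <- b$tokens$label
  # map labels to single characters so adist operates on label tokens
  alpha <- unique(c(la, lb))
  code <- stats::setNames(strsplit(intToUtf8(64 + seq_along(alpha)), "")[[1]],
                          alpha)
  d <- utils::adist(paste(code[la], collapse = ""),
                    paste(code[lb], collapse = ""))[1, 1]
  1 - d / max(length(la), length(lb))
}

#' Group fragments into organization types
#'
#' Single-linkage clustering of organization strings: two types merge when
#' any member pair has similarity at or above the threshold. Type ids are
#' assigned deterministically in order of each type's first member.
#'
#' @param organizations A list of `organization` objects (named by
#'   fragment id, or names are taken from the list order).
#' @param threshold Similarity threshold in `[0, 1]`.
#' @return A data.frame with `fragment_id`, `type_id` (`"T1"`, `"T2"`, ...)
#'   and `organization` (the token string).
#' @export
group_organization_types <- function(organizations, threshold = 0.8) {
  n <- length(organizations)
  stopifnot(n >= 1)
  ids <- names(organizations)
  if (is.null(ids)) ids <- sprintf("fragment%03d", seq_len(n))
  if (n == 1) {
    grp <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        1 - organization_similarity(organizations[[i]], organizations[[j]])
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    # merge at distance <= 1 - threshold, i.e. similarity >= threshold
    grp <- stats::cutree(hc, h = 1 - threshold + 1e-9)
  }
  first <- !duplicated(grp)
  relabel <- stats::setNames(seq_len(sum(first)), grp[first])
  data.frame(fragment_id = ids,
             type_id = paste0("T", relabel[as.character(grp)]),
             organization = vapply(organizations, function(o) o$string, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Presence/absence/pseudogene matrix of the ten alk genes
#'
#' @param fragments A named list of re-screened `alk_fragment`s.
#' @return A character matrix (rows = fragments, columns = the ten alk
#'   labels) with cells `"absent"`, `"present"` or `"pseudogene"`. A gene
#'   with both intact and pseudogene hits counts as present.
#' @export
presence_matrix <- function(fragments) {
  ids <- names(fragments)
  if (is.null(ids)) ids <- sprintf("fragment%03d", seq_along(fragments))
  m <- matrix("absent", nrow = length(fragments), ncol = length(.alk_labels),
              dimnames = list(ids, .alk_labels))
  for (i in seq_along(fragments)) {
    h <- fragments[[i]]$hits
    for (lab in unique(h$label)) {
      flags <- h$is_pseudogene[h$label == lab]
      m[i, lab] <- if (all(flags)) "pseudogene" else "present"
    }
  }
  m
}
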