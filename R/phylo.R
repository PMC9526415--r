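# Distance phylogenetics for the alkB monophyly question: p-distances on a
# pre-aligned nucleotide matrix, neighbor-joining, midpoint or outgroup
# rooting, and a monophyly test. NJ recovers the true tree exactly on
# additive distances, which is all the mono-clade property needs; alignment
# itself is out of scope (inputs are gap-free or pre-aligned).

#' Pairwise p-distances from an alignment
#'
#' Proportion of mismatching sites per pair; sites where either sequence has
#' a gap or ambiguity are deleted pairwise.
#'
#' @param aligned Named character vector of equal-length aligned nucleotide
#'   sequences (>= 2).
#' @return A symmetric distance matrix with the sequence names as labels.
#' @export
p_distance <- function(aligned) {
  stopifnot(length(aligned) >= 2, !is.null(names(aligned)))
  if (length(unique(nchar(aligned))) != 1)
    abort_alkscan("aligned sequences must have equal length", "FormatError")
  if (anyDuplicated(names(aligned)))
    abort_alkscan("duplicate sequence labels", "DuplicateId")
  bin <- ape::as.DNAbin(lapply(aligned, function(s)
    strsplit(tolower(s), "", fixed = TRUE)[[1]]))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (anyNA(d))
    abort_alkscan("a sequence pair has zero comparable sites", "ValueError")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' On an additive matrix the true topology and branch lengths are recovered
#' exactly (up to floating point).
#'
#' @param D Symmetric distance matrix with unique labels (>= 3).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) abort_alkscan("need at least 3 taxa", "ValueError")
  stopifnot(isSymmetric(unname(D)))
  ape::nj(D)
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path. The unrooted
#' topology and total branch length are preserved.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    abort_alkscan("tree has no positive branch lengths", "ValueError")
  phangorn::midpoint(tree)
}

#' Root a tree with an outgroup
#'
#' @param tree An unrooted `phylo` tree.
#' @param outgroup Tip label(s) forming one side of a branch of the tree.
#' @return A `phylo` tree rooted on the branch separating the outgroup from
#'   the ingroup.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  unknown <- setdiff(outgroup, tips)
  if (length(unknown))
    abort_alkscan(paste0("outgroup tip not in tree: ", unknown[1]),
                  "ValueError")
  if (length(outgroup) == 0 || length(outgroup) >= length(tips))
    abort_alkscan("outgroup must be a proper non-empty subset of the tips",
                  "ValueError")
  if (length(outgroup) > 1 &&
      !ape::is.monophyletic(tree, outgroup, reroot = TRUE))
    abort_alkscan("outgroup does not form a split of the tree", "ValueError")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Is a tip set monophyletic in a rooted tree?
#'
#' True iff some node's descendant leaf set equals `tips` exactly. The
#' complement of a clade is not itself assumed to be a clade.
#'
#' @param tree A rooted `phylo` tree.
#' @param tips Non-empty subset of the tree's tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    abort_alkscan(paste0("unknown tip: ", unknown[1]), "ValueError")
  if (length(tips) == 0) abort_alkscan("empty tip set", "ValueError")
  ape::is.monophyletic(tree, tips)
}

#' Read / write Newick trees
#'
#' Thin wrappers fixing the text-based Newick interchange used throughout.
#'
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
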