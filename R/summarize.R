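# Survey-level summary tables: replicon-location tallies, niche x taxonomy
# cross-tabulation, and the IS-family distribution matrix (IS counts
# normalized by fragment count per taxonomy group).

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

taxonomy_rank <- function(lineage, rank = "genus") {
  idx <- match(rank, .tax_ranks)
  stopifnot(!is.na(idx))
  vapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    if (length(p) >= idx && nzchar(p[idx])) p[idx] else "unclassified"
  }, character(1))
}

#' IS-family distribution matrix by taxonomy group
#'
#' Cell (group, family) = number of IS elements of that family across the
#' group's fragments, divided by the group's fragment count. Multiplying a
#' row by its group's fragment count recovers the raw integer counts.
#'
#' @param cluster_table Survey cluster table (one row per final fragment)
#'   with columns `fragment_id` and `taxonomy`.
#' @param is_table IS-element table with columns `fragment_id` and `family`.
#' @param rank Taxonomy rank used for grouping (a single uniform rank; rows
#'   mixing ranks as in hand-curated figures are not attempted).
#' @return A list with `matrix` (groups x families, normalized),
#'   `fragment_counts` (per group) and `family_totals` (per family).
#' @export
is_distribution_matrix <- function(cluster_table, is_table, rank = "genus") {
  groups <- taxonomy_rank(cluster_table$taxonomy, rank)
  names(groups) <- cluster_table$fragment_id
  group_levels <- unique(groups)
  fam_levels <- sort(unique(is_table$family))
  n_frag <- table(factor(groups, levels = group_levels))
  m <- matrix(0, length(group_levels), max(1, length(fam_levels)),
              dimnames = list(group_levels,
                              if (length(fam_levels)) fam_levels else "none"))
  if (nrow(is_table) > 0) {
    is_groups <- groups[is_table$fragment_id]
    counts <- table(factor(is_groups, levels = group_levels),
                    factor(is_table$family, levels = fam_levels))
    m <- sweep(unclass(counts), 1, as.numeric(n_frag), "/")
  }
  list(matrix = m,
       fragment_counts = as.integer(n_frag),
       family_totals = if (nrow(is_table) > 0)
         as.integer(table(factor(is_table$family, levels = fam_levels)))
       else integer(0))
}

#' Niche x taxonomy cross-tabulation of cluster-carrying genomes
#'
#' @param genome_table One row per genome carrying at least one cluster,
#'   with columns `genome_id`, `taxonomy`, `niche`.
#' @param rank Taxonomy rank for the rows.
#' @return A contingency table (taxonomy group x niche) of genome counts;
#'   empty niche labels are reported as `"unknown"`.
#' @export
niche_taxonomy_table <- function(genome_table, rank = "genus") {
  grp <- taxonomy_rank(genome_table$taxonomy, rank)
  niche <- ifelse(is.na(genome_table$niche) | !nzchar(genome_table$niche),
                  "unknown", genome_table$niche)
  table(taxonomy = grp, niche = niche)
}

#' Replicon-location tally of final fragments
#'
#' @param cluster_table Survey cluster table with a `replicon_class` column.
#' @return Named integer vector `c(chromosome, plasmid, contig_scaffold)`
#'   summing to the number of fragments.
#' @export
replicon_location_summary <- function(cluster_table) {
  lv <- c("chromosome", "plasmid", "contig_scaffold")
  out <- table(factor(cluster_table$replicon_class, levels = lv))
  stats::setNames(as.integer(out), lv)
}
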