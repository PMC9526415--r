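# End-to-end survey scan: ORF calling and homology screening per replicon,
# marker co-localization, fragment extraction with truncation exclusion,
# fragment re-annotation, IS detection, organization typing and summary
# tables, with a stage-count log mirroring the filtering funnel
# (candidates -> extracted -> excluded/rejected -> final).

#' Scan a set of assemblies for alk-gene clusters
#'
#' @param assemblies A list of [genome_assembly()] objects (e.g. from
#'   [generate_survey()], or built from FASTA + metadata files).
#' @param refs Alk-gene reference proteins ([load_alk_references()]).
#' @param is_refs Transposase references ([load_transposase_references()]);
#'   `NULL` skips IS detection.
#' @param params A [scoring_params()].
#' @param cfg A [cluster_config()].
#' @return A `survey_scan` list:
#'   \describe{
#'     \item{clusters}{one row per final fragment (coordinates, replicon
#'       class, labels, GC contrast, organization type, taxonomy, niche)}
#'     \item{fragments}{the `alk_fragment` objects, named by fragment id}
#'     \item{gene_hits}{per-fragment alk hits in genome coordinates}
#'     \item{is_elements}{IS table in fragment-local coordinates}
#'     \item{excluded}{truncated or rejected fragments with reasons}
#'     \item{multicopy}{[detect_multicopy()] report}
#'     \item{presence}{[presence_matrix()] over the final fragments}
#'     \item{log}{stage counters}
#'   }
#' @export
scan_survey <- function(assemblies, refs = load_alk_references(),
                        is_refs = load_transposase_references(),
                        params = scoring_params(), cfg = cluster_config()) {
  fragments <- list()
  excluded <- list()
  cluster_rows <- list()
  is_rows <- list()
  hit_rows <- list()
  n_candidates <- 0L
  n_extracted <- 0L

  for (asm in assemblies) {
    hits <- do.call(rbind, lapply(names(asm$replicons), function(rid)
      assign_alk_labels(call_orfs(asm$replicons[[rid]],
                                  min_nt = cfg$min_orf_nt,
                                  replicon_id = rid),
                        refs, params)))
    anchors <- find_candidate_loci(hits, cfg)
    n_candidates <- n_candidates + nrow(anchors)
    if (nrow(anchors) == 0) next
    seen <- character(0)
    for (a in seq_len(nrow(anchors))) {
      frag <- extract_fragment(asm, anchors[a, ], cfg)
      key <- paste(frag$replicon_id, frag$start, frag$end)
      if (key %in% seen) next                     # identical window: dedupe
      seen <- c(seen, key)
      n_extracted <- n_extracted + 1L
      fid <- paste0(asm$genome_id, "_f", length(seen))
      if (frag$truncated) {
        excluded[[length(excluded) + 1]] <- data.frame(
          fragment_id = fid, genome_id = asm$genome_id,
          replicon_id = frag$replicon_id, start = frag$start,
          end = frag$end, reason = "truncated_at_replicon_end",
          stringsAsFactors = FALSE)
        next
      }
      frag <- rescreen_fragment(frag, refs, params, cfg)
      if (!frag$accepted) {
        excluded[[length(excluded) + 1]] <- data.frame(
          fragment_id = fid, genome_id = asm$genome_id,
          replicon_id = frag$replicon_id, start = frag$start,
          end = frag$end, reason = frag$reject_reason,
          stringsAsFactors = FALSE)
        next
      }
      frag$fragment_id <- fid
      gc <- fragment_gc_delta(frag, asm)
      is_tab <- if (!is.null(is_refs))
        detect_is_elements(frag, is_refs, params)
      else data.frame()
      frag$is_elements <- is_tab
      org <- encode_organization(frag)
      frag$organization <- org
      fragments[[fid]] <- frag
      labs <- sort(unique(frag$hits$label))
      pseudo <- sort(unique(frag$hits$label[frag$hits$is_pseudogene]))
      cluster_rows[[length(cluster_rows) + 1]] <- data.frame(
        fragment_id = fid, genome_id = asm$genome_id,
        replicon_id = frag$replicon_id, start = frag$start,
        end = frag$end, anchor_strand = frag$anchor$strand,
        replicon_class = frag$replicon_class,
        n_genes = nrow(frag$hits),
        labels_present = paste(labs, collapse = ","),
        pseudogenes = paste(pseudo, collapse = ","),
        n_is = nrow(is_tab),
        gc_fragment = round(gc$gc_fragment, 3),
        gc_genome = round(gc$gc_genome, 3),
        gc_delta = round(gc$delta, 3),
        organization = org$string,
        taxonomy = asm$taxonomy, niche = asm$niche,
        stringsAsFactors = FALSE)
      if (nrow(is_tab) > 0)
        is_rows[[length(is_rows) + 1]] <-
          cbind(data.frame(fragment_id = fid, stringsAsFactors = FALSE),
                is_tab)
      h <- frag$hits
      if (nrow(h) > 0) {
        h$fragment_id <- fid
        h$genome_id <- asm$genome_id
        h$replicon_id <- frag$replicon_id
        h$start <- h$start + frag$start      # back to genome coordinates
        h$end <- h$end + frag$start
        hit_rows[[length(hit_rows) + 1]] <- h
      }
    }
  }

  empty_cl <- data.frame(fragment_id = character(), genome_id = character(),
                         replicon_id = character(), start = integer(),
                         end = integer(), anchor_strand = character(),
                         replicon_class = character(), n_genes = integer(),
                         labels_present = character(),
                         pseudogenes = character(), n_is = integer(),
                         gc_fragment = numeric(), gc_genome = numeric(),
                         gc_delta = numeric(), organization = character(),
                         taxonomy = character(), niche = character(),
                         stringsAsFactors = FALSE)
  clusters <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    empty_cl
  if (nrow(clusters) > 0) {
    types <- group_organization_types(
      lapply(fragments, function(f) f$organization))
    clusters$type_id <- types$type_id[match(clusters$fragment_id,
                                            types$fragment_id)]
  } else {
    clusters$type_id <- character(0)
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(fragment_id = character(), genome_id = character(),
               replicon_id = character(), start = integer(),
               end = integer(), reason = character(),
               stringsAsFactors = FALSE)
  is_elements <- if (length(is_rows)) do.call(rbind, is_rows) else
    data.frame(fragment_id = character(), family = character(),
               start = integer(), end = integer(), complete = logical(),
               tir_len = integer(), tir_mismatches = integer(),
               tnp_start = integer(), tnp_end = integer(),
               bit_score = numeric(), stringsAsFactors = FALSE)
  gene_hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(fragment_id = character(), genome_id = character(),
               replicon_id = character(), start = integer(),
               end = integer(), strand = character(), label = character(),
               is_pseudogene = logical(), stringsAsFactors = FALSE)
  rownames(clusters) <- rownames(excluded) <- rownames(is_elements) <-
    rownames(gene_hits) <- NULL

  structure(list(
    clusters = clusters,
    fragments = fragments,
    gene_hits = gene_hits,
    is_elements = is_elements,
    excluded = excluded,
    multicopy = detect_multicopy(clusters),
    presence = presence_matrix(fragments),
    log = c(candidates = n_candidates, extracted = n_extracted,
            excluded = nrow(excluded), final = nrow(clusters))),
    class = "survey_scan")
}

#' @export
print.survey_scan <- function(x, ...) {
  cat("alk-gene cluster survey scan\n")
  cat(sprintf("  candidates: %d; extracted: %d; excluded: %d; final: %d\n",
              x$log["candidates"], x$log["extracted"], x$log["excluded"],
              x$log["final"]))
  if (nrow(x$clusters) > 0) {
    cat(sprintf("  genomes with clusters: %d; organization types: %d\n",
                length(unique(x$clusters$genome_id)),
                length(unique(x$clusters$type_id))))
    loc <- replicon_location_summary(x$clusters)
    cat(sprintf("  location: %d chromosome / %d plasmid / %d contig-scaffold\n",
                loc[1], loc[2], loc[3]))
  }
  invisible(x)
}

#' Write the survey result tables
#'
#' Emits deterministic TSVs (`clusters.tsv`, `multicopy.tsv`,
#' `excluded.tsv`, `is_elements.tsv`, `presence_matrix.tsv`), the fragment
#' sequences (`fragments.fasta`), the fragment gene annotations
#' (`fragments.gff3`, fragment-local 1-based coordinates) and a stage-count
#' log (`log.txt`).
#'
#' @param scan A [scan_survey()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_results <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(scan$clusters, "clusters.tsv")
  tsv(scan$multicopy, "multicopy.tsv")
  tsv(scan$excluded, "excluded.tsv")
  tsv(scan$is_elements, "is_elements.tsv")
  utils::write.table(scan$presence, file.path(dir, "presence_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (length(scan$fragments) > 0) {
    write_fasta(data.frame(
      id = names(scan$fragments),
      desc = vapply(scan$fragments, function(f)
        sprintf("%s:%d-%d", f$replicon_id, f$start + 1, f$end), ""),
      seq = vapply(scan$fragments, function(f) f$sequence, ""),
      stringsAsFactors = FALSE), file.path(dir, "fragments.fasta"))
    gff <- do.call(rbind, lapply(scan$fragments, function(f) {
      h <- f$hits
      data.frame(replicon_id = f$fragment_id, start = h$start, end = h$end,
                 strand = h$strand, type = "CDS",
                 id = paste0(f$fragment_id, "_", seq_len(nrow(h))),
                 label = h$label, stringsAsFactors = FALSE)
    }))
    write_gff3(gff, file.path(dir, "fragments.gff3"))
  }
  writeLines(sprintf("%s\t%d", names(scan$log), scan$log),
             file.path(dir, "log.txt"))
  invisible(dir)
}

#' Write a generated survey to FASTA + metadata files
#'
#' @param survey A [generate_survey()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_survey_inputs <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (asm in survey$assemblies) {
    write_fasta(data.frame(id = names(asm$replicons), desc = "",
                           seq = unname(asm$replicons),
                           stringsAsFactors = FALSE),
                file.path(dir, paste0(asm$genome_id, ".fasta")))
  }
  utils::write.table(survey$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(survey$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read survey assemblies back from a directory of FASTA files + metadata
#'
#' @param dir Directory holding `<genome_id>.fasta` files and `metadata.tsv`.
#' @return A list of [genome_assembly()] objects.
#' @export
read_survey_inputs <- function(dir) {
  md_path <- file.path(dir, "metadata.tsv")
  metadata <- if (file.exists(md_path)) read_metadata(md_path) else NULL
  if (is.null(metadata))
    warning("no metadata.tsv: all replicons classed contig_scaffold")
  fas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  assemblies <- list()
  for (f in fas) {
    gid <- sub("\\.fasta$", "", basename(f))
    fa <- read_fasta(f)
    assemblies[[gid]] <- genome_assembly(
      gid, stats::setNames(fa$seq, fa$id), metadata)
  }
  assemblies
}
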