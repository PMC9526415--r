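# Synthetic genome survey with planted ground truth.
#
# Emulates the input of the real survey at desk scale: assemblies carrying
# alk-gene clusters in four organization templates, with IS elements,
# pseudogenes, multi-copy genomes, plasmid placements, contig fragmentation
# and decoy loci engineered to hit each rejection rule. Planted clusters
# live on a 38-kb island whose background GC follows `cluster_gc` while the
# host genome follows `host_gc`, implementing the known lower-GC signature
# of the cluster region; genes are amino-acid-mutated copies of the bundled
# references, back-translated with GC-biased codon choice.

# stop codons in all three forward frames, no start codons, and not its own
# reverse complement (so planted insulators can never pair as inverted
# repeats); island flips carry the reverse-frame stops along
.insulator <- "TAGATAGATAGA"

.templates <- list(
  pseudomonas_full = c("alkB", "alkF", "alkG", "alkH", "alkJ", "alkK",
                       "alkL", "alkS", "alkT", "alkN"),
  marinobacter = c("alkS", "alkT", "alkB", "alkG", "alkH", "alkJ", "alkK",
                   "alkL"),
  sphingomonadales = c("alkS", "alkB", "alkG", "alkH", "alkJ", "alkL"),
  alcanivorax_minimal = c("alkS", "alkB", "alkG", "alkJ", "alkH"))

#' Organization templates of the synthetic clusters
#'
#' Gene orders for the four planted organization types: the full
#' Pseudomonas-type set (alkBFGHJKL + alkST + alkN), the Marinobacter /
#' Rhodobacterales-type set (alkST + alkBGHJKL), the Sphingomonadales-type
#' set that additionally lacks alkK and alkT, and the minimal
#' Alcanivorax-type set (alkS + alkBGJH).
#'
#' @return Named list of label vectors.
#' @export
organization_templates <- function() .templates

# --- codon machinery -------------------------------------------------------

codon_table <- function() {
  gc <- genetic_code()
  split(names(gc), unname(gc))
}

codon_gc_count <- function(codons) {
  vapply(strsplit(codons, "", fixed = TRUE),
         function(x) sum(x %in% c("G", "C")), integer(1))
}

# expected GC fraction of a back-translated protein when each codon is drawn
# with weight q^gc * (1-q)^(3-gc) among its synonymous codons
expected_bt_gc <- function(protein, q, tab, gcc) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  tot <- 0
  for (a in unique(aas)) {
    cods <- tab[[a]]
    g <- gcc[cods]
    w <- q^g * (1 - q)^(3 - g)
    tot <- tot + sum(aas == a) * sum(w * g) / sum(w)
  }
  tot / (3 * nchar(protein))
}

#' Back-translate a protein with GC-biased codon choice
#'
#' Synonymous codons are sampled with weights `q^gc * (1-q)^(3-gc)` where `q`
#' is solved so the expected GC of the coding sequence matches `gc_target`
#' (clamped to the protein's achievable range). A stop codon is appended.
#'
#' @param protein Amino-acid string (no stop).
#' @param gc_target Target GC fraction of the emitted CDS.
#' @return A nucleotide CDS string, length `3 * (nchar(protein) + 1)`.
#' @export
back_translate <- function(protein, gc_target = 0.5) {
  tab <- codon_table()
  gcc <- stats::setNames(codon_gc_count(names(genetic_code())),
                         names(genetic_code()))
  f <- function(q) expected_bt_gc(protein, q, tab, gcc) - gc_target
  q <- if (f(0.02) >= 0) 0.02 else if (f(0.98) <= 0) 0.98 else
    stats::uniroot(f, c(0.02, 0.98), tol = 1e-4)$root
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  cods <- vapply(aas, function(a) {
    cc <- tab[[a]]
    if (length(cc) == 1) return(cc)
    g <- gcc[cc]
    sample(cc, 1, prob = q^g * (1 - q)^(3 - g))
  }, character(1))
  stops <- tab[["*"]]
  g <- gcc[stops]
  stop_c <- sample(stops, 1, prob = q^g * (1 - q)^(3 - g))
  paste0(paste(cods, collapse = ""), stop_c)
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(aas)) < rate)
  hit <- hit[hit > 1]  # keep the start methionine
  for (i in hit) aas[i] <- sample(setdiff(.aa20, aas[i]), 1)
  paste(aas, collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit) b[i] <- sample(setdiff(bases, b[i]), 1)
  paste(b, collapse = "")
}

spacer_dna <- function(gc, min_nt = 24, max_nt = 200) {
  inner <- sample(seq.int(min_nt, max_nt), 1) - 2 * nchar(.insulator)
  paste0(.insulator, if (inner > 0) random_dna(inner, gc) else "",
         .insulator)
}

# --- island construction ---------------------------------------------------

# Build one 38-kb cluster island: background at cluster_gc, genes in template
# order with the alkB start codon at exactly `upstream_nt`, stop-codon
# insulators guaranteeing exact ORF boundaries, IS elements and pseudogenes
# per plan. Returns list(seq, features) with island-local 0-based intervals.
build_island <- function(template, refs, cluster_gc, mutation_rate,
                         is_plan = NULL, is_refs = NULL,
                         pseudo_labels = character(0),
                         upstream_nt = 10000, downstream_nt = 28000) {
  labels <- .templates[[template]]
  if (is.null(labels)) abort_alkscan(paste0("unknown template: ", template),
                                     "ConfigError")
  total <- upstream_nt + downstream_nt
  k <- match("alkB", labels)
  make_cds <- function(lab) {
    prot <- refs$seq[refs$label == lab][1]
    if (lab %in% pseudo_labels)
      prot <- substr(prot, 1, max(30, floor(0.4 * nchar(prot))))
    back_translate(mutate_protein(prot, mutation_rate), cluster_gc)
  }
  feats <- list()
  # downstream block: alkB first, then the rest of the template
  down_parts <- character(0)
  pos <- upstream_nt
  for (lab in labels[k:length(labels)]) {
    cds <- make_cds(lab)
    feats[[length(feats) + 1]] <- data.frame(
      kind = if (lab %in% pseudo_labels) "pseudogene" else "alk_gene",
      label = lab, start = pos, end = pos + nchar(cds), strand = "+",
      complete = NA, stringsAsFactors = FALSE)
    sp <- spacer_dna(cluster_gc)
    down_parts <- c(down_parts, cds, sp)
    pos <- pos + nchar(cds) + nchar(sp)
  }
  # IS elements appended after the gene block
  if (!is.null(is_plan) && nrow(is_plan) > 0) {
    for (i in seq_len(nrow(is_plan))) {
      fam <- is_plan$family[i]
      prot <- is_refs$refs$seq[is_refs$refs$label == fam][1]
      cds <- back_translate(mutate_protein(prot, mutation_rate), cluster_gc)
      if (is_plan$complete[i]) {
        tir <- random_dna(sample(20:28, 1), cluster_gc)
        el <- paste0(tir, .insulator, cds, .insulator, revcomp(tir))
      } else {
        tir <- ""
        el <- cds
      }
      feats[[length(feats) + 1]] <- data.frame(
        kind = "is_element", label = fam, start = pos,
        end = pos + nchar(el), strand = "+",
        complete = is_plan$complete[i], stringsAsFactors = FALSE)
      sp <- spacer_dna(cluster_gc, min_nt = 60, max_nt = 240)
      down_parts <- c(down_parts, el, sp)
      pos <- pos + nchar(el) + nchar(sp)
    }
  }
  down_seq <- paste(down_parts, collapse = "")
  if (upstream_nt + nchar(down_seq) > total)
    abort_alkscan("template content exceeds the fragment window",
                  "ConfigError")
  # upstream block: genes before alkB, laid right-to-left ending at alkB
  up_parts <- character(0)
  pos_up <- upstream_nt
  if (k > 1) {
    for (lab in rev(labels[seq_len(k - 1)])) {
      cds <- make_cds(lab)
      sp <- spacer_dna(cluster_gc)
      pos_up <- pos_up - nchar(sp) - nchar(cds)
      feats[[length(feats) + 1]] <- data.frame(
        kind = if (lab %in% pseudo_labels) "pseudogene" else "alk_gene",
        label = lab, start = pos_up, end = pos_up + nchar(cds),
        strand = "+", complete = NA, stringsAsFactors = FALSE)
      up_parts <- c(paste0(cds, sp), up_parts)
    }
  } else {
    # no upstream genes: still guarantee the alkB ORF starts at upstream_nt
    pos_up <- upstream_nt - nchar(.insulator)
    up_parts <- .insulator
  }
  if (pos_up < 0)
    abort_alkscan("upstream template content exceeds the window",
                  "ConfigError")
  up_seq <- paste(up_parts, collapse = "")
  seq <- paste0(random_dna(pos_up, cluster_gc), up_seq, down_seq,
                random_dna(total - upstream_nt - nchar(down_seq), cluster_gc))
  feats <- do.call(rbind, feats)
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  list(seq = seq, features = feats)
}

# flip island-local features onto the reverse complement of the island
flip_features <- function(feats, island_len) {
  if (nrow(feats) == 0) return(feats)
  new_start <- island_len - feats$end
  feats$end <- island_len - feats$start
  feats$start <- new_start
  feats$strand <- ifelse(feats$strand == "+", "-", "+")
  feats[order(feats$start), , drop = FALSE]
}

build_decoy <- function(class, refs, cluster_gc, mutation_rate) {
  gene <- function(lab) back_translate(
    mutate_protein(refs$seq[refs$label == lab][1], mutation_rate),
    cluster_gc)
  feats <- list()
  parts <- character(0)
  pos <- 0L
  add <- function(lab, cds, kind = "decoy_gene") {
    feats[[length(feats) + 1]] <<- data.frame(
      kind = kind, label = lab, start = pos, end = pos + nchar(cds),
      strand = "+", complete = NA, stringsAsFactors = FALSE)
    sp <- spacer_dna(cluster_gc)
    parts <<- c(parts, cds, sp)
    pos <<- pos + nchar(cds) + nchar(sp)
  }
  if (class == "out_of_window") {
    # alkB with alkH/alkJ nearby but alkG 12 kb away: fails the 10-kb rule
    parts <- c(.insulator); pos <- nchar(.insulator)
    alkB_at <- pos
    add("alkB", gene("alkB"))
    add("alkH", gene("alkH"))
    add("alkJ", gene("alkJ"))
    pad <- alkB_at + 12000 - pos
    parts <- c(parts, random_dna(pad - nchar(.insulator), cluster_gc),
               .insulator)
    pos <- alkB_at + 12000
    add("alkG", gene("alkG"))
  } else if (class == "no_alkB") {
    parts <- c(.insulator); pos <- nchar(.insulator)
    add("alkG", gene("alkG"))
    add("alkH", gene("alkH"))
    add("alkJ", gene("alkJ"))
  } else {
    abort_alkscan(paste0("unknown decoy class: ", class), "ConfigError")
  }
  list(seq = paste(parts, collapse = ""), features = do.call(rbind, feats))
}

# --- survey plan and generation -------------------------------------------

.lineages <- c(
  Pseudomonas = "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas",
  Marinobacter = "Bacteria;Proteobacteria;Gammaproteobacteria;Alteromonadales;Marinobacteraceae;Marinobacter",
  Alcanivorax = "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Alcanivoracaceae;Alcanivorax",
  Thalassolituus = "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Oceanospirillaceae;Thalassolituus",
  Halomonas = "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;Halomonadaceae;Halomonas",
  Sphingobium = "Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Sphingobium")

#' The default 20-genome synthetic survey plan
#'
#' Twenty genomes cycling through the four organization templates, with
#' three multi-copy genomes (one with both copies on a single chromosome
#' 150 kb apart, two with one copy on the chromosome and one on a plasmid),
#' six decoy genomes covering the three rejection classes (marker beyond the
#' 10-kb window, missing alkB, contig-end truncation), pseudogene plantings,
#' a mix of Complete and Contig assembly levels, minus-strand plantings, and
#' an IS plan spanning eleven families with IS-free Alcanivorax and
#' Thalassolituus genomes.
#'
#' @return A data.frame with one row per genome describing what to plant.
#' @export
default_survey_plan <- function() {
  g <- function(id, template, genus, niche, level, placement, copies = 1,
                decoy = "none", is_fams = "", is_complete = "",
                pseudo = "", strand = "+") {
    data.frame(genome_id = id, template = template, genus = genus,
               niche = niche, level = level, placement = placement,
               copies = copies, decoy = decoy, is_fams = is_fams,
               is_complete = is_complete, pseudo = pseudo, strand = strand,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("g01", "pseudomonas_full", "Pseudomonas", "urban water", "Complete",
      "chromosome", copies = 2, is_fams = "IS3,IS5", is_complete = "1,0"),
    g("g02", "marinobacter", "Marinobacter", "oil field", "Complete",
      "chromosome+plasmid", copies = 2, is_fams = "IS3,IS6",
      is_complete = "1,1", pseudo = "alkK", strand = "-"),
    g("g03", "alcanivorax_minimal", "Alcanivorax", "marine", "Complete",
      "chromosome+plasmid", copies = 2),
    g("g04", "pseudomonas_full", "Pseudomonas", "soil", "Complete",
      "chromosome", is_fams = "IS3,IS30", is_complete = "1,0",
      strand = "-"),
    g("g05", "pseudomonas_full", "Pseudomonas", "urban water", "Contig",
      "chromosome", decoy = "out_of_window", is_fams = "IS5",
      is_complete = "1"),
    g("g06", "marinobacter", "Marinobacter", "oil field", "Complete",
      "chromosome", decoy = "out_of_window", is_fams = "IS6",
      is_complete = "1", pseudo = "alkK"),
    g("g07", "sphingomonadales", "Sphingobium", "soil", "Contig",
      "chromosome", decoy = "no_alkB", is_fams = "IS110", is_complete = "0",
      strand = "-"),
    g("g08", "sphingomonadales", "Sphingobium", "soil", "Complete",
      "chromosome", decoy = "no_alkB", is_fams = "IS21", is_complete = "1"),
    g("g09", "marinobacter", "Marinobacter", "marine", "Contig",
      "chromosome", decoy = "contig_end_truncated", is_fams = "IS256",
      is_complete = "1", pseudo = "alkK"),
    g("g10", "pseudomonas_full", "Pseudomonas", "urban water", "Contig",
      "chromosome", decoy = "contig_end_truncated", is_fams = "IS3,IS481",
      is_complete = "0,1", strand = "-"),
    g("g11", "sphingomonadales", "Sphingobium", "soil", "Contig",
      "chromosome", is_fams = "ISL3", is_complete = "0"),
    g("g12", "sphingomonadales", "Sphingobium", "freshwater", "Contig",
      "chromosome", is_fams = "IS630", is_complete = "1", strand = "-"),
    g("g13", "sphingomonadales", "Sphingobium", "soil", "Complete",
      "chromosome", is_fams = "IS5", is_complete = "1"),
    g("g14", "alcanivorax_minimal", "Alcanivorax", "marine", "Contig",
      "chromosome", strand = "-"),
    g("g15", "alcanivorax_minimal", "Alcanivorax", "marine", "Complete",
      "chromosome"),
    g("g16", "alcanivorax_minimal", "Alcanivorax", "marine", "Contig",
      "chromosome"),
    g("g17", "pseudomonas_full", "Pseudomonas", "soil", "Contig",
      "chromosome", is_fams = "IS3,IS5", is_complete = "1,1", strand = "-"),
    g("g18", "marinobacter", "Marinobacter", "oil field", "Contig",
      "chromosome", is_fams = "IS66", is_complete = "0"),
    g("g19", "alcanivorax_minimal", "Thalassolituus", "marine", "Complete",
      "plasmid"),
    g("g20", "marinobacter", "Halomonas", "oil field", "Complete",
      "chromosome", is_fams = "IS6,IS6", is_complete = "1,0"))
}

parse_is_plan <- function(is_fams, is_complete) {
  if (!nzchar(is_fams)) return(NULL)
  fams <- strsplit(is_fams, ",", fixed = TRUE)[[1]]
  comp <- as.integer(strsplit(is_complete, ",", fixed = TRUE)[[1]]) == 1L
  data.frame(family = fams, complete = comp, stringsAsFactors = FALSE)
}

#' Generate a synthetic survey with planted ground truth
#'
#' @param plan Survey plan data.frame (see [default_survey_plan()]).
#' @param seed Integer seed; identical plan + seed give byte-identical
#'   output.
#' @param host_gc,cluster_gc Background GC of the host genome and of the
#'   38-kb cluster island.
#' @param mutation_rate Amino-acid substitution rate applied to the
#'   reference proteins before back-translation.
#' @param chromosome_nt Length of a single-island chromosome; multi-copy and
#'   plasmid replicons are sized internally.
#' @param refs,is_refs Reference sets (default: bundled synthetic exemplars).
#' @return A list with `assemblies` (list of [genome_assembly()]),
#'   `metadata` (per-replicon data.frame) and `truth` (planted-feature
#'   table with genome-absolute 0-based half-open coordinates; cluster rows
#'   carry the exact expected fragment window and `expected_detected`).
#' @export
generate_survey <- function(plan = default_survey_plan(), seed = 1,
                            host_gc = 0.60, cluster_gc = 0.45,
                            mutation_rate = 0.08, chromosome_nt = 100000,
                            refs = load_alk_references(),
                            is_refs = load_transposase_references()) {
  assemblies <- list()
  metadata <- list()
  truth <- list()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    gseed <- (seed * 1009L + i * 101L) %% 2147483647L
    sim <- with_seed(gseed, simulate_assembly(
      row, host_gc = host_gc, cluster_gc = cluster_gc,
      mutation_rate = mutation_rate, chromosome_nt = chromosome_nt,
      refs = refs, is_refs = is_refs))
    assemblies[[row$genome_id]] <- sim$assembly
    metadata[[i]] <- sim$metadata
    truth[[i]] <- sim$truth
  }
  metadata <- classify_replicons(do.call(rbind, metadata))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  # re-resolve assemblies against the pooled metadata (sets replicon classes)
  for (gid in names(assemblies))
    assemblies[[gid]] <- genome_assembly(gid, assemblies[[gid]]$replicons,
                                         metadata)
  list(assemblies = assemblies, metadata = metadata, truth = truth)
}

# island + decoy placement for one genome of the plan
simulate_assembly <- function(row, host_gc, cluster_gc, mutation_rate,
                              chromosome_nt, refs, is_refs) {
  template <- row$template
  is_plan <- parse_is_plan(row$is_fams, row$is_complete)
  pseudo <- if (nzchar(row$pseudo))
    strsplit(row$pseudo, ",", fixed = TRUE)[[1]] else character(0)
  # split the IS plan across copies: all IS on the first copy
  islands <- list()
  for (cp in seq_len(row$copies)) {
    isl <- build_island(template, refs, cluster_gc, mutation_rate,
                        is_plan = if (cp == 1) is_plan else NULL,
                        is_refs = is_refs,
                        pseudo_labels = if (cp == 1) pseudo else character(0))
    strand <- if (cp == 1) row$strand else "+"
    if (strand == "-") {
      isl$features <- flip_features(isl$features, nchar(isl$seq))
      isl$seq <- revcomp(isl$seq)
    }
    isl$strand <- strand
    islands[[cp]] <- isl
  }
  island_len <- nchar(islands[[1]]$seq)

  replicons <- character(0)
  md <- list()
  truth <- list()
  gid <- row$genome_id

  place_island <- function(isl, bg_before, bg_after, rep_id, copy) {
    seq <- paste0(bg_before, isl$seq, bg_after)
    off <- nchar(bg_before)
    f <- isl$features
    f$start <- f$start + off
    f$end <- f$end + off
    f <- cbind(data.frame(genome_id = gid, replicon_id = rep_id,
                          stringsAsFactors = FALSE),
               f, data.frame(template = template, copy = copy,
                             expected_detected = TRUE,
                             stringsAsFactors = FALSE))
    cl <- data.frame(genome_id = gid, replicon_id = rep_id,
                     kind = "cluster", label = template, start = off,
                     end = off + island_len, strand = isl$strand,
                     complete = NA, template = template, copy = copy,
                     expected_detected = TRUE, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <<- rbind(cl, f)
    seq
  }

  if (row$placement == "chromosome" && row$copies == 2) {
    # both copies on one chromosome, separated by exactly 150 kb
    gap <- 150000
    m1 <- 20000; m2 <- 20000
    chrom_id <- paste0(gid, "_chr")
    part1 <- place_island(islands[[1]], random_dna(m1, host_gc), "",
                          chrom_id, 1)
    mid <- random_dna(gap, host_gc)
    # second island starts right after the gap; compute its offset manually
    off2 <- nchar(part1) + gap
    isl2 <- islands[[2]]
    f <- isl2$features
    f$start <- f$start + off2
    f$end <- f$end + off2
    truth[[length(truth) + 1]] <- rbind(
      data.frame(genome_id = gid, replicon_id = chrom_id, kind = "cluster",
                 label = template, start = off2, end = off2 + island_len,
                 strand = isl2$strand, complete = NA, template = template,
                 copy = 2, expected_detected = TRUE,
                 stringsAsFactors = FALSE),
      cbind(data.frame(genome_id = gid, replicon_id = chrom_id,
                       stringsAsFactors = FALSE),
            f, data.frame(template = template, copy = 2,
                          expected_detected = TRUE,
                          stringsAsFactors = FALSE)))
    chrom <- paste0(part1, mid, isl2$seq, random_dna(m2, host_gc))
    replicons[chrom_id] <- chrom
    md[[length(md) + 1]] <- data.frame(
      genome_id = gid, replicon_id = chrom_id, assembly_level = row$level,
      description = "chromosome 1", taxonomy = .lineages[[row$genus]],
      niche = row$niche, stringsAsFactors = FALSE)
  } else {
    # first copy on the chromosome (or the plasmid for plasmid placement)
    host_len <- chromosome_nt - island_len
    p <- 2000L + sample.int(host_len - 4000L, 1)  # keep 2 kb margins
    chrom_id <- paste0(gid, "_chr")
    if (row$placement == "plasmid") {
      # chromosome without cluster + plasmid carrying it
      replicons[chrom_id] <- random_dna(chromosome_nt %/% 2, host_gc)
      md[[length(md) + 1]] <- data.frame(
        genome_id = gid, replicon_id = chrom_id, assembly_level = row$level,
        description = "chromosome 1", taxonomy = .lineages[[row$genus]],
        niche = row$niche, stringsAsFactors = FALSE)
      plas_id <- paste0(gid, "_pAlk1")
      replicons[plas_id] <- place_island(islands[[1]],
                                         random_dna(3000, host_gc),
                                         random_dna(3000, host_gc),
                                         plas_id, 1)
      md[[length(md) + 1]] <- data.frame(
        genome_id = gid, replicon_id = plas_id, assembly_level = row$level,
        description = "plasmid pAlk1", taxonomy = .lineages[[row$genus]],
        niche = row$niche, stringsAsFactors = FALSE)
    } else {
      replicons[chrom_id] <- place_island(
        islands[[1]], random_dna(p, host_gc),
        random_dna(host_len - p, host_gc), chrom_id, 1)
      md[[length(md) + 1]] <- data.frame(
        genome_id = gid, replicon_id = chrom_id, assembly_level = row$level,
        description = "chromosome 1", taxonomy = .lineages[[row$genus]],
        niche = row$niche, stringsAsFactors = FALSE)
    }
    if (row$copies == 2 && row$placement == "chromosome+plasmid") {
      plas_id <- paste0(gid, "_pAlk1")
      replicons[plas_id] <- place_island(islands[[2]],
                                         random_dna(3000, host_gc),
                                         random_dna(3000, host_gc),
                                         plas_id, 2)
      md[[length(md) + 1]] <- data.frame(
        genome_id = gid, replicon_id = plas_id, assembly_level = row$level,
        description = "plasmid pAlk1", taxonomy = .lineages[[row$genus]],
        niche = row$niche, stringsAsFactors = FALSE)
    }
  }

  # decoys live on their own replicon so they cannot borrow markers
  if (row$decoy %in% c("out_of_window", "no_alkB")) {
    d <- build_decoy(row$decoy, refs, cluster_gc, mutation_rate)
    dep_id <- paste0(gid, "_decoy")
    pad <- random_dna(2000, host_gc)
    dseq <- paste0(pad, d$seq, random_dna(2000, host_gc))
    f <- d$features
    f$start <- f$start + nchar(pad)
    f$end <- f$end + nchar(pad)
    truth[[length(truth) + 1]] <- rbind(
      data.frame(genome_id = gid, replicon_id = dep_id, kind = "decoy",
                 label = row$decoy, start = nchar(pad),
                 end = nchar(pad) + nchar(d$seq), strand = "+",
                 complete = NA, template = template, copy = 0,
                 expected_detected = FALSE, stringsAsFactors = FALSE),
      cbind(data.frame(genome_id = gid, replicon_id = dep_id,
                       stringsAsFactors = FALSE),
            f, data.frame(template = template, copy = 0,
                          expected_detected = FALSE,
                          stringsAsFactors = FALSE)))
    replicons[dep_id] <- dseq
    md[[length(md) + 1]] <- data.frame(
      genome_id = gid, replicon_id = dep_id, assembly_level = row$level,
      description = if (row$level %in% c("Complete", "Chromosome"))
        "chromosome 2" else "contig", taxonomy = .lineages[[row$genus]],
      niche = row$niche, stringsAsFactors = FALSE)
  } else if (row$decoy == "contig_end_truncated") {
    # a full island cut so only 5 kb remains upstream of the alkB start:
    # the candidate is found but the window underflows the contig start
    isl <- build_island(template, refs, cluster_gc, mutation_rate)
    cut <- 5000
    dseq <- paste0(substr(isl$seq, 10000 - cut + 1, nchar(isl$seq)),
                   random_dna(2000, host_gc))
    dep_id <- paste0(gid, "_decoy")
    truth[[length(truth) + 1]] <- data.frame(
      genome_id = gid, replicon_id = dep_id, kind = "decoy",
      label = row$decoy, start = 0, end = nchar(dseq), strand = "+",
      complete = NA, template = template, copy = 0,
      expected_detected = FALSE, stringsAsFactors = FALSE)
    replicons[dep_id] <- dseq
    md[[length(md) + 1]] <- data.frame(
      genome_id = gid, replicon_id = dep_id, assembly_level = row$level,
      description = "contig", taxonomy = .lineages[[row$genus]],
      niche = row$niche, stringsAsFactors = FALSE)
  }

  # contig-level assemblies: split the chromosome away from the island
  if (row$level %in% c("Contig", "Scaffold")) {
    chrom_id <- paste0(gid, "_chr")
    chrom <- replicons[[chrom_id]]
    isl_truth <- do.call(rbind, truth)
    isl_rows <- isl_truth[isl_truth$replicon_id == chrom_id, , drop = FALSE]
    isl_start <- min(isl_rows$start)
    isl_end <- max(isl_rows$end)
    b1 <- max(0, isl_start %/% 2)
    b2 <- min(nchar(chrom), isl_end + 2000)
    bounds <- unique(c(0, b1, b2, nchar(chrom)))
    pieces <- substring(chrom, utils::head(bounds, -1) + 1, bounds[-1])
    ids <- paste0(gid, "_ctg", seq_along(pieces))
    replicons <- replicons[names(replicons) != chrom_id]
    for (k in seq_along(pieces)) replicons[ids[k]] <- pieces[k]
    # remap truth coordinates onto the contig holding the island
    offs <- utils::head(bounds, -1)
    for (t in seq_along(truth)) {
      tt <- truth[[t]]
      onchr <- tt$replicon_id == chrom_id
      if (!any(onchr)) next
      piece <- findInterval(tt$start[onchr], offs)
      tt$replicon_id[onchr] <- ids[piece]
      tt$start[onchr] <- tt$start[onchr] - offs[piece]
      tt$end[onchr] <- tt$end[onchr] - offs[piece]
      truth[[t]] <- tt
    }
    md <- md[vapply(md, function(m) m$replicon_id != chrom_id, logical(1))]
    for (k in seq_along(pieces))
      md[[length(md) + 1]] <- data.frame(
        genome_id = gid, replicon_id = ids[k], assembly_level = row$level,
        description = paste("contig", k),
        taxonomy = .lineages[[row$genus]], niche = row$niche,
        stringsAsFactors = FALSE)
  }

  metadata <- do.call(rbind, md)
  assembly <- genome_assembly(gid, replicons, classify_replicons(metadata))
  list(assembly = assembly, metadata = metadata,
       truth = do.call(rbind, truth))
}

# --- alkB family radiation for the phylogeny test --------------------------

#' Simulate divergent alkB families plus one cluster-derived clade
#'
#' One ancestral alkB coding sequence radiates into `n_families` background
#' families and one cluster-derived family; an outgroup (xylM-like, the most
#' divergent sequence) is added. All sequences are equal-length and gap-free,
#' so no aligner is needed.
#'
#' @param seed Integer seed.
#' @param n_families Number of background families.
#' @param tips_per_family Tips per background family.
#' @param n_cluster Tips in the cluster-derived family.
#' @param family_rate Substitution rate on the branch to each family
#'   ancestor.
#' @param tip_rate,cluster_tip_rate Rates on the tip branches.
#' @param outgroup_rate Rate on the outgroup branch (largest divergence).
#' @param refs Alk references supplying the ancestral alkB protein.
#' @return A list with `seqs` (named character vector), `cluster_tips`,
#'   `outgroup` (the label `"xylM_outgroup"`) and `family` (tip -> family).
#' @export
evolve_alkB_families <- function(seed = 1, n_families = 8,
                                 tips_per_family = 5, n_cluster = 10,
                                 family_rate = 0.2, tip_rate = 0.05,
                                 cluster_tip_rate = 0.03,
                                 outgroup_rate = 0.5,
                                 refs = load_alk_references()) {
  with_seed(seed, {
    root <- back_translate(refs$seq[refs$label == "alkB"][1], 0.5)
    seqs <- character(0)
    family <- character(0)
    for (f in seq_len(n_families)) {
      anc <- mutate_dna(root, family_rate)
      for (t in seq_len(tips_per_family)) {
        lab <- sprintf("bg%02d_t%02d", f, t)
        seqs[lab] <- mutate_dna(anc, tip_rate)
        family[lab] <- sprintf("bg%02d", f)
      }
    }
    anc <- mutate_dna(root, family_rate)
    for (t in seq_len(n_cluster)) {
      lab <- sprintf("cluster_t%02d", t)
      seqs[lab] <- mutate_dna(anc, cluster_tip_rate)
      family[lab] <- "cluster"
    }
    seqs["xylM_outgroup"] <- mutate_dna(root, outgroup_rate)
    family["xylM_outgroup"] <- "outgroup"
    list(seqs = seqs,
         cluster_tips = names(family)[family == "cluster"],
         outgroup = "xylM_outgroup", family = family)
  })
}

# --- recovery scoring ------------------------------------------------------

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

#' Score a scan against the generator's truth table
#'
#' Features are matched by genome, replicon and reciprocal interval overlap
#' of at least 0.9.
#'
#' @param scan A [scan_survey()] result.
#' @param truth The truth table from [generate_survey()].
#' @param min_overlap Reciprocal overlap required for a match.
#' @return A list of per-kind scores: `clusters` (precision, recall, counts,
#'   decoy false positives), `is_elements` (recall, family accuracy,
#'   completeness accuracy) and `alk_genes` (recall, pseudogene-flag
#'   accuracy).
#' @export
score_recovery <- function(scan, truth, min_overlap = 0.9) {
  cl <- scan$clusters
  if (length(setdiff(cl$genome_id, truth$genome_id)) > 0)
    abort_alkscan("scan contains genomes absent from the truth table",
                  "ConsistencyError")
  match_rows <- function(a, b) {
    # indices into b matching each row of a (genome+replicon+overlap)
    vapply(seq_len(nrow(a)), function(i) {
      j <- which(b$genome_id == a$genome_id[i] &
                   b$replicon_id == a$replicon_id[i] &
                   reciprocal_overlap(a$start[i], a$end[i], b$start,
                                      b$end) >= min_overlap)
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
  }
  tc <- truth[truth$kind == "cluster" & truth$expected_detected, ,
              drop = FALSE]
  m_scan <- match_rows(cl, tc)
  m_truth <- match_rows(tc, cl)
  decoys <- truth[truth$kind == "decoy", , drop = FALSE]
  decoy_fp <- sum(!is.na(match_rows(decoys, cl)))
  clusters <- list(
    n_truth = nrow(tc), n_detected = nrow(cl),
    precision = if (nrow(cl)) mean(!is.na(m_scan)) else NA_real_,
    recall = if (nrow(tc)) mean(!is.na(m_truth)) else NA_real_,
    decoy_false_positives = decoy_fp)

  # IS elements: scan table carries fragment-local coords + fragment start
  ti <- truth[truth$kind == "is_element", , drop = FALSE]
  it <- scan$is_elements
  if (nrow(it) > 0) {
    frag <- scan$clusters[match(it$fragment_id, scan$clusters$fragment_id), ]
    it$genome_id <- frag$genome_id
    it$replicon_id <- frag$replicon_id
    it$start <- it$start + frag$start
    it$end <- it$end + frag$start
  }
  m_is <- if (nrow(ti)) match_rows(ti, it) else integer(0)
  fam_ok <- !is.na(m_is) & ti$label == it$family[m_is]
  comp_ok <- !is.na(m_is) & ti$complete == it$complete[m_is]
  is_elements <- list(
    n_truth = nrow(ti), n_detected = nrow(it),
    recall = if (nrow(ti)) mean(!is.na(m_is)) else NA_real_,
    family_accuracy = if (any(!is.na(m_is)))
      sum(fam_ok) / sum(!is.na(m_is)) else NA_real_,
    completeness_accuracy = if (any(!is.na(m_is)))
      sum(comp_ok) / sum(!is.na(m_is)) else NA_real_)

  # alk genes (incl. pseudogenes): compare against fragment-local hits
  tg <- truth[truth$kind %in% c("alk_gene", "pseudogene"), , drop = FALSE]
  hits <- scan$gene_hits
  m_g <- if (nrow(tg) && nrow(hits)) match_rows(tg, hits) else
    rep(NA_integer_, nrow(tg))
  pseudo_ok <- !is.na(m_g) &
    (hits$is_pseudogene[m_g] == (tg$kind == "pseudogene"))
  alk_genes <- list(
    n_truth = nrow(tg),
    recall = if (nrow(tg)) mean(!is.na(m_g)) else NA_real_,
    pseudogene_flag_accuracy = if (any(!is.na(m_g)))
      sum(pseudo_ok) / sum(!is.na(m_g)) else NA_real_)

  list(clusters = clusters, is_elements = is_elements,
       alk_genes = alk_genes)
}
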