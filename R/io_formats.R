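# FASTA / GFF3 / metadata readers and writers, and the coordinate convention.
#
# All internal coordinates are 0-based half-open [start, end). GFF3 files and
# human-facing reports use 1-based inclusive coordinates; the conversion is
# start + 1 / end on the way out and the inverse on the way in.

#' Read a FASTA file
#'
#' Sequences are uppercased and whitespace inside records is stripped.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return A data.frame with columns `id` (first word of the header),
#'   `desc` (remainder of the header, possibly empty) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_alkscan(paste0("no such file: ", path), "FormatError")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_alkscan("empty FASTA file", "EmptyInput")
  if (!startsWith(lines[[1]], ">"))
    abort_alkscan("sequence data before first FASTA header", "FormatError")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort_alkscan("empty FASTA file", "EmptyInput")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    abort_alkscan(paste0("duplicate FASTA id: ",
                         ids[duplicated(ids)][1]), "DuplicateId")
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) abort_alkscan("record with empty sequence", "FormatError")
  data.frame(id = ids, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records A data.frame with columns `id`, `seq` and optionally `desc`,
#'   as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$desc) && nzchar(records$desc[i]))
      hdr <- paste(hdr, records$desc[i])
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write gene features as GFF3
#'
#' Internal 0-based half-open intervals are emitted as 1-based inclusive GFF3
#' columns 4-5.
#'
#' @param features A data.frame with columns `replicon_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), and optionally `type`,
#'   `id`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  type <- if (is.null(features$type)) rep("CDS", nrow(features)) else features$type
  gr <- GenomicRanges::GRanges(
    seqnames = features$replicon_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <-
    if (is.null(features$id)) sprintf("feat%05d", seq_len(nrow(features))) else features$id
  if (!is.null(features$label)) S4Vectors::mcols(gr)$label <- features$label
  S4Vectors::mcols(gr)$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 file back into the internal 0-based convention
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `replicon_id`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, `id` and, when present, `label`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- data.frame(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    id = as.character(S4Vectors::mcols(gr)$ID),
    stringsAsFactors = FALSE)
  if (!is.null(S4Vectors::mcols(gr)$label))
    out$label <- as.character(S4Vectors::mcols(gr)$label)
  out
}

.assembly_levels <- c("Complete", "Chromosome", "Contig", "Scaffold")

#' Read the per-replicon metadata sidecar table
#'
#' Expected TSV columns: `genome_id`, `replicon_id`, `assembly_level`,
#' `description`, `taxonomy` (semicolon-delimited lineage), `niche`. One row
#' per replicon.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the columns above plus `replicon_class`, filled
#'   by [classify_replicons()].
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genome_id", "replicon_id", "assembly_level", "description")
  miss <- setdiff(need, names(md))
  if (length(miss))
    abort_alkscan(paste0("metadata missing column(s): ",
                         paste(miss, collapse = ", ")), "FormatError")
  if (is.null(md$taxonomy)) md$taxonomy <- ""
  if (is.null(md$niche)) md$niche <- ""
  bad <- setdiff(unique(md$assembly_level), .assembly_levels)
  if (length(bad))
    abort_alkscan(paste0("unknown assembly_level: ", bad[1]), "FormatError")
  classify_replicons(md)
}

#' Classify replicons as chromosome, plasmid or contig/scaffold
#'
#' Replicons from Complete/Chromosome-level assemblies whose description
#' matches `plasmid_regex` (case-insensitive) are plasmids; other replicons of
#' such assemblies are chromosomes; everything from Contig/Scaffold-level
#' assemblies is `contig_scaffold`.
#'
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param plasmid_regex Regular expression applied to the replicon description.
#' @return `metadata` with a `replicon_class` column.
#' @export
classify_replicons <- function(metadata, plasmid_regex = "plasmid") {
  lv <- metadata$assembly_level
  placed <- lv %in% c("Complete", "Chromosome")
  is_plasmid <- placed & grepl(plasmid_regex, metadata$description,
                               ignore.case = TRUE)
  metadata$replicon_class <- ifelse(is_plasmid, "plasmid",
                                    ifelse(placed, "chromosome",
                                           "contig_scaffold"))
  metadata
}

#' Assemble a genome object from sequences and metadata
#'
#' @param genome_id Genome identifier.
#' @param replicons Named character vector of replicon sequences.
#' @param metadata Optional metadata data.frame restricted to this genome; when
#'   absent every replicon is classed `contig_scaffold`.
#' @return A `genome_assembly` list with fields `genome_id`, `replicons`,
#'   `assembly_level`, `replicon_class`, `taxonomy`, `niche`.
#' @export
genome_assembly <- function(genome_id, replicons, metadata = NULL) {
  stopifnot(!is.null(names(replicons)), all(nzchar(names(replicons))))
  if (is.null(metadata)) {
    level <- "Contig"
    cls <- stats::setNames(rep("contig_scaffold", length(replicons)),
                           names(replicons))
    taxonomy <- ""
    niche <- ""
  } else {
    md <- metadata[metadata$genome_id == genome_id, , drop = FALSE]
    missing_ids <- setdiff(md$replicon_id, names(replicons))
    if (length(missing_ids))
      abort_alkscan(paste0("metadata replicon not in assembly: ",
                           missing_ids[1]), "ConsistencyError")
    level <- md$assembly_level[1]
    cls <- stats::setNames(rep("contig_scaffold", length(replicons)),
                           names(replicons))
    cls[md$replicon_id] <- md$replicon_class
    taxonomy <- md$taxonomy[1]
    niche <- md$niche[1]
  }
  structure(list(genome_id = genome_id, replicons = replicons,
                 assembly_level = level, replicon_class = cls,
                 taxonomy = taxonomy, niche = niche),
            class = "genome_assembly")
}
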