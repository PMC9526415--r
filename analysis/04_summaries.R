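#!/usr/bin/env Rscript
# Step 4 — survey-level tables.
#
# Replicon-location tally, niche x taxonomy cross-tabulation, organization
# types, and the IS-family distribution matrix (IS counts normalized by
# fragment count per genus). Writes TSVs under results/summary/.

library(alkscan)

assemblies <- read_survey_inputs("results/survey")
scan <- scan_survey(assemblies)

dir.create("results/summary", recursive = TRUE, showWarnings = FALSE)

loc <- replicon_location_summary(scan$clusters)
cat("Replicon location of final fragments:\n")
print(loc)
utils::write.table(data.frame(class = names(loc), n = unname(loc)),
                   "results/summary/replicon_location.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

genomes <- scan$clusters[!duplicated(scan$clusters$genome_id),
                         c("genome_id", "taxonomy", "niche")]
nt <- niche_taxonomy_table(genomes, rank = "genus")
cat("\nNiche x genus distribution of cluster-carrying genomes:\n")
print(nt)
utils::write.table(as.data.frame.matrix(nt),
                   "results/summary/niche_taxonomy.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)

types <- unique(scan$clusters[, c("type_id", "organization")])
cat("\nOrganization types:\n")
for (i in order(types$type_id))
  cat(sprintf("  %s  %s\n", types$type_id[i], types$organization[i]))
utils::write.table(scan$clusters[, c("fragment_id", "type_id",
                                     "organization")],
                   "results/summary/organization.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

m <- is_distribution_matrix(scan$clusters, scan$is_elements, rank = "genus")
cat("\nIS elements per fragment, by genus and family:\n")
print(round(m$matrix, 2))
utils::write.table(as.data.frame(round(m$matrix, 4)),
                   "results/summary/is_distribution.tsv", sep = "\t",
                   quote = FALSE, col.names = NA)
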