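#!/usr/bin/env Rscript
# Step 1 — build the synthetic survey.
#
# Generates the default 20-genome study set: four cluster organization
# templates, three multi-copy genomes, decoys for each rejection rule,
# pseudogenes, IS elements from eleven families, and a 45% GC cluster
# island inside 60% GC hosts. Writes the assemblies, the per-replicon
# metadata sidecar and the planted-truth table under results/survey/.

library(alkscan)

seed <- 20220928
survey <- generate_survey(default_survey_plan(), seed = seed)
write_survey_inputs(survey, "results/survey")

cat("Synthetic survey written to results/survey/\n")
cat(sprintf("  genomes:          %d\n", length(survey$assemblies)))
cat(sprintf("  replicons:        %d\n", nrow(survey$metadata)))
cat(sprintf("  planted clusters: %d (in %d genomes)\n",
            sum(survey$truth$kind == "cluster"),
            length(unique(survey$truth$genome_id[
              survey$truth$kind == "cluster"]))))
cat(sprintf("  planted IS:       %d (%d families)\n",
            sum(survey$truth$kind == "is_element"),
            length(unique(survey$truth$label[
              survey$truth$kind == "is_element"]))))
cat(sprintf("  decoy loci:       %d\n", sum(survey$truth$kind == "decoy")))
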