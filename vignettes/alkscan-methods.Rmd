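---
title: "Methods: detecting alkB-anchored alk-gene clusters"
author: "alkscan"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: detecting alkB-anchored alk-gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological question

The *alkB*-type alkane hydroxylase system converts mid-chain n-alkanes into
fatty acids. Its full gene complement — the membrane monooxygenase *alkB*,
the rubredoxins *alkF*/*alkG*, the rubredoxin reductase *alkT*, the
dehydrogenases *alkH* (aldehyde) and *alkJ* (alcohol), the acyl-CoA
synthetase *alkK*, the outer-membrane protein *alkL*, the chemotaxis protein
*alkN*, and the regulator *alkS* — can occur as a compact gene cluster,
first described on the OCT plasmid of *Pseudomonas putida* GPo1. Clustered
*alk* genes travel together: their neighborhood carries insertion-sequence
(IS) elements, their GC content is lower than the host average, and the
*alkB* copies found inside such clusters are phylogenetically much narrower
than *alkB* at large. `alkscan` implements a genome survey for these
clusters: detection by marker co-localization, extraction of a fixed window
around each anchor, re-annotation, IS characterization, organization
typing, replicon localization, GC contrast, and a monophyly test for
cluster-derived *alkB*.

## The two-step cluster caller

**Step 1 — co-localization.** ORFs are predicted on both strands of every
replicon (bacterial code; starts ATG/GTG/TTG, stops TAA/TAG/TGA; the
longest ORF per stop-anchored frame; default minimum 90 nt) and screened
against the ten reference proteins by Smith–Waterman local alignment with
affine gaps (BLOSUM62, gap open 11 / extend 1). Significance uses the
Karlin–Altschul form `E = K·m·n·exp(−λS)` with the classic gapped constants
λ = 0.267, K = 0.041 and the operating threshold `E ≤ 1e-10`. The effective
search-space (length-adjustment) correction is deliberately omitted: at
this threshold true cluster homologs score orders of magnitude below the
cutoff and random ORFs orders of magnitude above it, so the correction
cannot change a decision. An exact-word seed (default 5 residues) skips
alignments that cannot plausibly reach the threshold, mirroring how seeded
protein search works in practice; setting `word_size = 0` disables it.

A candidate locus is an *alkB* hit for which each of *alkG*, *alkH*, *alkJ*
has at least one hit on the same replicon within 10 kb. Distance is
measured between interval boundaries (0 for overlapping genes) — the most
permissive natural reading, and symmetric in strand.

**Step 2 — window extraction and re-annotation.** Around the *alkB* start
codon a window from 10 kb upstream to 28 kb downstream *in gene
orientation* is extracted (a `--no-strand-aware` style flag,
`cluster_config(strand_aware = FALSE)`, reproduces the naive genomic-left
reading). Windows clipped by a replicon end are excluded as truncated but
logged, so contig-end cases are visible in `excluded.tsv`. Each surviving
fragment is re-annotated in isolation: ORFs are re-called on the fragment
sequence alone and screened against all ten labels. Two automated rules
replace the original study's manual review: the anchor must retain its
*alkB* label after re-screening, and at least three distinct alk labels
must survive. Hits whose aligned subject fraction falls below 0.6 are
flagged as pseudogenes; 0.6 is our quantification of "nested white bar"
pseudogene marks and is configurable.

Every qualifying *alkB* seeds its own fragment; identical windows are
deduplicated, and two anchors closer than 38 kb yield two overlapping
fragments (fragments are counted per anchor, as in multi-copy genomes).

## IS elements

Transposase ORFs inside fragments are screened against bundled exemplar
proteins for eleven common IS families (IS3, IS5, IS6, IS21, IS30, IS66,
IS110, IS256, IS481, IS630, ISL3) at the same E-value threshold. The
bundled exemplars are synthetic stand-ins (see *Bundled references*); the
family list is a reasonable default, not a claim about any particular
survey. Each transposase hit is extended by a terminal-inverted-repeat
(TIR) search; an element is complete when a qualifying TIR pair flanks the
transposase.

The TIR finder is exhaustive within its windows and its parameters were
fixed from the binomial arithmetic of chance inverted repeats, not from
data: a pair of random positions qualifies as a 10-nt repeat with two
mismatches with probability ≈ 4×10⁻⁴, so any permissive short-repeat rule
fires constantly in random DNA. The defaults therefore require at least
15 nt, grade the mismatch budget by length (exact below 20 nt, one mismatch
for 20–25 nt, two from 26 nt), and confine the search to 400-nt windows
immediately flanking the transposase, where real IS boundaries sit. Under
these defaults the chance-hit expectation per fragment is far below one.
One consequence worth knowing: a planted exact repeat can be *extended*
outward by chance-matching flanking bases within the mismatch budget, so
detected element boundaries may exceed planted ones by a few nucleotides.

## Organization typing

Fragments are aligned on the *alkB* start codon: a fragment whose anchor
lies on the minus strand is flipped, so organization strings are
strand-normalized (`encode(fragment) == encode(revcomp(fragment))`).
Organization similarity is one minus the Levenshtein distance between label
sequences divided by the longer length — the organization concept in the
source material is qualitative, so a concrete metric had to be chosen;
normalized edit distance respects gene order, which set-based similarity
(Jaccard) would ignore. Types are single-linkage clusters at similarity
≥ 0.8; the threshold separates the four canonical templates (below) while
merging same-template fragments, whose label sequences are identical.

## Phylogenetics

The mono-clade question only needs distances: cluster-derived *alkB*
sequences are compared by p-distance (pairwise deletion of gap/ambiguity
columns), a neighbor-joining tree is built, rooted on a xylM-like outgroup
(or at the midpoint of the longest path), and the cluster tip set is tested
for monophyly (exact descendant-set equality; complements are not assumed
to be clades). NJ recovers topology and branch lengths exactly on additive
matrices, which the tests verify against simulated reference trees, and is
dependency-light; maximum likelihood with bootstrap would not change a
yes/no monophyly answer on data this strongly structured. Multiple
alignment is out of scope: inputs are pre-aligned or, for the generator,
substitution-only and therefore gap-free.

## The synthetic survey generator

The generator is first-class, tested code: it emulates the survey inputs
with planted ground truth so every pipeline claim can be scored exactly.

* **Templates.** Four organization templates:
  `pseudomonas_full` (*alkB F G H J K L* + *S T* + *N*, the full GPo1-style
  complement), `marinobacter` (*alkS T* + *alkB G H J K L*),
  `sphingomonadales` (additionally lacking *alkK* and *alkT*), and
  `alcanivorax_minimal` (*alkS* + *alkB G J H*).
* **Islands.** Each cluster lives on a 38-kb island whose background is
  drawn at `cluster_gc` (default 0.45) inside a host drawn at `host_gc`
  (default 0.60), implementing the low-GC signature. Genes are amino-acid
  mutated copies (default rate 0.08) of the bundled references,
  back-translated with GC-biased codon choice: synonymous codons are
  weighted `q^gc (1−q)^(3−gc)` with `q` solved by root-finding so the
  expected CDS GC hits the target. Spacers are 24–200 nt and are capped by
  a 12-nt insulator (`TAGATAGATAGA`) carrying stop codons in all three
  forward frames, no start codons, and — deliberately — not equal to its
  own reverse complement, so insulators can never masquerade as inverted
  repeats. The insulators pin ORF boundaries to the planted coordinates
  exactly.
* **Default survey.** Twenty genomes (five per template), chromosome
  ~100 kb (a deliberately reduced genome so the survey stays desk-scale;
  the GC-contrast analysis uses a 1-Mb host, see below), three multi-copy
  genomes — one with both copies on a single chromosome exactly 150 kb
  apart, two with one chromosomal and one plasmid copy — plasmid-only
  placement in one genome, a mix of Complete and Contig assembly levels,
  minus-strand plantings, alkK pseudogenes (truncated to 40% of the
  reference), an IS plan covering all eleven families with IS-free
  *Alcanivorax* and *Thalassolituus* genomes, and six decoy genomes, two
  per rejection class: a marker 12 kb from *alkB* (violating the 10-kb
  rule), a *alkGHJ* locus with no *alkB*, and a full cluster cut so only
  5 kb remains upstream of *alkB* on its contig (forcing truncation).
* **GC contrast arithmetic.** The fragment-minus-genome GC delta equals
  `(1 − f)·(cluster_gc − host_gc)·100` points, where `f` is the island's
  fraction of the genome. A −15-point signal from a −15-point planting
  therefore requires the island to be a small fraction of the genome; the
  GC analysis plants the island in a 1-Mb host (f ≈ 3.8%, expected delta
  ≈ −14.4).
* **alkB radiation.** `evolve_alkB_families` radiates one ancestral *alkB*
  CDS into eight background families (0.2 substitutions/site to each
  family ancestor, 0.05 to each tip) plus one cluster-derived family
  (tighter tips, 0.03) and a xylM-like outgroup (0.5, the most divergent
  sequence). All sequences are substitution-only, hence equal length.
* **Reproducibility.** Per-genome seeds are derived arithmetically from the
  survey seed; identical plan + seed give byte-identical FASTA and truth
  tables.

What the generator does *not* emulate: real codon usage, rearrangements,
horizontal-transfer mosaicism, assembly gaps, sequencing error, or genuine
phylogenetic heterogeneity among references. Passing the recovery tests
therefore shows the *pipeline logic* is sound (windows, thresholds,
coordinate arithmetic, strand handling, exclusion rules) — not that the
bundled synthetic references would detect real alk operons; for real
surveys, supply curated reference FASTAs.

## Bundled references

The original reference proteins are not reprinted in any bundled resource
and cannot be fetched at build time, so the package ships deterministic
*synthetic exemplar* proteins (`inst/extdata/*_synthetic.faa`, labelled
synthetic in filename and headers) with realistic lengths (e.g. AlkB
401 aa, AlkS 640 aa; transposases 235–420 aa). Both the generator and the
scanner use the same reference set by default, which is exactly what makes
planted-truth recovery a meaningful closed-loop test. Both accept
user-supplied FASTAs (`load_alk_references(path)`,
`load_transposase_references(path, family_table)`).

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GFF3 and reports
  are 1-based inclusive. Round-trips are identities.
* Best-hit tie-breaking: bit score, then E-value, then reference order.
  Smith–Waterman traceback ties break toward the smallest (row, column).
* TIR ties: longest, then fewest mismatches, then leftmost.
* Organization-type ids are assigned in order of first membership, making
  outputs deterministic and input-order invariant.
* `p_distance` raises `ValueError` when a pair has no comparable sites;
  `nj_tree` requires ≥ 3 taxa; `midpoint_root` rejects all-zero branch
  lengths; outgroups must form a split and be a proper subset of tips.
* A zero mutation rate in the radiation generator yields identical
  sequences; monophyly is undefined there and the tests treat it as the
  degenerate case it is.
* Problem sizes in the tests (20-genome survey, 100-kb chromosomes, 100 NJ
  matrices ≤ 12 leaves, 100 radiation replicates, 200 alignment-oracle
  pairs, 50 TIR-oracle sequences ≤ 5 kb) were chosen so the whole suite
  runs on a laptop in a few minutes while still exercising every rule.

## Known limitations

* Clusters anchored on genes other than *alkB* are out of scope, as are
  operon/promoter prediction and assembly-gap resolution.
* The E-value model is the plain Karlin–Altschul form with raw `m·n`;
  near-threshold decisions (which do not occur at 1e-10 with real
  homologs) would need the length adjustment.
* IS detection is fragment-restricted and exemplar-based; it does not
  reproduce a profile-HMM IS annotator, and family calls are only as good
  as the supplied exemplars.
* The organization-type metric and its 0.8 threshold are a surrogate for a
  concept the source material leaves qualitative; both are configurable.
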