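# One-off generator for the bundled synthetic reference proteins.
# Run from the package root; committed fixtures under inst/extdata were
# produced by exactly this script.
# (committed as text under inst/extdata). Fixed seed; rerunning reproduces
# the identical files.
set.seed(20220928)

aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
        "T","V","W","Y")
# approximate average amino-acid frequencies of bacterial proteomes
freq <- c(A=8.8,C=1.2,D=5.9,E=6.3,F=4.0,G=7.8,H=2.1,I=6.0,K=4.6,L=10.0,
          M=2.4,N=3.9,P=4.6,Q=3.5,R=5.6,S=6.0,T=5.4,V=7.1,W=1.2,Y=3.0)
rand_prot <- function(n) paste0("M", paste(sample(aa, n - 1, TRUE, freq),
                                           collapse = ""))

alk_len <- c(alkB=401, alkF=120, alkG=170, alkH=486, alkJ=558, alkK=548,
             alkL=230, alkN=430, alkS=640, alkT=342)
lines <- character(0)
for (lab in names(alk_len)) {
  p <- rand_prot(alk_len[[lab]])
  lines <- c(lines, paste0(">", lab, "|synthetic_exemplar"),
             substring(p, seq(1, nchar(p), 70),
                       pmin(seq(1, nchar(p), 70) + 69, nchar(p))))
}
writeLines(lines, "inst/extdata/alk_references_synthetic.faa")

fams <- c("IS3","IS5","IS6","IS21","IS30","IS66","IS110","IS256","IS481",
          "IS630","ISL3")
tnp_len <- c(IS3=330, IS5=320, IS6=235, IS21=400, IS30=300, IS66=420,
             IS110=380, IS256=390, IS481=290, IS630=345, ISL3=400)
lines <- character(0)
for (f in fams) {
  p <- rand_prot(tnp_len[[f]])
  lines <- c(lines, paste0(">", f, "|synthetic_exemplar"),
             substring(p, seq(1, nchar(p), 70),
                       pmin(seq(1, nchar(p), 70) + 69, nchar(p))))
}
writeLines(lines, "inst/extdata/transposase_references_synthetic.faa")

fam_tab <- data.frame(family = fams,
                      tir_min = 15, tir_max = 45,
                      element_min = 700,
                      element_max = 3500)
write.table(fam_tab, "inst/extdata/is_families_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("written\n")
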