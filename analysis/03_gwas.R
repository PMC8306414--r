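#!/usr/bin/env Rscript
# Stage 3 — genome-wide association scans.
#
# Two parallel formulations over the QC'd cohort, both additively coded and
# adjusted for sex, age and ten PCs: (1) binomial logistic models of the
# four dichotomized phenotypes (O-vs-nonO, A-vs-nonA, B-vs-nonB,
# AB-vs-nonAB); (2) one multinomial log-linear model per SNP with type O as
# the reference level (contrasts A-vs-O, B-vs-O, AB-vs-O).

library(abokit)
library(data.table)

dat <- "results/data"; qc <- "results/qc"
out <- "results/gwas"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

geno <- read_genotypes(file.path(dat, "genotypes.vcf"), "vcf")
keep <- fread(file.path(qc, "retained_samples.tsv"))$sample_id
pheno <- read_phenotypes(file.path(dat, "phenotypes.tsv"),
                         geno_sample_ids = keep)
geno <- subset_geno(geno, samples = keep)
pcs <- as.matrix(fread(file.path(qc, "pc_scores.tsv"))[, -1])

scan_bin <- run_scan(geno, pheno$samples, "binomial", pcs = pcs)
scan_multi <- run_scan(geno, pheno$samples, "multinomial", pcs = pcs)
fwrite(scan_bin, file.path(out, "gwas_binomial.tsv"), sep = "\t")
fwrite(scan_multi, file.path(out, "gwas_multinomial.tsv"), sep = "\t")

hits_bin <- screen_hits(scan_bin)
hits_multi <- screen_hits(scan_multi)
fwrite(hits_bin, file.path(out, "hits_binomial.tsv"), sep = "\t")
fwrite(hits_multi, file.path(out, "hits_multinomial.tsv"), sep = "\t")

for (tab in list(c("binomial", "hits_bin"), c("multinomial", "hits_multi"))) {
  h <- get(tab[2])
  cat(sprintf("%s: %d genome-wide hits (p < 5e-8) at %d SNPs, all on chr %s\n",
              tab[1], nrow(h), length(unique(h$snp_id)),
              paste(unique(h$chrom), collapse = ",")))
}
cat("top binomial hits:\n")
print(head(hits_bin[, c("snp_id", "contrast", "beta", "OR", "p", "neg_log10_p")]))
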