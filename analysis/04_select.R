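#!/usr/bin/env Rscript
# Stage 4 — LD-aware instrument selection.
#
# Iterative selection over the p-ordered binomial hits (accept a SNP only
# if r2 < 0.8 against everything already selected), then common-tag
# replacement: when two selected SNPs are themselves in high LD, a single
# candidate in high LD with both — and independent of the rest — replaces
# the pair. On the simulated architecture this collapses the redundant
# O-indicator tags onto one SNP, leaving one tag per functional allele.

library(abokit)
library(data.table)

dat <- "results/data"; qc <- "results/qc"; gw <- "results/gwas"
out <- "results/select"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

geno <- read_genotypes(file.path(dat, "genotypes.vcf"), "vcf")
keep <- fread(file.path(qc, "retained_samples.tsv"))$sample_id
geno <- subset_geno(geno, samples = keep)
scan_bin <- as.data.frame(fread(file.path(gw, "gwas_binomial.tsv")))
scan_bin$chrom <- as.character(scan_bin$chrom)

sel <- select_instruments(scan_bin, geno)
writeLines(sel$selected, file.path(out, "selected_snps.txt"))
ld_df <- as.data.frame(as.table(unclass(sel$ld)))
names(ld_df) <- c("snp_a", "snp_b", "r2")
fwrite(ld_df[as.character(ld_df$snp_a) < as.character(ld_df$snp_b), ],
       file.path(out, "ld_table.tsv"), sep = "\t")
fwrite(sel$replacements, file.path(out, "tag_replacements.tsv"), sep = "\t")

cat(sprintf("selected %d independent SNPs: %s\n", length(sel$selected),
            paste(sel$selected, collapse = ", ")))
if (nrow(sel$replacements)) {
  with(sel$replacements, cat(sprintf(
    "common-tag replacement: {%s, %s} -> %s\n", snp_x, snp_y, replacement)))
}
sub_ld <- sel$ld[sel$selected, sel$selected]
cat(sprintf("max pairwise r2 within the selected set: %.3f\n",
            max(sub_ld[upper.tri(sub_ld)])))
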