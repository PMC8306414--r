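#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a cohort with the structure of the serological/genotyping study
# the pipeline emulates: ~1000 recruited individuals, ABO functional
# diplotypes with three perfect tag SNPs plus two redundant high-LD tags of
# the O indicator at the ABO locus on chromosome 9, a 2000-SNP null
# autosomal background, sex/age covariates, blood pressures, and planted QC
# contaminants (40 duplicate pairs, 39 sibling pairs, one low-call-rate
# sample) so that downstream QC has real work to do.

library(abokit)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(rng_seed = 20210624)
cohort <- simulate_cohort(cfg)

write_vcf(cohort$genotypes, file.path(out, "genotypes.vcf"))
write_phenotypes(cohort$samples, file.path(out, "phenotypes.tsv"))
write_truth_tables(cohort, out)
write_sim_config(cfg, file.path(out, "sim_config.txt"))

cat(sprintf("cohort: %d samples, %d SNPs (%d at the ABO locus)\n",
            nrow(cohort$samples), ncol(cohort$genotypes$dosage),
            sum(cohort$genotypes$snp_info$chrom == "9")))
cat("serotype distribution:\n")
print(table(cohort$samples$serotype))
cat(sprintf("planted relatives: %d pairs; see %s/truth_relatives.tsv\n",
            nrow(cohort$truth$relatives), out))
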