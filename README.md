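# abokit

Genomic determination of ABO blood types: GWAS, genotype-based
classification, and Mendelian randomization — with a fully generative
cohort simulator so every stage is testable without any data download.

## The problem

The ABO blood system is a single-gene Mendelian phenotype: the A and B
alleles of the ABO gene (chromosome 9q34) build the A and B antigens, the
O allele is inactivated by a single-base deletion, O is recessive and A/B
are codominant. Large biobanks rarely serotype their participants and
instead infer blood type from SNP-array genotypes — usually without
quantifying the inference error. `abokit` is for statistical geneticists
who want to build and evaluate that inference chain end to end on a
cohort carrying both serological types and genotypes:

1. **simulate** a cohort: ABO functional diplotypes, tag SNPs at a target
   haplotype r², serological typing error, a null autosomal background,
   covariates, blood-pressure traits, and planted QC contaminants
   (duplicates, siblings, low-call-rate samples);
2. **QC**: call-rate filtering, method-of-moments IBD relatedness
   pruning (pi-hat), top-10 PCs for structure adjustment;
3. **GWAS**, two parallel formulations per SNP with additive
   minor-allele coding: binomial logistic models of the four dichotomized
   phenotypes (O vs non-O, ...), and one multinomial log-linear model
   `log P(k)/P(O) = α_k + β_k·dosage + γ_kᵀcovariates`, k ∈ {A, B, AB};
   hits screened at p < 5×10⁻⁸;
4. **LD-aware selection**: greedy acceptance in p-order at r² < 0.8,
   plus common-tag replacement of redundant high-LD pairs;
5. **classification**: ridge-penalised multinomial model of serotype on
   the selected dosages; prevalence-threshold binary metrics, ROC/AUC,
   confusion matrix, accuracy, micro/macro F1;
6. **Mendelian randomization** with the selected SNPs as instruments:
   per-instrument Wald ratios combined by fixed-effect IVW
   (θ̂ = Σwⱼθ̂ⱼ/Σwⱼ, wⱼ = seⱼ⁻²) and by the weighted median, one-sample
   (within-cohort) and two-sample (summary statistics, with effect-allele
   harmonization).

## Worked example

The numbered scripts under `analysis/` run the whole workflow
(`Rscript analysis/01_simulate.R` ... `06_mr.R`), writing tables under
`results/`. In code, the same path is:

```r
library(abokit)

cohort <- simulate_cohort(sim_config(rng_seed = 20210624))
qc     <- qc_cohort(cohort)                      # call rate + IBD pruning
pcs    <- compute_pcs(qc$geno, k = 10)
scan   <- run_scan(qc$geno, qc$samples, "binomial", pcs = pcs$scores)
sel    <- select_instruments(scan, qc$geno)      # screen + LD-aware pick
ev     <- evaluate_snp_set(qc$geno, qc$samples, sel$selected)
mr     <- one_sample_mr(qc$geno, qc$samples, "B-vs-nonB", "sbp",
                        sel$selected)
```

On the default simulated cohort (1008 samples; 40 duplicate and 39
sibling pairs planted; 5 ABO-locus tag SNPs + 2000 null SNPs) the
drivers print:

```
input 1008 samples: 1 dropped for call rate, 82 dropped for relatedness, 925 retained
binomial: 20 genome-wide hits (p < 5e-8) at 5 SNPs, all on chr 9
selected 3 independent SNPs: tagO, tagB, tagA
max pairwise r2 within the selected set: 0.387
full set {tagO+tagB+tagA}: accuracy 1.0000, F1 micro 1.0000, F1 macro 1.0000
misassigned individuals: 0 of 925; O<->AB confusions: 0
sequential boost over nested subsets:
          snp_set  accuracy  f1_micro  f1_macro
1:           tagO 0.6709817 0.6709817 0.7814646
2:      tagO+tagB 1.0000000 1.0000000 1.0000000
3: tagO+tagB+tagA 1.0000000 1.0000000 1.0000000
```

Reading this: QC caught every planted contaminant; every genome-wide hit
maps to the simulated ABO locus and none to the null background; the
LD step collapses five locus SNPs onto one tag per functional allele
(mutual r² ≤ 0.39); a single O-tag classifies only 67% of samples
(it cannot tell A from B), adding a B-tag makes the three remaining
classes separable, and the full three-SNP set types every individual
correctly with no O↔AB confusion. One-sample MR of blood type on blood
pressure returns estimates tightly bracketing zero (e.g. IVW 0.002,
p = 0.88 for O-vs-nonO on SBP), as it should: the generative model
plants no causal effect.

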