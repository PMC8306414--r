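---
title: "Genomic determination of ABO blood types: models, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic determination of ABO blood types: models, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The ABO blood system is a classical Mendelian phenotype: a single gene on
chromosome 9q34 encodes a glycosyltransferase whose A and B alleles build
the A and B antigens, while the O allele is inactivated by a single-base
frameshift deletion and builds neither. Serologically there are four
mutually exclusive types — O, A, B, AB — with O recessive and A/B
codominant. Because the phenotype is fully genetic, it should be
predictable from genotypes; in practice large biobanks type almost nobody
serologically and instead *infer* blood type from SNP arrays, usually
without any estimate of the inference error. `abokit` implements the full
analysis chain needed to quantify that error on a cohort that has both
serological types and genotypes: cohort simulation, quality control,
association scanning, linkage-disequilibrium (LD) aware variant selection,
multi-class prediction with a complete evaluation battery, and Mendelian
randomization (MR) using the selected variants as instruments.

No individual-level genotypes from the motivating study design are
publicly available, so the package ships a generative model of the cohort
instead. Every analysis stage is exercised, and its statistical behaviour
verified, against cohorts drawn from that model.

# The generative model

## Functional alleles and serotypes

A haplotype carries one of three functional classes, O, A or B, drawn
i.i.d. with frequencies $(f_O, f_A, f_B)$. Two haplotypes pair into an
individual; the serotype follows the dominance rules
(OO→O; AO/AA→A; BO/BB→B; AB→AB). An optional typing-error rate
$\varepsilon$ replaces each recorded type with a uniform draw from the
other three types, a deliberately structureless error model: serological
mistyping has no published error structure to emulate.

The default frequencies $(0.55, 0.22, 0.23)$ give a type distribution
(roughly 30% O, 29% A, 31% B, 10% AB) qualitatively similar to East-Asian
cohorts. They are configuration values, not estimates of any published
cohort, and live in `sim_config()`, never in the logic. The restriction to
three alleles is intentional: the >100 curated ABO alleles (A1/A2 subtypes
and the rest) matter for serology but not for the phenotype logic this
package studies.

## Tag SNPs at a target LD

A tag SNP is attached to a functional indicator (say, the O allele) at a
target haplotype-level $r^2$ by the D-parameterization: with anchor
frequency $p$, tag-allele frequency $q$ and
$D = \sqrt{r^2\,p(1-p)q(1-q)}$, the tag bit is drawn with
$P(\text{tag}=1\mid\text{anchor}=1) = q + D/p$ and
$P(\text{tag}=1\mid\text{anchor}=0) = q - D/(1-p)$. The target $r^2$ is
therefore exact in expectation — this is the population-genetic definition
of $r^2$, not an ad-hoc genotype shuffle. Feasibility is checked against
$r^2_{\max} = D_{\max}^2 / (p(1-p)q(1-q))$ and violations name
$D_{\max}$ in the error.

One subtlety: a target $r^2 = 1$ requires $q$ to equal the *empirical*
anchor frequency, which drifts from any pre-specified $q$ by sampling
noise. `tag_snp_spec()` therefore treats `tag_allele_freq = NULL` as
"match the anchor frequency", the realistic case for array SNPs tagging
the same underlying variant, and the default tag panel uses it. The
default panel carries three perfect tags (one per functional class) plus
two redundant O tags at $r^2$ 0.95 and 0.98, reproducing the situation
where several array SNPs tag the same inactivating deletion and must
later be collapsed onto a common tag.

## Covariates, traits and contaminants

Sex is Bernoulli(0.5), age Uniform(30, 70) years — arbitrary but
config-exposed, and deliberately independent of serotype so that the
covariate-robustness property (hit identity unchanged with or without
sex/age adjustment) holds by construction. Systolic and diastolic blood
pressures are Gaussian with additive age and sex terms
($\text{SBP} = 110 + 0.25\,\text{age} + 4\,\text{male} + e$,
$e \sim N(0, 12^2)$ mmHg, and analogously for DBP) plus an optional
configured shift for one blood-type contrast; a binary outcome follows a
logistic model with a configured log-odds ratio. With no causal effect
configured, traits are null with respect to blood type — the MR
calibration surface.

QC contaminants are planted with recorded ground truth: duplicate pairs
copy both haplotypes and the whole null-genome row; sibling pairs are
rebuilt as two children of two freshly drawn parents (one parental
haplotype from each at the ABO locus, per-SNP Mendelian transmission in
the null genome); one sample gets an extra 10% block of missing calls; a
0.2% background missingness covers everything. The defaults (40 duplicate
+ 39 sibling pairs in 1008 samples) make the QC stage remove 80 samples,
emulating a cohort in which roughly nine in ten recruits survive
preprocessing.

The null genome — 2000 SNPs binomial(2, MAF) with MAF uniform on
[0.05, 0.5], independent of everything — stands in for the autosomal
array background at reduced scale. What the simulator does *not* emulate:
population stratification (a single panmictic population), genotyping
intensity/cluster artefacts, Rh and other blood-group systems, phased
haplotype structure beyond the ABO block, and sequencing reads. Passing
tests therefore certify the statistical machinery under a clean Mendelian
architecture, not robustness to structure or assay artefacts in real
arrays.

# Quality control

Samples below 95% call rate are dropped first, then SNPs below 95% call
rate; relatedness is estimated by the method-of-moments IBS→IBD estimator
(per pair, observed identity-by-state counts combined with their
frequency-based expectations give $P(\text{IBD}=0,1,2)$, and
$\hat\pi = P(2) + P(1)/2$). Only the final $\hat\pi$ is clamped to
[0, 1]: clamping the per-state probabilities would rectify sampling noise
into an upward bias of a few percent, enough to matter at the 0.1875
threshold. That threshold — midway between the second- and third-degree
relative expectations — and the greedy pruning rule (repeatedly drop the
member of the worst pair with the greater missingness, ties to the
lexicographically larger id) are package choices, documented because no
canonical values exist; the greedy rule is standard practice and
deterministic, though not a minimum vertex cover.

PCA LD-prunes first (window-free greedy over MAF-ordered SNPs at
$r^2 < 0.2$), mean-imputes missing dosages, column-standardises and
eigendecomposes. Mean imputation is confined to PCA; association fits are
complete-case per SNP. Components get a deterministic sign (largest
loading positive) so runs are byte-reproducible.

# Association models

Genotypes are coded additively as minor-allele copies, with the major
allele as reference; an exact 50/50 tie takes the lexicographically
smaller allele string as effect allele. Two formulations run in parallel:

* **Binomial**: logistic regression of each dichotomized phenotype
  (O-vs-nonO, A-vs-nonA, B-vs-nonB, AB-vs-nonAB) on dosage, sex, age and
  ten PCs.
* **Multinomial**: one joint log-linear model per SNP,
  $\log P(k)/P(O) = \alpha_k + \beta_k d + \gamma_k^\top z$ for
  $k \in \{A, B, AB\}$, fitted by Newton with step-halving — a single
  model, not three separate logistics, so the contrasts share one
  likelihood.

P-values are Wald, matching standard GWAS output. Separation — a
near-certainty for good ABO tags, where e.g. every dosage-0 carrier is
type O — is detected from diverging coefficients or exploding standard
errors, and triggers a refit with a fixed ridge of $10^{-6}$ on
non-intercept coefficients plus `converged = FALSE`. Because the Wald
statistic degenerates under separation (the SE diverges with the
estimate, so the most significant SNPs in the genome would report
p ≈ 0.8), separated fits report the 1-df likelihood-ratio p instead:
against the dosage-free model in the binomial case, against the model
with that contrast's dosage coefficient pinned to zero in the
multinomial case. Converged fits keep plain Wald. Screening keeps
$p < 5\times10^{-8}$ (the Bonferroni-style genome-wide convention,
$-\log_{10} p \approx 7.3$), sorted by p with ties broken by larger
|effect| then genomic position.

# LD-aware selection

LD is the squared Pearson correlation of dosage vectors (composite LD):
the inputs are unphased, and under Hardy–Weinberg equilibrium the dosage
$r^2$ estimates the haplotype $r^2$; users comparing against phased EM
estimates should expect small discrepancies. Selection is greedy in
p-order: accept a hit iff $r^2 < 0.8$ against everything already
selected. A post-pass collapses redundant pairs: if two selected SNPs
have $r^2 \ge 0.9$ with each other, a candidate in LD $\ge 0.9$ with both
and $< 0.8$ with every other selected SNP replaces the pair (best
candidate by larger min-$r^2$, then smaller p, then id). The 0.9/0.8
thresholds are package defaults — the worked situation this models
involves values of 0.95 and higher, but no canonical cutoffs exist.
"Strong odds ratio" in the selection rule is operationalised as pure
p-ordering, with effect size entering only via tie-breaks, since no OR
cutoff is canonical either. On the default simulation the pipeline
returns exactly three SNPs, one per functional allele.

# The classifier and its evaluation

The predictive model is the same multinomial log-linear form on the
selected dosages, with a mandatory ridge (default $10^{-4}$): noiseless
tagging makes the four classes perfectly separable, so the unpenalised
MLE does not exist; the ridge bounds the coefficients near ±10 while the
fitted probabilities stay saturated within $10^{-4}$ of 0/1, leaving
argmax assignments untouched. Prediction is a softmax with O as reference
(its linear predictor is identically zero), rows summing to 1 within
$10^{-9}$. Missing dosages are an error at prediction time, never
silently imputed; genotype combinations absent from training are still
scored, as extrapolation.

Two evaluation framings coexist deliberately. The per-type *binary*
battery thresholds the type probability at the baseline type prevalence
(≥ counts as positive) and reports accuracy, sensitivity, specificity,
PPV, NPV, F1 and AUC; zero-denominator ratios are reported missing, not
zero. AUC is the midrank Mann–Whitney statistic (all-tied scores give
exactly 0.5). The *multi-class* report assigns by argmax (probability
ties to the more prevalent type) and reports accuracy, the confusion
matrix, micro F1 over pooled one-vs-rest tables and macro F1 as the
unweighted mean of defined per-type F1 values. Under single-label argmax
assignment micro F1 equals accuracy algebraically; conventions in which
the two differ on the same predictions exist but cannot be reconstructed
unambiguously, so the standard pooled definition is used and the
acceptance surface treats the published micro-F1 value as a lower bound
rather than a point target. No train/test split is used — evaluation is
in-sample, matching the framing the package reproduces, and the
noiseless-simulation results (accuracy 1.0) should be read as
achievability ceilings, not generalisation estimates.

# Mendelian randomization

Per-instrument Wald ratios $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order SEs $se_{Yj}/|\hat\beta_{Xj}|$ feed two estimators:

* **IVW**, fixed-effect: $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$,
  $w_j = se_j^{-2}$, $se = (\sum w_j)^{-1/2}$. Fixed rather than
  random effects because three instruments cannot support a heterogeneity
  estimate. With one instrument IVW *is* the Wald ratio, exactly.
* **Weighted median**: ratios ordered, standardised weights accumulated,
  linear interpolation at cumulative weight 0.5 under the midpoint
  convention $s_j - w_j/2$; consistent when instruments carrying ≥50% of
  weight are valid. Its SE comes from a seeded parametric bootstrap
  (1000 draws from $N(\hat\theta_j, se_j)$), so identical seeds give
  identical SEs.

One-sample MR builds the instrument table inside the cohort: exposure
effects from logistic regressions of the binary blood-type contrast on
each instrument dosage (plus covariates), outcome effects from linear
(continuous traits) or logistic (binary) regressions on the same dosage.
Because the exposure is binary, estimates are on the outcome-per-log-odds
scale and are reported without rescaling; recovering a planted effect in
simulation therefore requires generating the outcome on that same scale,
which is exactly what the recovery tests do. Two practical caveats the
tests make explicit: fixed-effect IVW assumes near-independent
instruments (three tags of the *same* functional allele are strongly
correlated and undercover; one tag per allele, mirroring the selected
set, restores ~95% null coverage), and perfect tags separate the exposure
logistic, so MR simulations use moderate-LD instruments.

Two-sample MR inner-joins exposure and outcome summary tables on SNP id
and harmonises effect alleles: swapped alleles flip the outcome beta;
strand-ambiguous A/T and C/G SNPs are dropped with a warning (no
frequency-based strand inference); irreconcilable allele pairs are
dropped too. MR-Egger, MR-PRESSO and Steiger filtering are out of scope:
only IVW and the weighted median are implemented.

# Numerical choices and problem sizes

All randomness flows from one root seed, split per stage by fixed
offsets; a fixed seed reproduces every table byte-for-byte. Logistic IRLS
converges at a relative step below $10^{-10}$ (cap 100 iterations), the
multinomial Newton at $10^{-9}$ (cap 200; 500 for the classifier); IRLS
weights are floored at $10^{-12}$; softmax and log-likelihood
computations are max-shifted and floored to avoid overflow. Monomorphic
SNPs are skipped and logged, never fatal.

The shipped test and acceptance workloads use cohorts of 921 (the
study-sized noiseless benchmark), a 10⁴-SNP null background for the
hit-mapping property, 10⁵ haplotypes for LD-target verification, 1000
simulations for type-I calibration and 500 for MR null coverage — sizes
chosen to pin each statistical property with comfortable sampling margins
at desk scale.

# Known limitations

Three functional alleles, one population, no genotyping-intensity model;
composite LD only; in-sample evaluation; Wald inference away from
separation (no Firth correction); greedy rather than optimal relatedness
pruning; binary-exposure MR reported on the log-odds scale. Each is a
deliberate scope decision discussed above, not an oversight.
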