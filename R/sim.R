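#' ABO allele system
#'
#' Frequencies of the three classical functional haplotype classes at the
#' ABO locus. O carries the inactivating single-base deletion and produces
#' neither antigen; A and B encode glycosyltransferases for the A and B
#' antigens respectively.
#'
#' @param freq_O,freq_A,freq_B haplotype frequencies; must sum to 1.
#' @return An object of class `allele_system`.
#' @export
allele_system <- function(freq_O = 0.55, freq_A = 0.22, freq_B = 0.23) {
  freqs <- c(O = freq_O, A = freq_A, B = freq_B)
  if (any(freqs < 0) || any(freqs > 1)) {
    stop_abokit("allele frequencies must lie in [0, 1]")
  }
  if (abs(sum(freqs) - 1) > 1e-12) {
    stop_abokit("allele frequencies must sum to 1 (got %.15f)", sum(freqs))
  }
  structure(list(freqs = freqs), class = "allele_system")
}

# Maximum D (positive-association direction) between two binary loci with
# allele-1 frequencies p and q.
d_max_pos <- function(p, q) min(p * (1 - q), q * (1 - p))

#' Tag-SNP specification
#'
#' Describes a SNP whose "1" allele tags one of the functional ABO allele
#' classes at a target haplotype-level r-squared. Feasibility of the target
#' is checked against the attainable maximum
#' `D_max^2 / (p(1-p) q(1-q))` given the two allele frequencies.
#'
#' @param snp_id SNP label.
#' @param anchor which functional indicator the SNP tags: `"O"`, `"A"`,
#'   `"B"`, or `"none"` for a SNP unlinked to the locus.
#' @param tag_allele_freq frequency of the tag ("1") allele; `NULL` (the
#'   default) matches the anchor's empirical frequency at attach time —
#'   the realistic situation for array SNPs tagging the same underlying
#'   variant, and the only way a target r-squared of 1 stays feasible
#'   under sampling noise.
#' @param target_r2 haplotype-level squared correlation with the anchor
#'   indicator, in `[0, 1]`. Ignored when `anchor = "none"`.
#' @param anchor_freq frequency of the anchor indicator; needed only for the
#'   feasibility check at construction and rechecked when attaching.
#' @return An object of class `tag_snp_spec`.
#' @export
tag_snp_spec <- function(snp_id, anchor, tag_allele_freq = NULL, target_r2 = 0,
                         anchor_freq = NULL) {
  anchor <- match.arg(anchor, c("O", "A", "B", "none"))
  if (anchor == "none" && is.null(tag_allele_freq)) {
    stop_abokit("tag_allele_freq is required for an unanchored SNP")
  }
  if (!is.null(tag_allele_freq) &&
      (tag_allele_freq <= 0 || tag_allele_freq >= 1)) {
    stop_abokit("tag_allele_freq must lie strictly in (0, 1)")
  }
  if (target_r2 < 0 || target_r2 > 1) stop_abokit("target_r2 must be in [0, 1]")
  if (anchor != "none" && !is.null(anchor_freq) && !is.null(tag_allele_freq)) {
    check_r2_feasible(anchor_freq, tag_allele_freq, target_r2, snp_id)
  }
  structure(list(snp_id = snp_id, anchor = anchor,
                 tag_allele_freq = tag_allele_freq, target_r2 = target_r2),
            class = "tag_snp_spec")
}

check_r2_feasible <- function(p, q, target_r2, snp_id) {
  dmax <- d_max_pos(p, q)
  r2max <- dmax^2 / (p * (1 - p) * q * (1 - q))
  if (target_r2 > r2max + 1e-9) {
    stop_abokit(
      "target r2 = %.4f for %s is infeasible: with p = %.4f, q = %.4f, D_max = %.6f gives max r2 = %.4f",
      target_r2, snp_id, p, q, dmax, r2max)
  }
  invisible(r2max)
}

#' Sample ABO functional haplotypes
#'
#' Draws `n_haplotypes` functional alleles i.i.d. from the allele system.
#' Haplotypes pair consecutively into individuals, so the count must be
#' even.
#'
#' @param n_haplotypes even number of haplotypes to draw.
#' @param allele_sys an [allele_system()].
#' @param seed integer seed.
#' @return An object of class `haplotype_set` with elements `functional`
#'   (character vector in `{O,A,B}`), `tags` (0/1 matrix, one column per
#'   attached tag SNP) and `tag_specs`.
#' @export
sample_abo_haplotypes <- function(n_haplotypes, allele_sys, seed = NULL) {
  if (n_haplotypes <= 0 || n_haplotypes %% 2 != 0) {
    stop_abokit("n_haplotypes must be a positive even count")
  }
  functional <- with_seed(seed, {
    sample(names(allele_sys$freqs), n_haplotypes, replace = TRUE,
           prob = allele_sys$freqs)
  })
  structure(list(functional = functional,
                 tags = matrix(integer(0), nrow = n_haplotypes, ncol = 0),
                 tag_specs = list()),
            class = "haplotype_set")
}

#' Attach a tag SNP to a haplotype set
#'
#' Draws per-haplotype tag-allele bits conditionally on the anchor
#' indicator so that the haplotype-level disequilibrium equals
#' `D = sqrt(target_r2 * p(1-p) q(1-q))` (positive-association direction):
#' `P(tag = 1 | anchor = 1) = q + D/p` and
#' `P(tag = 1 | anchor = 0) = q - D/(1-p)`, where `p` is the empirical
#' anchor-indicator frequency in the set and `q` the tag-allele frequency.
#' The target r-squared is therefore exact in expectation.
#'
#' @param haps a `haplotype_set`.
#' @param spec a [tag_snp_spec()].
#' @param seed integer seed.
#' @return The haplotype set with one more tag column.
#' @export
attach_tag_snp <- function(haps, spec, seed = NULL) {
  n <- length(haps$functional)
  if (spec$anchor == "none") {
    bits <- with_seed(seed, rbinom(n, 1, spec$tag_allele_freq))
  } else {
    anchor_ind <- as.integer(haps$functional == spec$anchor)
    p <- mean(anchor_ind)
    if (p <= 0 || p >= 1) {
      stop_abokit("anchor '%s' is monomorphic in this haplotype set; cannot tag",
                  spec$anchor)
    }
    q <- spec$tag_allele_freq %||% p
    check_r2_feasible(p, q, spec$target_r2, spec$snp_id)
    d <- sqrt(spec$target_r2 * p * (1 - p) * q * (1 - q))
    p1 <- min(1, max(0, q + d / p))
    p0 <- min(1, max(0, q - d / (1 - p)))
    bits <- with_seed(seed, {
      rbinom(n, 1, ifelse(anchor_ind == 1L, p1, p0))
    })
  }
  haps$tags <- cbind(haps$tags, bits)
  colnames(haps$tags)[ncol(haps$tags)] <- spec$snp_id
  haps$tag_specs <- c(haps$tag_specs, list(spec))
  haps
}

#' Serotype an ABO diplotype
#'
#' Applies the Mendelian dominance rules of the ABO system (O recessive, A
#' and B codominant), then corrupts each call with probability
#' `typing_error_rate` by a uniform draw from the other three types,
#' emulating serological typing error.
#'
#' @param allele1,allele2 character vectors over `{O, A, B}`.
#' @param typing_error_rate probability in `[0, 1)` of a wrong recorded type.
#' @param seed integer seed (used only when the error rate is positive).
#' @return Character vector of blood types in `{O, A, B, AB}`.
#' @export
serotype <- function(allele1, allele2, typing_error_rate = 0, seed = NULL) {
  if (!all(allele1 %in% c("O", "A", "B")) || !all(allele2 %in% c("O", "A", "B"))) {
    stop_abokit("functional alleles must be O, A or B")
  }
  if (typing_error_rate < 0 || typing_error_rate >= 1) {
    stop_abokit("typing_error_rate must lie in [0, 1)")
  }
  has_a <- allele1 == "A" | allele2 == "A"
  has_b <- allele1 == "B" | allele2 == "B"
  type <- ifelse(has_a & has_b, "AB", ifelse(has_a, "A", ifelse(has_b, "B", "O")))
  if (typing_error_rate > 0) {
    type <- with_seed(seed, {
      flip <- runif(length(type)) < typing_error_rate
      wrong <- vapply(type[flip], function(t) {
        sample(setdiff(c("O", "A", "B", "AB"), t), 1)
      }, character(1))
      type[flip] <- wrong
      type
    })
  }
  type
}

#' Simulate a genome-wide background of null SNPs
#'
#' Each SNP's dosage is binomial(2, maf), independent of everything else;
#' this emulates the autosomal array background at reduced scale. MAFs are
#' drawn uniformly from `maf_range` and recorded in the metadata.
#'
#' @param n_samples number of individuals.
#' @param n_null_snps number of SNPs (0 gives a valid empty matrix).
#' @param maf_range length-2 numeric within (0, 0.5].
#' @param seed integer seed.
#' @param sample_ids optional sample-id row names.
#' @return A [geno_matrix()] with SNPs assigned round-robin to autosomes
#'   1..22 (chromosome 9 positions kept clear of the ABO locus block).
#' @export
simulate_null_genome <- function(n_samples, n_null_snps, maf_range = c(0.05, 0.5),
                                 seed = NULL, sample_ids = NULL) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_abokit("maf_range must be within (0, 0.5]")
  }
  ids <- sample_ids %||% sprintf("S%04d", seq_len(n_samples))
  if (n_null_snps == 0) {
    dos <- matrix(integer(0), nrow = n_samples, ncol = 0,
                  dimnames = list(ids, NULL))
    info <- data.frame(snp_id = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0), alt = character(0),
                       maf = numeric(0), stringsAsFactors = FALSE)
    return(geno_matrix(dos, info))
  }
  res <- with_seed(seed, {
    mafs <- runif(n_null_snps, maf_range[1], maf_range[2])
    dos <- vapply(mafs, function(m) rbinom(n_samples, 2, m), integer(n_samples))
    list(mafs = mafs, dos = dos)
  })
  dos <- matrix(as.integer(res$dos), nrow = n_samples,
                dimnames = list(ids, NULL))
  info <- data.frame(
    snp_id = sprintf("null%05d", seq_len(n_null_snps)),
    chrom = as.character(rep_len(c(1:8, 10:22), n_null_snps)),
    pos = 1e6L + 1000L * seq_len(n_null_snps),
    ref = "A", alt = "G",
    maf = res$mafs,
    stringsAsFactors = FALSE)
  geno_matrix(dos, info)
}

#' Simulation configuration
#'
#' Collects every knob of the cohort generator. Defaults emulate the study
#' structure: ~1000 recruited individuals, three perfect tag SNPs (one per
#' functional allele class) plus two redundant high-LD tags of the O
#' indicator, a null autosomal background, and QC contaminants (duplicate
#' and sibling pairs, one low-call-rate sample) that downstream QC should
#' remove.
#'
#' @param n_samples cohort size before QC.
#' @param allele_sys an [allele_system()]; defaults give a type distribution
#'   qualitatively similar to East-Asian cohorts.
#' @param tag_specs list of [tag_snp_spec()]s for the ABO-locus block.
#' @param n_null_snps,null_maf_range background SNP count and MAF window.
#' @param typing_error_rate probability a serotype is recorded wrongly.
#' @param n_duplicate_pairs,n_sib_pairs QC contaminants to inject.
#' @param causal_effects named list configuring trait generation, see
#'   [simulate_traits()].
#' @param missing_rate background genotype missingness.
#' @param n_low_callrate_samples samples with an extra block of missing
#'   calls (fraction `low_callrate_missing_frac`), to exercise call-rate QC.
#' @param low_callrate_missing_frac see above.
#' @param rng_seed root seed; every stage derives its own stream from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1008,
                       allele_sys = allele_system(),
                       tag_specs = default_tag_specs(allele_sys),
                       n_null_snps = 2000,
                       null_maf_range = c(0.05, 0.5),
                       typing_error_rate = 0,
                       n_duplicate_pairs = 40,
                       n_sib_pairs = 39,
                       causal_effects = list(),
                       missing_rate = 0.002,
                       n_low_callrate_samples = 1,
                       low_callrate_missing_frac = 0.10,
                       rng_seed = 1L) {
  if (n_samples <= 0) stop_abokit("n_samples must be positive")
  if (typing_error_rate < 0 || typing_error_rate >= 1) {
    stop_abokit("typing_error_rate must lie in [0, 1)")
  }
  structure(list(n_samples = n_samples, allele_sys = allele_sys,
                 tag_specs = tag_specs, n_null_snps = n_null_snps,
                 null_maf_range = null_maf_range,
                 typing_error_rate = typing_error_rate,
                 n_duplicate_pairs = n_duplicate_pairs,
                 n_sib_pairs = n_sib_pairs,
                 causal_effects = causal_effects,
                 missing_rate = missing_rate,
                 n_low_callrate_samples = n_low_callrate_samples,
                 low_callrate_missing_frac = low_callrate_missing_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Default ABO-locus tag panel
#'
#' Three perfect tags (r2 = 1), one per functional allele class, plus two
#' redundant tags of the O indicator at r2 0.95 and 0.98 — mirroring the
#' field-typical situation where several array SNPs tag the same
#' inactivating deletion and must later be collapsed onto a common tag.
#'
#' @param allele_sys an [allele_system()] providing anchor frequencies for
#'   the feasibility check.
#' @return List of [tag_snp_spec()]s.
#' @export
default_tag_specs <- function(allele_sys = allele_system()) {
  list(
    tag_snp_spec("tagO",  "O", target_r2 = 1.00),
    tag_snp_spec("tagA",  "A", target_r2 = 1.00),
    tag_snp_spec("tagB",  "B", target_r2 = 1.00),
    tag_snp_spec("tagO2", "O", target_r2 = 0.95),
    tag_snp_spec("tagO3", "O", target_r2 = 0.98))
}

# ABO locus lives at ~133.2 Mb on chromosome 9; tags get consecutive slots.
abo_snp_info <- function(tag_ids) {
  data.frame(snp_id = tag_ids, chrom = "9",
             pos = 133255000L + 1000L * seq_along(tag_ids),
             ref = "C", alt = "T", stringsAsFactors = FALSE)
}

#' Simulate trait phenotypes for a cohort
#'
#' Systolic and diastolic blood pressure are Gaussian with additive age and
#' sex terms plus an optional blood-type contrast shift; an optional binary
#' outcome follows a logistic model with a configured log odds ratio for a
#' contrast. All effect sizes and noise SDs are visible in `causal_effects`:
#' a named list whose entries `sbp`, `dbp` and `outcome` are lists with
#' elements `contrast` (e.g. `"B-vs-nonB"`) and `beta` (mmHg for pressures,
#' log-OR for the outcome).
#'
#' @param samples data.frame with columns `serotype`, `age`, `sex`.
#' @param causal_effects see above; empty list means no causal effect.
#' @param seed integer seed.
#' @param noise_sd_sbp,noise_sd_dbp residual SDs in mmHg.
#' @return The sample table with `sbp`, `dbp` and (if configured) `outcome`
#'   columns appended.
#' @export
simulate_traits <- function(samples, causal_effects = list(), seed = NULL,
                            noise_sd_sbp = 12, noise_sd_dbp = 8) {
  stopifnot(all(c("serotype", "age", "sex") %in% names(samples)))
  n <- nrow(samples)
  male <- as.integer(samples$sex == "male")
  shift <- function(cfg) {
    if (is.null(cfg)) return(rep(0, n))
    ind <- contrast_indicator(samples$serotype, cfg$contrast)
    cfg$beta * ind
  }
  with_seed(seed, {
    samples$sbp <- 110 + 0.25 * samples$age + 4 * male +
      shift(causal_effects$sbp) + rnorm(n, 0, noise_sd_sbp)
    samples$dbp <- 70 + 0.15 * samples$age + 3 * male +
      shift(causal_effects$dbp) + rnorm(n, 0, noise_sd_dbp)
    if (!is.null(causal_effects$outcome)) {
      eta <- -1 + shift(causal_effects$outcome)
      samples$outcome <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    }
    samples
  })
}

#' Binary indicator for a blood-type contrast
#'
#' @param serotype character vector over `{O, A, B, AB}`.
#' @param contrast one of `"O-vs-nonO"`, `"A-vs-nonA"`, `"B-vs-nonB"`,
#'   `"AB-vs-nonAB"`.
#' @return Integer 0/1 vector (1 = named type).
#' @export
contrast_indicator <- function(serotype, contrast) {
  type <- switch(contrast,
                 "O-vs-nonO" = "O", "A-vs-nonA" = "A",
                 "B-vs-nonB" = "B", "AB-vs-nonAB" = "AB",
                 stop_abokit("unknown contrast label '%s'", contrast))
  as.integer(serotype == type)
}

#' Inject duplicate and sibling pairs into a cohort
#'
#' Duplicates copy both ABO haplotypes and the whole null-genome row of a
#' source sample onto a target sample. Siblings are rebuilt as two children
#' of two simulated parents: at the ABO locus each child inherits one
#' parental haplotype from each parent; at each null SNP each parent
#' transmits one allele drawn from its genotype. Injected pair ids are
#' recorded as ground truth.
#'
#' @param cohort an `abo_cohort` (see [simulate_cohort()]).
#' @param n_duplicate_pairs,n_sib_pairs counts of pairs to inject.
#' @param seed integer seed.
#' @return The modified cohort with `truth$relatives` filled in.
#' @export
inject_relatives <- function(cohort, n_duplicate_pairs, n_sib_pairs, seed = NULL) {
  n_needed <- 2 * (n_duplicate_pairs + n_sib_pairs)
  n <- nrow(cohort$haplotypes$h1)
  if (n_needed > n) stop_abokit("not enough samples to inject %d pairs", n_needed %/% 2)
  if (n_needed == 0) {
    cohort$truth$relatives <- data.frame(id1 = character(0), id2 = character(0),
                                         relation = character(0),
                                         stringsAsFactors = FALSE)
    return(cohort)
  }
  ids <- cohort$samples$sample_id
  rel <- list()
  cohort <- with_seed(seed, {
    # use the tail of the cohort so pair membership is deterministic
    slot <- n
    take2 <- function() { s <- c(slot - 1L, slot); slot <<- slot - 2L; s }
    for (k in seq_len(n_duplicate_pairs)) {
      ij <- take2()
      cohort$haplotypes$h1[ij[2], ] <- cohort$haplotypes$h1[ij[1], ]
      cohort$haplotypes$h2[ij[2], ] <- cohort$haplotypes$h2[ij[1], ]
      cohort$null_geno$dosage[ij[2], ] <- cohort$null_geno$dosage[ij[1], ]
      rel[[length(rel) + 1]] <- data.frame(id1 = ids[ij[1]], id2 = ids[ij[2]],
                                           relation = "duplicate")
    }
    n_tags <- ncol(cohort$haplotypes$h1) - 1L
    for (k in seq_len(n_sib_pairs)) {
      ij <- take2()
      # two parents drawn fresh from the same generative distribution
      par_haps <- lapply(1:4, function(i) draw_one_haplotype(cohort))
      for (child in 1:2) {
        from_p1 <- sample(1:2, 1)
        from_p2 <- sample(3:4, 1)
        cohort$haplotypes$h1[ij[child], ] <- par_haps[[from_p1]]
        cohort$haplotypes$h2[ij[child], ] <- par_haps[[from_p2]]
      }
      # null SNPs: parents' genotypes then Mendelian transmission
      mafs <- cohort$null_geno$snp_info$maf
      if (length(mafs)) {
        gp1 <- rbinom(length(mafs), 2, mafs)
        gp2 <- rbinom(length(mafs), 2, mafs)
        for (child in 1:2) {
          a1 <- rbinom(length(mafs), 1, gp1 / 2)
          a2 <- rbinom(length(mafs), 1, gp2 / 2)
          cohort$null_geno$dosage[ij[child], ] <- as.integer(a1 + a2)
        }
      }
      rel[[length(rel) + 1]] <- data.frame(id1 = ids[ij[1]], id2 = ids[ij[2]],
                                           relation = "sib")
    }
    cohort
  })
  cohort$truth$relatives <- do.call(rbind, rel)
  cohort
}

# One haplotype (functional allele + tag bits) from the cohort's generative
# distribution; caller manages the RNG stream.
draw_one_haplotype <- function(cohort) {
  f <- cohort$config$allele_sys$freqs
  func <- sample(names(f), 1, prob = f)
  bits <- vapply(cohort$config$tag_specs, function(spec) {
    if (spec$anchor == "none") return(rbinom(1, 1, spec$tag_allele_freq))
    p <- f[[spec$anchor]]
    q <- spec$tag_allele_freq %||% p
    d <- sqrt(spec$target_r2 * p * (1 - p) * q * (1 - q))
    pr <- if (func == spec$anchor) min(1, q + d / p) else max(0, q - d / (1 - p))
    rbinom(1, 1, pr)
  }, integer(1))
  c(func = func, as.character(bits))
}

#' Simulate a full ABO cohort
#'
#' End-to-end generator: functional haplotypes, tag SNPs at target LD,
#' relative injection, serotyping with optional error, null genome,
#' covariates and traits, and missingness contaminants. All randomness
#' derives from `config$rng_seed` via fixed per-stage offsets, so a fixed
#' seed yields a byte-identical cohort.
#'
#' @param config a [sim_config()].
#' @return An object of class `abo_cohort`: list with `genotypes`
#'   (ABO-locus tags then null SNPs, one [geno_matrix()]), `samples`
#'   (sample table with serotype, covariates, traits), `truth` (diplotypes,
#'   injected relative pairs) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  seed <- config$rng_seed
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  haps <- sample_abo_haplotypes(2 * n, config$allele_sys,
                                seed = derive_seed(seed, 1))
  for (i in seq_along(config$tag_specs)) {
    haps <- attach_tag_snp(haps, config$tag_specs[[i]],
                           seed = derive_seed(seed, 10 + i))
  }
  # consecutive haplotypes pair into individuals
  odd <- seq(1, 2 * n, by = 2)
  h1 <- cbind(func = haps$functional[odd], haps$tags[odd, , drop = FALSE])
  h2 <- cbind(func = haps$functional[odd + 1], haps$tags[odd + 1, , drop = FALSE])

  null_geno <- simulate_null_genome(n, config$n_null_snps, config$null_maf_range,
                                    seed = derive_seed(seed, 2), sample_ids = ids)

  cohort <- structure(list(haplotypes = list(h1 = h1, h2 = h2),
                           null_geno = null_geno,
                           samples = data.frame(sample_id = ids,
                                                stringsAsFactors = FALSE),
                           truth = list(), config = config),
                      class = "abo_cohort")
  cohort <- inject_relatives(cohort, config$n_duplicate_pairs,
                             config$n_sib_pairs, seed = derive_seed(seed, 3))

  h1 <- cohort$haplotypes$h1; h2 <- cohort$haplotypes$h2
  cohort$samples$serotype <- serotype(h1[, "func"], h2[, "func"],
                                      config$typing_error_rate,
                                      seed = derive_seed(seed, 4))
  cohort$samples <- with_seed(derive_seed(seed, 5), {
    s <- cohort$samples
    s$sex <- ifelse(runif(n) < 0.5, "male", "female")
    s$age <- round(runif(n, 30, 70), 1)
    s
  })
  cohort$samples <- simulate_traits(cohort$samples, config$causal_effects,
                                    seed = derive_seed(seed, 6))

  tag_ids <- vapply(config$tag_specs, `[[`, character(1), "snp_id")
  tag_dos <- matrix(NA_integer_, n, length(tag_ids), dimnames = list(ids, tag_ids))
  for (j in seq_along(tag_ids)) {
    tag_dos[, j] <- as.integer(h1[, tag_ids[j]]) + as.integer(h2[, tag_ids[j]])
  }
  abo_geno <- geno_matrix(tag_dos, abo_snp_info(tag_ids))
  geno <- cbind_geno(abo_geno, cohort$null_geno)

  # missingness contaminants
  geno$dosage <- with_seed(derive_seed(seed, 7), {
    dos <- geno$dosage
    if (config$missing_rate > 0 && length(dos)) {
      dos[runif(length(dos)) < config$missing_rate] <- NA_integer_
    }
    if (config$n_low_callrate_samples > 0 && ncol(dos) > 0) {
      victims <- seq_len(min(config$n_low_callrate_samples, n))
      for (v in victims) {
        mask <- runif(ncol(dos)) < config$low_callrate_missing_frac
        dos[v, mask] <- NA_integer_
      }
    }
    dos
  })
  cohort$genotypes <- geno
  cohort$truth$diplotypes <- data.frame(sample_id = ids,
                                        allele1 = h1[, "func"],
                                        allele2 = h2[, "func"],
                                        stringsAsFactors = FALSE)
  cohort$haplotypes <- list(h1 = h1, h2 = h2)
  cohort
}

#' @export
print.abo_cohort <- function(x, ...) {
  cat(sprintf("abo_cohort: %d samples, %d SNPs (%d ABO-locus tags)\n",
              nrow(x$samples), ncol(x$genotypes$dosage),
              length(x$config$tag_specs)))
  print(table(x$samples$serotype))
  invisible(x)
}
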