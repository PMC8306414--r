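test_that("Wald ratio follows its closed form and harmonization symmetry", {
  expect_equal(wald_ratio(0.6, 0.1, 0, 0.05)$ratio, 0)
  wr <- wald_ratio(0.6, 0.1, 0.30, 0.05)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.05 / 0.6)
  # flipping the effect allele negates both betas: ratio invariant
  wr_flip <- wald_ratio(-0.6, 0.1, -0.30, 0.05)
  expect_equal(wr_flip$ratio, wr$ratio)
  expect_equal(wr_flip$se, wr$se)
  expect_error(wald_ratio(0, 0.1, 0.3, 0.05), "weak instrument")
})

test_that("IVW reduces to the Wald ratio and to the closed-form pooled mean", {
  one <- data.frame(snp_id = "s1", beta_exposure = 0.6, se_exposure = 0.1,
                    beta_outcome = 0.3, se_outcome = 0.05)
  res1 <- ivw(one)
  expect_equal(res1$estimate, 0.5)
  expect_equal(res1$se, 0.05 / 0.6)

  two <- data.frame(snp_id = c("s1", "s2"),
                    beta_exposure = 1, se_exposure = 0.1,
                    beta_outcome = c(0.5, 0.7), se_outcome = 0.1)
  res2 <- ivw(two)
  expect_equal(res2$estimate, 0.6)
  expect_equal(res2$se, 0.1 / sqrt(2))
})

test_that("IVW p-values are calibrated for null summary instruments", {
  set.seed(71)
  n_sims <- 1000
  pv <- vapply(seq_len(n_sims), function(i) {
    rows <- data.frame(snp_id = paste0("s", 1:3),
                       beta_exposure = 0.5, se_exposure = 0.02,
                       beta_outcome = rnorm(3, 0, 0.1), se_outcome = 0.1)
    ivw(rows)$p
  }, numeric(1))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("weighted median is the middle ratio under equal weights and is robust", {
  eq <- data.frame(snp_id = paste0("s", 1:3),
                   beta_exposure = 1, se_exposure = 0.1,
                   beta_outcome = c(0.2, 0.5, 0.9), se_outcome = 0.1)
  wm <- weighted_median(eq, seed = 5)
  expect_equal(wm$estimate, 0.5)

  # identical seeds give identical bootstrap SEs
  expect_equal(weighted_median(eq, seed = 9)$se,
               weighted_median(eq, seed = 9)$se)

  # one grossly pleiotropic instrument out of three: median stays near the
  # common ratio while IVW is dragged away
  pl <- eq
  pl$beta_outcome <- c(0.5, 0.5, 10.5)
  wm_pl <- weighted_median(pl, seed = 6)
  expect_lt(abs(wm_pl$estimate - 0.5), 2 * wm_pl$se)
  expect_gt(abs(ivw(pl)$estimate - 0.5), abs(wm_pl$estimate - 0.5))

  expect_error(weighted_median(eq[1, ]), "at least 2")
  expect_warning(weighted_median(eq[1:2, ], seed = 1), "fewer than 3")
})

# Outcome built on the log-odds scale of the exposure contrast: with a
# binary exposure the ratio estimator targets outcome units per log-odds,
# so a recoverable truth must be generated on that scale. eta(z) is the
# empirical per-dosage logit of the contrast.
logit_scale_outcome <- function(dos, indicator, theta, noise_sd, seed) {
  eta <- vapply(0:2, function(z) {
    p <- mean(indicator[dos == z])
    log(pmin(pmax(p, 0.01), 0.99) / (1 - pmin(pmax(p, 0.01), 0.99)))
  }, numeric(1))
  set.seed(seed)
  120 + theta * eta[dos + 1] + rnorm(length(dos), 0, noise_sd)
}

test_that("one-sample MR recovers a log-odds-scale causal effect", {
  tags <- list(tag_snp_spec("tagB1", "B", target_r2 = 0.6),
               tag_snp_spec("tagB2", "B", target_r2 = 0.5))
  co <- simulate_cohort(clean_config(n = 4000, seed = 72, tags = tags))
  ind <- as.integer(co$samples$serotype == "B")
  dos <- code_additive(subset_geno(co$genotypes, snps = "tagB1"))$dosage[, 1]
  co$samples$sbp <- logit_scale_outcome(dos, ind, theta = 5, noise_sd = 8,
                                        seed = 73)
  res <- one_sample_mr(co$genotypes, co$samples, "B-vs-nonB", "sbp",
                       "tagB1", covariates = character(0))
  expect_lt(abs(res$ivw$estimate - 5), 4 * res$ivw$se + 0.5)

  # single instrument: weighted median refuses, IVW proceeds
  expect_null(res$weighted_median)
  expect_s3_class(res$ivw, "mr_result")

  # two instruments: both estimators run (median warns about fragility)
  res2 <- suppressWarnings(
    one_sample_mr(co$genotypes, co$samples, "B-vs-nonB", "sbp",
                  c("tagB1", "tagB2"), covariates = character(0),
                  boot_seed = 3))
  expect_s3_class(res2$weighted_median, "mr_result")
  expect_identical(res2$ivw$n_instruments, 2L)
})

test_that("two-sample MR harmonizes alleles and respects proportionality", {
  expo <- data.frame(snp_id = c("s1", "s2", "s3"),
                     effect_allele = c("A", "C", "G"),
                     other_allele = c("G", "T", "A"),
                     beta = c(0.5, -0.4, 0.3), se = c(0.05, 0.04, 0.06))
  # outcome = 2 x exposure: both estimators return exactly 2
  outc <- expo
  outc$beta <- 2 * expo$beta
  res <- two_sample_mr(expo, outc, boot_seed = 11)
  expect_equal(res$ivw$estimate, 2)
  expect_equal(res$weighted_median$estimate, 2)

  # swapping outcome alleles (with negated betas) changes nothing
  outc_sw <- outc
  outc_sw$effect_allele <- expo$other_allele
  outc_sw$other_allele <- expo$effect_allele
  outc_sw$beta <- -outc$beta
  res_sw <- two_sample_mr(expo, outc_sw, boot_seed = 11)
  expect_equal(res_sw$ivw$estimate, res$ivw$estimate)

  # strand-ambiguous SNPs are dropped with a warning
  expo_at <- expo
  expo_at$effect_allele[1] <- "A"; expo_at$other_allele[1] <- "T"
  outc_at <- expo_at; outc_at$beta <- 2 * expo_at$beta
  w <- capture_warnings(res_at <- two_sample_mr(expo_at, outc_at, boot_seed = 11))
  expect_true(any(grepl("strand-ambiguous", w)))
  expect_identical(res_at$ivw$n_instruments, 2L)

  expect_error(two_sample_mr(expo, data.frame(snp_id = "zz", effect_allele = "A",
                                              other_allele = "G", beta = 1,
                                              se = 0.1)),
               "no shared SNPs")
})

test_that("two independently simulated GWAS recover a shared causal effect", {
  # two cohorts from the same architecture (different seeds); exposure =
  # O-vs-nonO log-odds from cohort 1, outcome = sbp generated on the same
  # log-odds scale (theta = 6) in cohort 2
  tags <- list(tag_snp_spec("ivO", "O", target_r2 = 0.6))
  make_cohort <- function(seed) {
    simulate_cohort(clean_config(n = 3000, seed = seed, tags = tags))
  }
  stat_row <- function(co, outcome, seed = NULL) {
    coded <- code_additive(subset_geno(co$genotypes, snps = "ivO"))
    dos <- coded$dosage[, 1]
    ind <- as.integer(co$samples$serotype == "O")
    if (outcome) {
      y <- logit_scale_outcome(dos, ind, theta = 6, noise_sd = 8, seed = seed)
      sm <- summary(lm(y ~ dos))$coefficients
      beta <- sm[2, 1]; se <- sm[2, 2]
    } else {
      f <- fit_logistic_snp(dos, ind)
      beta <- f$beta; se <- f$se
    }
    data.frame(snp_id = "ivO", effect_allele = coded$info$effect_allele,
               other_allele = coded$info$other_allele, beta = beta, se = se)
  }
  expo <- stat_row(make_cohort(81), outcome = FALSE)
  outc <- stat_row(make_cohort(82), outcome = TRUE, seed = 83)
  res <- two_sample_mr(expo, outc)
  # the OLS projection of eta(Z) and the logistic slope of X on Z differ
  # slightly when eta(z) is not exactly linear in z, so allow a modest
  # structural margin beyond the sampling CI
  expect_lt(abs(res$ivw$estimate - 6), 4 * res$ivw$se + 0.8)
})
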