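test_that("additive coding orients to the minor allele with stated tie-break", {
  dos <- cbind(a = c(2L, 2L, 1L, 2L), b = c(0L, 1L, 0L, 0L),
               c = c(2L, 0L, 2L, 0L))
  info <- data.frame(snp_id = c("a", "b", "c"), chrom = "1", pos = 1:3,
                     ref = c("G", "G", "G"), alt = c("A", "A", "A"))
  g <- geno_matrix(dos, info)
  coded <- code_additive(g)
  # a: alt freq 7/8 -> flipped, dosage counts REF copies
  expect_true(coded$info$flipped[1])
  expect_identical(coded$info$effect_allele[1], "G")
  expect_equal(unname(coded$dosage[, "a"]), c(0, 0, 1, 0))
  # b: alt freq 1/8 -> unchanged
  expect_false(coded$info$flipped[2])
  expect_equal(unname(coded$dosage[, "b"]), c(0, 1, 0, 0))
  # c: exactly 0.5 with alleles G/A -> 'A' (smaller string) is the effect allele
  expect_identical(coded$info$effect_allele[3], "A")
  expect_false(coded$info$flipped[3])

  info_bad <- info; info_bad$alt[2] <- "A,T"
  expect_error(code_additive(geno_matrix(dos, info_bad)), "b")
})

test_that("logistic fit matches the closed-form two-group odds ratio", {
  # dosage 0: 10 cases / 30 controls; dosage 1: 20 cases / 20 controls
  dosage <- c(rep(0, 40), rep(1, 40))
  outcome <- c(rep(1, 10), rep(0, 30), rep(1, 20), rep(0, 20))
  fit <- fit_logistic_snp(dosage, outcome)
  expect_equal(fit$beta, log(3), tolerance = 1e-6)
  expect_equal(fit$OR, 3.0, tolerance = 1e-6)
  expect_equal(fit$OR, exp(fit$beta), tolerance = 1e-12)
  expect_true(fit$converged)
  expect_identical(fit$n_used, 80L)

  # agreement with glm on a non-degenerate covariate-adjusted fit
  set.seed(31)
  n <- 400
  dos <- rbinom(n, 2, 0.3)
  age <- runif(n, 30, 70)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * dos + 0.01 * age))
  ours <- fit_logistic_snp(dos, y, cbind(age = age))
  ref <- glm(y ~ dos + age, family = binomial())
  expect_equal(ours$beta, unname(coef(ref)["dos"]), tolerance = 1e-6)
  expect_equal(ours$se, unname(sqrt(diag(vcov(ref)))["dos"]), tolerance = 1e-6)

  expect_error(fit_logistic_snp(rep(1, 50), rbinom(50, 1, 0.5)), "monomorphic")
  expect_error(fit_logistic_snp(rbinom(50, 2, 0.4), rep(1, 50)), "single class")
})

test_that("Wald p-values are calibrated under the null", {
  set.seed(32)
  n_sims <- 1000
  n <- 300
  pvals <- vapply(seq_len(n_sims), function(i) {
    dos <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.4)
    fit_logistic_snp(dos, y)$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("separation triggers the ridge-stabilised fallback, never divergence", {
  dosage <- c(rep(0, 40), rep(2, 40))
  outcome <- c(rep(0, 40), rep(1, 40))
  fit <- fit_logistic_snp(dosage, outcome)
  expect_false(fit$converged)
  expect_true(is.finite(fit$beta))
  expect_true(fit$beta > 2)  # large but bounded
})

test_that("multinomial fit matches nnet::multinom away from separation", {
  skip_if_not_installed("nnet")
  set.seed(33)
  n <- 600
  dos <- rbinom(n, 2, 0.4)
  # serotype probabilities depend mildly on dosage (no separation)
  lp <- cbind(0, 0.4 * dos, -0.3 * dos, 0.1 * dos)
  pr <- exp(lp) / rowSums(exp(lp))
  sero <- apply(pr, 1, function(p) sample(c("O", "A", "B", "AB"), 1, prob = p))
  ours <- fit_multinomial_snp(dos, sero)
  ref <- nnet::multinom(factor(sero, levels = c("O", "A", "B", "AB")) ~ dos,
                        trace = FALSE)
  rc <- coef(ref)[, "dos"]
  expect_equal(ours$beta, unname(rc[c("A", "B", "AB")]), tolerance = 1e-3)
  expect_true(all(ours$converged))
})

test_that("multinomial per-contrast tests behave under null and strong signal", {
  set.seed(34)
  # null: dosage independent of type
  pvals <- replicate(200, {
    dos <- rbinom(400, 2, 0.35)
    sero <- sample(c("O", "A", "B", "AB"), 400, TRUE, prob = c(0.4, 0.25, 0.25, 0.1))
    min(fit_multinomial_snp(dos, sero)$p)
  })
  # Bonferroni over 3 contrasts: min-p < 0.05/3 should occur ~5% of the time
  expect_lt(mean(pvals < 0.05 / 3), 0.12)

  # a perfect O-allele tag with the O allele minor: all three contrasts
  # point away from O (negative betas) at genome-wide significance
  cfg <- clean_config(n = 900, seed = 35, tags = three_tag_specs())
  cfg$allele_sys <- allele_system(0.4, 0.3, 0.3)
  co <- simulate_cohort(cfg)
  dos <- tag_dosages(co, "tagO")[, 1]
  res <- fit_multinomial_snp(dos, co$samples$serotype, snp_id = "tagO")
  expect_true(all(res$beta < 0))
  expect_true(all(res$p < 5e-8))
  expect_true(all(!res$converged))  # separation flagged, LRT p reported

  expect_error(fit_multinomial_snp(rbinom(50, 2, .4),
                                   sample(c("A", "B"), 50, TRUE)),
               "reference class O absent")
})

test_that("binomial and multinomial conclusions agree on null SNPs", {
  set.seed(36)
  agree <- replicate(100, {
    dos <- rbinom(500, 2, 0.3)
    sero <- sample(c("O", "A", "B", "AB"), 500, TRUE, prob = c(0.4, 0.25, 0.25, 0.1))
    pb <- fit_logistic_snp(dos, as.integer(sero == "O"), contrast = "O-vs-nonO")$p
    pm <- min(fit_multinomial_snp(dos, sero)$p)
    (pb > 5e-8) == (pm > 5e-8)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("scan hits map only to the ABO locus and hit screening is exact", {
  cfg <- sim_config(n_samples = 500, n_null_snps = 400,
                    tag_specs = three_tag_specs(),
                    n_duplicate_pairs = 0, n_sib_pairs = 0,
                    missing_rate = 0, n_low_callrate_samples = 0, rng_seed = 37)
  co <- simulate_cohort(cfg)
  scan <- run_scan(co$genotypes, co$samples, "binomial",
                   covariates = character(0))
  hits <- screen_hits(scan)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$chrom == "9"))

  # deterministic rerun
  scan2 <- run_scan(co$genotypes, co$samples, "binomial",
                    covariates = character(0))
  expect_identical(scan, scan2)

  # threshold straddle and ordering contract
  fake <- data.frame(snp_id = c("x", "y"), chrom = "1", pos = 1:2,
                     beta = c(1, 1), se = 1, OR = exp(1),
                     p = c(4e-8, 6e-8), n_used = 10L, converged = TRUE)
  kept <- screen_hits(fake, 5e-8)
  expect_identical(kept$snp_id, "x")
  expect_identical(nrow(screen_hits(fake[0, , drop = FALSE])), 0L)

  # sex/age adjustment leaves hit identity unchanged (independence holds
  # by construction in the simulator)
  scan_adj <- run_scan(co$genotypes, co$samples, "binomial",
                       covariates = c("sex", "age"))
  expect_setequal(unique(screen_hits(scan_adj)$snp_id), unique(hits$snp_id))
})
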