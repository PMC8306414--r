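test_that("haplotype sampling respects frequencies, degeneracy and seeds", {
  all_o <- sample_abo_haplotypes(100, allele_system(1, 0, 0), seed = 1)
  expect_true(all(all_o$functional == "O"))

  asys <- allele_system(0.6, 0.2, 0.2)
  h <- sample_abo_haplotypes(200000, asys, seed = 2)
  bound <- 3 * sqrt(0.6 * 0.4 / 200000)
  expect_lt(abs(mean(h$functional == "O") - 0.6), bound)

  h1 <- sample_abo_haplotypes(1000, asys, seed = 33)
  h2 <- sample_abo_haplotypes(1000, asys, seed = 33)
  expect_identical(h1, h2)

  expect_error(allele_system(0.5, 0.2, 0.2), "sum to 1")
  expect_error(sample_abo_haplotypes(101, asys), "even")
})

test_that("tag SNPs hit their target r2 and reject infeasible targets", {
  asys <- allele_system(0.4, 0.3, 0.3)
  h <- sample_abo_haplotypes(100000, asys, seed = 5)

  # perfect LD with matched frequency: tag equals the anchor indicator
  h1 <- attach_tag_snp(h, tag_snp_spec("t1", "O", target_r2 = 1), seed = 6)
  expect_identical(as.integer(h1$tags[, "t1"]),
                   as.integer(h1$functional == "O"))

  # independence: empirical r2 below 0.01 at this n
  h0 <- attach_tag_snp(h, tag_snp_spec("t0", "O", 0.4, target_r2 = 0), seed = 7)
  r2_0 <- cor(h0$tags[, "t0"], as.integer(h0$functional == "O"))^2
  expect_lt(r2_0, 0.01)

  # target 0.95 at p = q = 0.4: empirical r2 within +-0.02
  h95 <- attach_tag_snp(h, tag_snp_spec("t95", "O", 0.4, target_r2 = 0.95),
                        seed = 8)
  r2_95 <- cor(h95$tags[, "t95"], as.integer(h95$functional == "O"))^2
  expect_lt(abs(r2_95 - 0.95), 0.02)

  # infeasible: wildly mismatched frequencies cannot reach r2 = 0.95
  expect_error(
    attach_tag_snp(h, tag_snp_spec("bad", "O", 0.05, target_r2 = 0.95), seed = 9),
    "D_max")
})

test_that("serotyping follows ABO dominance and the typing-error model", {
  expect_identical(serotype("O", "O"), "O")
  expect_identical(serotype("A", "O"), "A")  # A dominant over recessive O
  expect_identical(serotype("O", "B"), "B")
  expect_identical(serotype("A", "B"), "AB") # codominant
  expect_identical(serotype(c("A", "B"), c("A", "B")), c("A", "B"))

  # error rate: flipped calls are never the true type
  n <- 20000
  s <- serotype(rep("O", n), rep("O", n), typing_error_rate = 0.3, seed = 10)
  expect_lt(abs(mean(s != "O") - 0.3), 0.02)
  expect_setequal(unique(s[s != "O"]), c("A", "B", "AB"))
  expect_error(serotype("A", "C"), "must be O, A or B")
})

test_that("null genome is seeded, unlinked and honours its MAF window", {
  g <- simulate_null_genome(50000, 1, maf_range = c(0.5, 0.5), seed = 11)
  expect_lt(abs(mean(g$dosage) - 1.0), 0.02)

  empty <- simulate_null_genome(10, 0, seed = 12)
  expect_s3_class(empty, "geno_matrix")
  expect_identical(ncol(empty$dosage), 0L)

  a <- simulate_null_genome(100, 50, seed = 13)
  b <- simulate_null_genome(100, 50, seed = 13)
  expect_identical(a, b)
  expect_error(simulate_null_genome(10, 5, maf_range = c(0, 0.5)), "maf_range")
})

test_that("trait simulation recovers configured effects and respects the null", {
  cfg <- clean_config(n = 5000, seed = 14, tags = three_tag_specs())
  co <- simulate_cohort(cfg)

  # null: B vs non-B difference in SBP bounded by 4 standard errors
  b <- co$samples$serotype == "B"
  d <- mean(co$samples$sbp[b]) - mean(co$samples$sbp[!b])
  se <- sqrt(var(co$samples$sbp[b]) / sum(b) + var(co$samples$sbp[!b]) / sum(!b))
  expect_lt(abs(d), 4 * se)

  # +5 mmHg for B vs non-B is recovered within its CI
  cfg5 <- clean_config(n = 5000, seed = 15, tags = three_tag_specs(),
                       causal_effects = list(sbp = list(contrast = "B-vs-nonB",
                                                        beta = 5)))
  co5 <- simulate_cohort(cfg5)
  b5 <- co5$samples$serotype == "B"
  d5 <- mean(co5$samples$sbp[b5]) - mean(co5$samples$sbp[!b5])
  se5 <- sqrt(var(co5$samples$sbp[b5]) / sum(b5) +
                var(co5$samples$sbp[!b5]) / sum(!b5))
  expect_lt(abs(d5 - 5), 3 * se5)

  expect_error(
    simulate_traits(co$samples, list(sbp = list(contrast = "Z-vs-nonZ", beta = 1))),
    "unknown contrast")
})

test_that("injected duplicates are concordant and zero pairs is a no-op", {
  cfg <- sim_config(n_samples = 60, n_null_snps = 200, n_duplicate_pairs = 2,
                    n_sib_pairs = 0, missing_rate = 0,
                    n_low_callrate_samples = 0, rng_seed = 16)
  co <- simulate_cohort(cfg)
  rel <- co$truth$relatives
  expect_identical(nrow(rel), 2L)
  for (i in seq_len(nrow(rel))) {
    d1 <- co$genotypes$dosage[rel$id1[i], ]
    d2 <- co$genotypes$dosage[rel$id2[i], ]
    expect_identical(unname(d1), unname(d2))
  }

  cfg0 <- sim_config(n_samples = 30, n_null_snps = 50, n_duplicate_pairs = 0,
                     n_sib_pairs = 0, missing_rate = 0,
                     n_low_callrate_samples = 0, rng_seed = 17)
  co0 <- simulate_cohort(cfg0)
  expect_identical(nrow(co0$truth$relatives), 0L)
})

test_that("with perfect tags and no typing error, serotype is a function of dosages", {
  cfg <- clean_config(n = 800, seed = 18, tags = three_tag_specs())
  co <- simulate_cohort(cfg)
  dos <- co$genotypes$dosage  # alt-coded: counts of each tag allele
  key <- paste(dos[, "tagO"], dos[, "tagA"], dos[, "tagB"])
  split_types <- split(co$samples$serotype, key)
  expect_true(all(vapply(split_types, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("a fixed seed reproduces the cohort byte-for-byte", {
  cfg <- sim_config(n_samples = 120, n_null_snps = 80, n_duplicate_pairs = 2,
                    n_sib_pairs = 2, rng_seed = 19)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})
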