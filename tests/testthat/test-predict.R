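test_that("the three-tag classifier perfectly recovers noiseless serotypes", {
  co <- simulate_cohort(clean_config(n = 900, seed = 51, tags = three_tag_specs()))
  dos <- tag_dosages(co, c("tagO", "tagA", "tagB"))
  model <- fit_abo_classifier(dos, co$samples$serotype)
  pr <- predict_probabilities(model, dos)
  rep <- multiclass_metrics(pr, co$samples$serotype,
                            prevalence = model$train_prevalence)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$f1_micro, 1.0)
  expect_equal(rep$f1_macro, 1.0)
  # O and AB are never confused, in either direction
  expect_identical(rep$confusion["O", "AB"] + rep$confusion["AB", "O"], 0L)
})

test_that("adding tag SNPs never hurts noiseless training accuracy", {
  co <- simulate_cohort(clean_config(n = 900, seed = 52, tags = three_tag_specs()))
  sero <- co$samples$serotype
  acc <- vapply(list("tagO", c("tagO", "tagA"), c("tagO", "tagA", "tagB")),
                function(set) {
                  dos <- tag_dosages(co, set)
                  m <- fit_abo_classifier(dos, sero)
                  # small subsets leave some types unassigned: macro-F1
                  # warns about undefined per-type F1, which is expected
                  suppressWarnings(
                    multiclass_metrics(predict_probabilities(m, dos), sero,
                                       m$train_prevalence)$accuracy)
                }, numeric(1))
  expect_true(all(diff(acc) >= -1e-12))
  expect_equal(acc[3], 1.0)
})

test_that("a single O-tag cannot separate A from B beyond their prevalences", {
  co <- simulate_cohort(clean_config(n = 4000, seed = 53, tags = three_tag_specs()))
  sero <- co$samples$serotype
  dos <- tag_dosages(co, "tagO")
  m <- fit_abo_classifier(dos, sero)
  pr <- predict_probabilities(m, dos)
  # among carriers of zero O alleles (two minor non-O alleles after
  # minor-allele coding) the model can only echo prevalence: fitted odds
  # A:B match the empirical ratio in that stratum
  idx <- dos[, 1] == 2
  emp <- sum(sero[idx] == "A") / sum(sero[idx] == "B")
  fit_ratio <- mean(pr[idx, "A"]) / mean(pr[idx, "B"])
  expect_lt(abs(log(fit_ratio / emp)), 0.1)
})

test_that("permuted labels drive accuracy to the majority prevalence", {
  co <- simulate_cohort(clean_config(n = 2000, seed = 54, tags = three_tag_specs()))
  sero <- sample(co$samples$serotype)  # break the genotype-phenotype link
  dos <- tag_dosages(co, c("tagO", "tagA", "tagB"))
  m <- fit_abo_classifier(dos, sero)
  rep <- suppressWarnings(
    multiclass_metrics(predict_probabilities(m, dos), sero,
                       m$train_prevalence))
  expect_lt(abs(rep$accuracy - max(m$train_prevalence)), 0.05)
})

test_that("predicted probabilities are a proper softmax", {
  co <- simulate_cohort(clean_config(n = 500, seed = 55, tags = three_tag_specs()))
  dos <- tag_dosages(co, c("tagO", "tagA", "tagB"))
  m <- fit_abo_classifier(dos, co$samples$serotype)

  # all-zero coefficients: uniform quarter probabilities
  m0 <- m; m0$coef[] <- 0
  pr0 <- predict_probabilities(m0, dos[1:5, ])
  expect_equal(unname(pr0), matrix(0.25, 5, 4))

  # rows sum to one for arbitrary genotype rows
  set.seed(56)
  rand <- matrix(sample(0:2, 3000, TRUE), ncol = 3,
                 dimnames = list(NULL, m$snp_subset))
  pr <- predict_probabilities(m, rand)
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-9)

  expect_error(predict_probabilities(m, dos[, 1:2]), "SNP subset")
  bad <- dos[1:3, ]; bad[2, 1] <- NA
  expect_error(predict_probabilities(m, bad), "missing dosages")
})

test_that("binary prevalence-threshold metrics match hand arithmetic", {
  # perfect scores
  perfect <- binary_metrics(c(rep(1, 10), rep(0, 30)),
                            c(rep(1, 10), rep(0, 30)), threshold = 0.25)
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  # constant score at the prevalence: the >= convention predicts all positive
  const <- binary_metrics(rep(0.25, 40), c(rep(1, 10), rep(0, 30)),
                          threshold = 0.25)
  expect_equal(const$sensitivity, 1)
  expect_equal(const$specificity, 0)

  # fixed 2x2 table TP=45 FN=5 FP=10 TN=40
  probs <- c(rep(0.9, 45), rep(0.1, 5), rep(0.9, 10), rep(0.1, 40))
  truth <- c(rep(1, 50), rep(0, 50))
  got <- binary_metrics(probs, truth, threshold = 0.5)
  expect_equal(got$sensitivity, 0.9)
  expect_equal(got$specificity, 0.8)
  expect_equal(got$ppv, 45 / 55)
  expect_equal(got$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9))

  expect_error(binary_metrics(runif(5), rep(1, 5)), "single class")
})

test_that("rank-statistic AUC handles ties and matches pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 50), rbinom(50, 1, 0.5))$auc, 0.5)

  set.seed(61)
  sc <- runif(2000); tr <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, tr)$auc - 0.5), 0.03)

  skip_if_not_installed("pROC")
  sc2 <- c(runif(300), runif(300) + 0.3); tr2 <- rep(0:1, each = 300)
  ours <- roc_auc(sc2, tr2)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(tr2, sc2, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("multi-class metrics satisfy their defining identities", {
  # constructed assignment with a known confusion structure
  sero <- c(rep("O", 40), rep("A", 30), rep("B", 20), rep("AB", 10))
  prob_for <- function(type) {
    p <- matrix(0.01, 1, 4, dimnames = list(NULL, c("O", "A", "B", "AB")))
    p[1, type] <- 0.97
    p
  }
  # 5 O->A and 2 B->AB mistakes, everything else on target
  assigned <- sero
  assigned[1:5] <- "A"
  assigned[71:72] <- "AB"
  pr <- do.call(rbind, lapply(assigned, prob_for))
  rep <- multiclass_metrics(pr, sero)
  expect_equal(rep$accuracy, 93 / 100)
  expect_equal(sum(rep$confusion), 100L)
  expect_equal(unname(diag(rep$confusion)), c(35L, 30L, 18L, 10L))
  # row sums equal per-type truth counts
  expect_equal(unname(rowSums(rep$confusion)), c(40L, 30L, 20L, 10L))
  # micro F1 equals accuracy for single-label argmax assignment
  expect_equal(rep$f1_micro, rep$accuracy)
  # macro F1 equals the unweighted mean of hand-computed per-type F1
  f1_hand <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)
  expect_equal(rep$f1_macro,
               mean(c(f1_hand(35, 0, 5), f1_hand(30, 5, 0),
                      f1_hand(18, 0, 2), f1_hand(10, 2, 0))))
  # per-type F1 identity against PPV and sensitivity
  pt <- rep$per_type
  expect_equal(pt$f1, 2 * pt$ppv * pt$sensitivity / (pt$ppv + pt$sensitivity))
})

test_that("probability patterns enumerate genotype combinations faithfully", {
  co <- simulate_cohort(clean_config(n = 2000, seed = 57, tags = three_tag_specs()))
  dos <- tag_dosages(co, c("tagO", "tagA", "tagB"))
  m <- fit_abo_classifier(dos, co$samples$serotype)
  pat <- probability_pattern_table(m, dos)
  expect_lte(nrow(pat), 27)
  expect_equal(sum(pat$n_obs), nrow(dos))

  # noiseless generative truth: each pattern's argmax is the Mendelian type
  truth_by_combo <- tapply(co$samples$serotype,
                           apply(dos, 1, paste, collapse = "/"),
                           function(x) unique(x))
  got_key <- apply(pat[, 1:3], 1, paste, collapse = "/")
  expect_identical(unname(pat$predicted),
                   as.vector(truth_by_combo[got_key]))

  # single-SNP model: at most 3 rows
  m1 <- fit_abo_classifier(dos[, "tagO", drop = FALSE], co$samples$serotype)
  expect_lte(nrow(probability_pattern_table(m1, dos[, "tagO", drop = FALSE])), 3)
})

test_that("binary one-vs-rest tag models classify at the prevalence threshold", {
  co <- simulate_cohort(clean_config(n = 900, seed = 58, tags = three_tag_specs()))
  sero <- co$samples$serotype
  dos <- tag_dosages(co, c("tagO", "tagA"))
  truth <- as.integer(sero == "O")
  m <- fit_binary_classifier(dos[, 1], truth)
  pr <- predict_binary_probability(m, dos[, 1])
  got <- binary_metrics(pr, truth, threshold = m$prevalence)
  expect_equal(got$accuracy, 1.0)  # perfect tag, noiseless cohort
  expect_false(m$converged)        # separation flagged, fit ridge-stabilised
})
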