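#' Wald ratio for one instrument
#'
#' Per-instrument causal estimate: SNP-outcome effect divided by
#' SNP-exposure effect, with the first-order delta-method standard error
#' `se_outcome / |beta_exposure|`.
#'
#' @param beta_exposure,se_exposure SNP-to-exposure effect and SE.
#' @param beta_outcome,se_outcome SNP-to-outcome effect and SE.
#' @return List with `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (beta_exposure == 0) {
    stop_abokit("weak instrument: beta_exposure is zero, Wald ratio undefined")
  }
  list(ratio = beta_outcome / beta_exposure,
       se = se_outcome / abs(beta_exposure))
}

mr_result <- function(method, estimate, se, n_instruments, ratios) {
  z <- estimate / se
  structure(list(method = method, estimate = estimate, se = se,
                 p = 2 * pnorm(-abs(z)), n_instruments = n_instruments,
                 ratios = ratios),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: estimate %.4f (se %.4f), p = %.3g, %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  invisible(x)
}

# Assemble per-instrument Wald ratios from an instrument table.
instrument_ratios <- function(rows) {
  stopifnot(all(c("snp_id", "beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome") %in% names(rows)))
  if (any(rows$se_exposure <= 0) || any(rows$se_outcome <= 0)) {
    stop_abokit("standard errors must be positive")
  }
  wr <- Map(wald_ratio, rows$beta_exposure, rows$se_exposure,
            rows$beta_outcome, rows$se_outcome)
  data.frame(snp_id = rows$snp_id,
             ratio = vapply(wr, `[[`, numeric(1), "ratio"),
             se = vapply(wr, `[[`, numeric(1), "se"),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW over the per-instrument Wald ratios: the weighted mean
#' with weights `1/se^2`, `se = 1/sqrt(sum(w))`, two-sided normal p. With
#' a single instrument this reduces exactly to the Wald ratio.
#'
#' @param rows data.frame with `snp_id`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @return An `mr_result`.
#' @export
ivw <- function(rows) {
  if (nrow(rows) < 1) stop_abokit("IVW needs at least one instrument")
  rat <- instrument_ratios(rows)
  w <- 1 / rat$se^2
  est <- sum(w * rat$ratio) / sum(w)
  mr_result("IVW", est, 1 / sqrt(sum(w)), nrow(rat), rat)
}

#' Weighted-median MR estimate
#'
#' Orders the Wald ratios, standardises the inverse-variance weights, and
#' takes the weighted median by linear interpolation at cumulative weight
#' 0.5 under the midpoint convention `s_j - w_j/2`. Consistent when
#' instruments carrying at least half the weight are valid. The SE comes
#' from a seeded parametric bootstrap resampling each ratio from
#' `Normal(ratio_j, se_j)`.
#'
#' @param rows instrument table as for [ivw()]; at least 2 rows (warns
#'   below 3).
#' @param n_boot bootstrap draws for the SE.
#' @param seed bootstrap seed.
#' @return An `mr_result`.
#' @export
weighted_median <- function(rows, n_boot = 1000, seed = 1L) {
  if (nrow(rows) < 2) stop_abokit("weighted median needs at least 2 instruments")
  if (nrow(rows) < 3) warning("weighted median with fewer than 3 instruments is fragile")
  rat <- instrument_ratios(rows)
  est <- weighted_median_point(rat$ratio, 1 / rat$se^2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      r <- rnorm(nrow(rat), rat$ratio, rat$se)
      weighted_median_point(r, 1 / rat$se^2)
    }, numeric(1))
  })
  mr_result("weighted_median", est, sd(boots), nrow(rat), rat)
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5)$y
}

#' One-sample Mendelian randomization within a cohort
#'
#' Builds the instrument table inside the cohort — per SNP, the exposure
#' effect is the logistic log-odds of the binary blood-type contrast on
#' the dosage (plus covariates), the outcome effect a linear (continuous
#' trait) or logistic (binary trait) regression on the same dosage and
#' covariates — then applies IVW and the weighted median. Monomorphic
#' instruments are dropped with a warning.
#'
#' @param geno a [geno_matrix()].
#' @param samples aligned sample table with `serotype`, covariates and the
#'   outcome trait.
#' @param exposure_contrast e.g. `"B-vs-nonB"`.
#' @param outcome_trait column name in `samples` (e.g. `"sbp"`).
#' @param iv_snps instrument SNP ids.
#' @param covariates covariate column names (sex recoded 0/1).
#' @param boot_seed seed for the weighted-median bootstrap.
#' @return List with `ivw`, `weighted_median` (NULL if < 2 instruments),
#'   `instruments` (the assembled table).
#' @export
one_sample_mr <- function(geno, samples, exposure_contrast, outcome_trait,
                          iv_snps, covariates = c("sex", "age"),
                          boot_seed = 1L) {
  stopifnot(outcome_trait %in% names(samples))
  coded <- code_additive(subset_geno(geno, snps = iv_snps))
  covar <- build_covar_matrix(samples, covariates)
  expo <- contrast_indicator(samples$serotype, exposure_contrast)
  outv <- samples[[outcome_trait]]
  binary_outcome <- all(outv %in% c(0, 1, NA))
  rows <- list()
  for (j in seq_along(iv_snps)) {
    dos <- coded$dosage[, j]
    if (length(unique(dos[!is.na(dos)])) < 2) {
      warning(sprintf("instrument %s is monomorphic; dropped", iv_snps[j]))
      next
    }
    fe <- fit_logistic_snp(dos, expo, covar, snp_id = iv_snps[j],
                           contrast = exposure_contrast)
    if (binary_outcome) {
      fo <- fit_logistic_snp(dos, outv, covar, snp_id = iv_snps[j],
                             contrast = outcome_trait)
      bo <- fo$beta; so <- fo$se
    } else {
      df <- data.frame(.y = outv, .dos = dos)
      if (!is.null(covar)) df <- cbind(df, as.data.frame(covar))
      fit <- lm(.y ~ ., data = df[stats::complete.cases(df), , drop = FALSE])
      sm <- summary(fit)$coefficients
      bo <- sm[".dos", 1]; so <- sm[".dos", 2]
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = iv_snps[j], effect_allele = coded$info$effect_allele[j],
      beta_exposure = fe$beta, se_exposure = fe$se,
      beta_outcome = bo, se_outcome = so, stringsAsFactors = FALSE)
  }
  inst <- do.call(rbind, rows)
  if (is.null(inst) || nrow(inst) == 0) stop_abokit("no usable instruments")
  wm <- if (nrow(inst) >= 2) weighted_median(inst, seed = boot_seed) else NULL
  list(ivw = ivw(inst), weighted_median = wm, instruments = inst)
}

#' Two-sample Mendelian randomization from summary statistics
#'
#' Inner-joins exposure and outcome summary tables on `snp_id`, harmonises
#' effect alleles (flipping the outcome beta when its effect/other alleles
#' are swapped relative to the exposure; strand-ambiguous A/T and C/G
#' SNPs are dropped with a warning; irreconcilable allele pairs are
#' dropped too), then applies IVW and the weighted median.
#'
#' @param exposure_stats,outcome_stats data.frames with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`.
#' @param boot_seed weighted-median bootstrap seed.
#' @return List with `ivw`, `weighted_median`, `instruments`.
#' @export
two_sample_mr <- function(exposure_stats, outcome_stats, boot_seed = 1L) {
  shared <- intersect(exposure_stats$snp_id, outcome_stats$snp_id)
  if (!length(shared)) stop_abokit("no shared SNPs between the two tables")
  ex <- exposure_stats[match(shared, exposure_stats$snp_id), ]
  ou <- outcome_stats[match(shared, outcome_stats$snp_id), ]
  ambiguous <- function(a, b) {
    p <- paste0(toupper(a), toupper(b))
    p %in% c("AT", "TA", "CG", "GC")
  }
  amb <- ambiguous(ex$effect_allele, ex$other_allele)
  if (any(amb)) {
    warning(sprintf("dropping %d strand-ambiguous SNP(s): %s", sum(amb),
                    paste(ex$snp_id[amb], collapse = ", ")))
  }
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ou$effect_allele == ex$other_allele
  bad <- !same & !swapped
  if (any(bad & !amb)) {
    warning(sprintf("dropping %d SNP(s) with irreconcilable alleles", sum(bad & !amb)))
  }
  keep <- !amb & (same | swapped)
  if (!any(keep)) stop_abokit("no SNPs left after harmonization")
  inst <- data.frame(snp_id = ex$snp_id[keep],
                     effect_allele = ex$effect_allele[keep],
                     beta_exposure = ex$beta[keep],
                     se_exposure = ex$se[keep],
                     beta_outcome = ifelse(swapped[keep], -ou$beta[keep], ou$beta[keep]),
                     se_outcome = ou$se[keep], stringsAsFactors = FALSE)
  wm <- if (nrow(inst) >= 2) weighted_median(inst, seed = boot_seed) else NULL
  list(ivw = ivw(inst), weighted_median = wm, instruments = inst)
}
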