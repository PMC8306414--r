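#' Additive minor-allele coding
#'
#' Re-orients stored alt-allele dosages so each SNP's dosage counts copies
#' of the minor allele in the analysed sample (the major allele becomes the
#' reference). Exact 50/50 frequency ties are broken by taking the
#' lexicographically smaller allele string as the effect allele.
#'
#' @param geno a [geno_matrix()] of biallelic SNPs.
#' @return List with `dosage` (recoded matrix) and `info` (data.frame:
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`, `flipped`).
#' @export
code_additive <- function(geno) {
  info <- geno$snp_info
  multi <- grepl(",", info$alt) | grepl(",", info$ref)
  if (any(multi)) {
    stop_abokit("multi-allelic site(s) not supported: %s",
                paste(info$snp_id[multi], collapse = ", "))
  }
  dos <- geno$dosage
  f_alt <- alt_freq(dos)
  eff <- character(ncol(dos)); oth <- character(ncol(dos))
  flipped <- logical(ncol(dos)); eaf <- numeric(ncol(dos))
  for (j in seq_len(ncol(dos))) {
    ref <- info$ref[j]; alt <- info$alt[j]; f <- f_alt[j]
    flip <- if (is.na(f)) FALSE
            else if (f < 0.5) FALSE
            else if (f > 0.5) TRUE
            else min(ref, alt) != alt  # tie: smaller allele string wins
    if (flip) {
      dos[, j] <- 2L - dos[, j]
      eff[j] <- ref; oth[j] <- alt; eaf[j] <- 1 - f
    } else {
      eff[j] <- alt; oth[j] <- ref; eaf[j] <- f
    }
    flipped[j] <- flip
  }
  list(dosage = dos,
       info = data.frame(snp_id = info$snp_id, effect_allele = eff,
                         other_allele = oth, eaf = eaf, flipped = flipped,
                         stringsAsFactors = FALSE))
}

assoc_row <- function(snp_id, contrast, beta, se, p, n_used, converged) {
  data.frame(snp_id = snp_id, contrast = contrast, beta = beta, se = se,
             OR = exp(beta), p = p, n_used = n_used, converged = converged,
             stringsAsFactors = FALSE)
}

#' Per-SNP binomial logistic association
#'
#' Maximum-likelihood logistic regression of a binary blood-type indicator
#' on a single SNP dosage plus covariates, Wald-tested. When separation is
#' detected (diverging coefficients or exploding standard errors — routine
#' with near-perfect ABO tags) the model is refit with a fixed tiny ridge
#' (1e-6) on non-intercept coefficients, flagged `converged = FALSE`, and
#' the reported p switches to the 1-df likelihood-ratio test (the Wald
#' statistic degenerates under separation as the SE diverges with the
#' estimate).
#'
#' @param dosage numeric dosage vector (minor-allele copies; NA = missing,
#'   dropped complete-case).
#' @param outcome 0/1 vector.
#' @param covariates optional numeric matrix (no intercept column).
#' @param snp_id,contrast labels carried into the result row.
#' @return One-row data.frame: `snp_id`, `contrast`, `beta`, `se`, `OR`,
#'   `p`, `n_used`, `converged`.
#' @export
fit_logistic_snp <- function(dosage, outcome, covariates = NULL,
                             snp_id = "snp", contrast = "binary") {
  keep <- !is.na(dosage) & !is.na(outcome)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  dosage <- dosage[keep]; outcome <- outcome[keep]
  covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  if (length(unique(outcome)) < 2) stop_abokit("outcome has a single class")
  if (length(unique(dosage)) < 2) {
    stop_abokit("SNP %s is monomorphic in the analysed samples", snp_id)
  }
  X <- cbind(`(Intercept)` = 1, dosage = dosage, covariates)
  fit <- fit_logistic_core(X, outcome, ridge = 0)
  converged <- TRUE
  if (looks_separated(fit)) {
    fit <- fit_logistic_core(X, outcome, ridge = 1e-6)
    converged <- FALSE
  }
  beta <- fit$coef[2]
  se <- sqrt(fit$vcov[2, 2])
  if (converged) {
    p <- 2 * pnorm(-abs(beta / se))
  } else {
    # Wald collapses under separation (diverging SE); fall back to the
    # 1-df likelihood-ratio test against the dosage-free model
    fit0 <- fit_logistic_core(X[, -2, drop = FALSE], outcome, ridge = 0)
    lrt <- max(2 * (fit$loglik - fit0$loglik), 0)
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  assoc_row(snp_id, contrast, beta, se, max(p, .Machine$double.xmin),
            length(outcome), converged)
}

#' Per-SNP multinomial log-linear association
#'
#' One joint multinomial fit per SNP of the quaternary blood type (O as
#' the reference level) on dosage plus covariates:
#' `log(P(k)/P(O)) = a_k + b_k * dosage + covariates`, k in {A, B, AB}.
#' Same ridge-on-separation contract as the binomial fit: Wald p per
#' contrast for converged fits, per-contrast 1-df likelihood-ratio p when
#' separation is flagged.
#'
#' @param dosage numeric dosage vector.
#' @param serotype character/factor over `{O, A, B, AB}`; O must be present.
#' @param covariates optional numeric matrix.
#' @param snp_id label for the result rows.
#' @return Three-row data.frame with contrasts `A-vs-O`, `B-vs-O`,
#'   `AB-vs-O`.
#' @export
fit_multinomial_snp <- function(dosage, serotype, covariates = NULL,
                                snp_id = "snp") {
  keep <- !is.na(dosage) & !is.na(serotype)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  dosage <- dosage[keep]
  sero <- as.character(serotype)[keep]
  covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  if (!any(sero == "O")) stop_abokit("reference class O absent")
  if (length(unique(sero)) < 2) stop_abokit("serotype has a single level")
  if (length(unique(dosage)) < 2) {
    stop_abokit("SNP %s is monomorphic in the analysed samples", snp_id)
  }
  present <- intersect(c("O", "A", "B", "AB"), unique(sero))
  y <- factor(sero, levels = present)
  X <- cbind(`(Intercept)` = 1, dosage = dosage, covariates)
  fit <- fit_multinom_core(X, y, ridge = 0)
  converged <- TRUE
  if (multinom_looks_separated(fit)) {
    fit <- fit_multinom_core(X, y, ridge = 1e-6)
    converged <- FALSE
  }
  p_cols <- ncol(X)
  rows <- lapply(seq_along(present[-1]), function(a) {
    idx <- (a - 1) * p_cols + 2  # dosage coefficient of class a+1
    beta <- fit$coef[2, a]
    se <- sqrt(fit$vcov[idx, idx])
    if (converged) {
      pval <- 2 * pnorm(-abs(beta / se))
    } else {
      # per-contrast 1-df likelihood ratio: refit with this class's dosage
      # coefficient pinned to zero (same stabilising ridge)
      fit0 <- fit_multinom_core(X, y, ridge = 1e-6, fix_idx = idx)
      lrt <- max(2 * (fit$loglik_unpen - fit0$loglik_unpen), 0)
      pval <- pchisq(lrt, df = 1, lower.tail = FALSE)
    }
    assoc_row(snp_id, paste0(present[a + 1], "-vs-O"), beta, se,
              max(pval, .Machine$double.xmin), length(dosage), converged)
  })
  do.call(rbind, rows)
}

#' Genome-wide association scan
#'
#' Applies the per-SNP binomial (all four dichotomizations) or multinomial
#' (three contrasts vs O) fit over every SNP, with additive minor-allele
#' coding and covariate adjustment, and emits a Manhattan-plot-ready
#' summary table. Monomorphic or otherwise unfittable SNPs are skipped and
#' logged in the `skipped` attribute, never fatal.
#'
#' @param geno a [geno_matrix()] (post-QC).
#' @param samples sample table aligned with `geno` rows; needs `serotype`
#'   plus any covariate columns.
#' @param mode `"binomial"` or `"multinomial"`.
#' @param covariates character vector of `samples` column names to adjust
#'   for (`sex` is recoded 0/1); use `pcs` to append PC scores.
#' @param pcs optional matrix of per-sample PC scores to include.
#' @return Data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `contrast`, `beta`, `se`,
#'   `OR`, `p`, `n_used`, `converged`, `neg_log10_p`.
#' @export
run_scan <- function(geno, samples, mode = c("binomial", "multinomial"),
                     covariates = c("sex", "age"), pcs = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(samples) == nrow(geno$dosage))
  coded <- code_additive(geno)
  covar <- build_covar_matrix(samples, covariates, pcs)
  contrasts_bin <- c("O-vs-nonO", "A-vs-nonA", "B-vs-nonB", "AB-vs-nonAB")
  out <- vector("list", ncol(coded$dosage))
  skipped <- character(0)
  for (j in seq_len(ncol(coded$dosage))) {
    sid <- coded$info$snp_id[j]
    dos <- coded$dosage[, j]
    res <- tryCatch({
      if (mode == "binomial") {
        do.call(rbind, lapply(contrasts_bin, function(ct) {
          fit_logistic_snp(dos, contrast_indicator(samples$serotype, ct),
                           covar, snp_id = sid, contrast = ct)
        }))
      } else {
        fit_multinomial_snp(dos, samples$serotype, covar, snp_id = sid)
      }
    }, error = function(e) {
      skipped <<- c(skipped, sprintf("%s: %s", sid, conditionMessage(e)))
      NULL
    })
    out[[j]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop_abokit("no SNP could be fit")
  meta <- geno$snp_info[match(res$snp_id, geno$snp_info$snp_id), c("chrom", "pos")]
  add <- coded$info[match(res$snp_id, coded$info$snp_id), ]
  res <- cbind(res[, "snp_id", drop = FALSE], meta,
               add[, c("effect_allele", "other_allele", "eaf")],
               res[, setdiff(names(res), "snp_id")])
  res$neg_log10_p <- -log10(res$p)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

build_covar_matrix <- function(samples, covariates, pcs = NULL) {
  cols <- list()
  for (cv in covariates) {
    if (!cv %in% names(samples)) stop_abokit("covariate '%s' not in sample table", cv)
    v <- samples[[cv]]
    if (cv == "sex") v <- as.integer(v == "male")
    cols[[cv]] <- as.numeric(v)
  }
  covar <- if (length(cols)) do.call(cbind, cols) else NULL
  if (!is.null(pcs)) covar <- cbind(covar, pcs)
  covar
}

#' Screen genome-wide hits
#'
#' Retains rows with `p < alpha` (default 5e-8, the Bonferroni-style
#' genome-wide threshold, -log10 of about 7.3), sorted ascending by p with
#' ties broken by larger absolute effect then by (chrom, pos).
#'
#' @param results scan table from [run_scan()].
#' @param alpha significance threshold in (0, 1).
#' @return The hit subset, same columns.
#' @export
screen_hits <- function(results, alpha = 5e-8) {
  if (alpha <= 0 || alpha >= 1) stop_abokit("alpha must be in (0, 1)")
  hits <- results[results$p < alpha, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$p, -abs(hits$beta), hits$chrom, hits$pos)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
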