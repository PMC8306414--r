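ABO_LEVELS <- c("O", "A", "B", "AB")

#' Fit the multinomial ABO classifier
#'
#' Ridge-penalised maximum-likelihood multinomial logistic model of the
#' quaternary blood type (reference O) on the dosages of a selected SNP
#' subset. The ridge (default 1e-4 on non-intercept coefficients) is
#' mandatory because noiseless tagging makes the classes perfectly
#' separable; it bounds the coefficients while leaving the fitted class
#' probabilities effectively saturated.
#'
#' @param dosages numeric matrix, samples x selected SNPs, with column
#'   names.
#' @param serotypes character/factor over `{O, A, B, AB}`; all four types
#'   must be present for training.
#' @param ridge penalty on non-intercept coefficients.
#' @return Object of class `abo_classifier`: `snp_subset`, `coef`
#'   (one column per non-reference class A, B, AB), `ridge`,
#'   `train_prevalence`, `converged`, `train_levels`.
#' @export
fit_abo_classifier <- function(dosages, serotypes, ridge = 1e-4) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  sero <- as.character(serotypes)
  missing_types <- setdiff(ABO_LEVELS, unique(sero))
  if (length(missing_types)) {
    stop_abokit("training data lacks type(s): %s",
                paste(missing_types, collapse = ", "))
  }
  keep <- stats::complete.cases(dosages) & !is.na(sero)
  dosages <- dosages[keep, , drop = FALSE]
  y <- factor(sero[keep], levels = ABO_LEVELS)
  X <- cbind(`(Intercept)` = 1, dosages)
  fit <- fit_multinom_core(X, y, ridge = ridge, max_iter = 500)
  if (!fit$converged) {
    stop_abokit("multinomial classifier failed to converge (ridge = %g); max |coef| = %.3g",
                ridge, max(abs(fit$coef)))
  }
  prev <- prop.table(table(factor(sero[keep], levels = ABO_LEVELS)))
  structure(list(snp_subset = colnames(dosages), coef = fit$coef,
                 ridge = ridge,
                 train_prevalence = setNames(as.numeric(prev), ABO_LEVELS),
                 converged = fit$converged, train_levels = ABO_LEVELS),
            class = "abo_classifier")
}

#' @export
print.abo_classifier <- function(x, ...) {
  cat(sprintf("abo_classifier: {%s}, ridge %g\n",
              paste(x$snp_subset, collapse = ", "), x$ridge))
  print(round(x$coef, 3))
  invisible(x)
}

#' Predict per-type probabilities
#'
#' Softmax over the per-class linear predictors with type O as the
#' reference (its linear predictor is identically zero); each row sums
#' to 1. Genotype rows whose joint combination was never seen in training
#' are still scored by the linear model but flagged as extrapolation.
#'
#' @param model an [fit_abo_classifier()] result.
#' @param dosages matrix whose columns match `model$snp_subset`.
#' @return Matrix samples x 4 (`O`, `A`, `B`, `AB`), with attribute
#'   `extrapolated` (logical per row, set by [probability_pattern_table()]
#'   consumers via the `seen` attribute when available).
#' @export
predict_probabilities <- function(model, dosages) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(model$snp_subset)) {
    stop_abokit("dosage columns do not match the model's SNP subset")
  }
  if (!is.null(colnames(dosages)) &&
      !identical(colnames(dosages), model$snp_subset)) {
    if (!all(model$snp_subset %in% colnames(dosages))) {
      stop_abokit("dosage columns do not match the model's SNP subset")
    }
    dosages <- dosages[, model$snp_subset, drop = FALSE]
  }
  if (anyNA(dosages)) stop_abokit("missing dosages are not imputed at prediction")
  X <- cbind(1, dosages)
  eta <- cbind(0, X %*% model$coef)  # O is the reference: eta_O = 0
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  pr <- e / rowSums(e)
  colnames(pr) <- ABO_LEVELS
  rownames(pr) <- rownames(dosages)
  pr
}

#' Prevalence-threshold binary classification metrics
#'
#' The by-type binary battery: predict positive iff the predicted
#' probability is at least the threshold (by default the baseline type
#' prevalence), then compute the 2x2-table metrics. Zero-denominator
#' ratios are reported `NA`, never 0.
#'
#' @param prob_of_type per-sample probability of the type.
#' @param truth_indicator 0/1 truth for the type.
#' @param threshold classification cutoff in (0, 1); defaults to the
#'   observed prevalence of the positive class.
#' @return One-row data.frame: `threshold`, `tp`, `fn`, `fp`, `tn`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `f1`, `auc`.
#' @export
binary_metrics <- function(prob_of_type, truth_indicator, threshold = NULL) {
  truth <- as.integer(truth_indicator)
  if (length(unique(truth)) < 2) {
    stop_abokit("truth indicator has a single class; AUC undefined")
  }
  threshold <- threshold %||% mean(truth)
  if (threshold <= 0 || threshold >= 1) stop_abokit("threshold must be in (0, 1)")
  pred <- as.integer(prob_of_type >= threshold)
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  fp <- sum(pred == 1 & truth == 0); tn <- sum(pred == 0 & truth == 0)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(tp, tp + fn); ppv <- rat(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  data.frame(threshold = threshold, tp = tp, fn = fn, fp = fp, tn = tn,
             accuracy = (tp + tn) / length(truth),
             sensitivity = sens, specificity = rat(tn, tn + fp),
             ppv = ppv, npv = rat(tn, tn + fn), f1 = f1,
             auc = roc_auc(prob_of_type, truth)$auc)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) statistic with midrank tie handling —
#' all-tied scores give exactly 0.5 — plus curve points from a threshold
#' sweep over the unique scores.
#'
#' @param scores predicted probabilities or any monotone score.
#' @param truth_indicator 0/1 truth.
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, truth_indicator) {
  truth <- as.integer(truth_indicator)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop_abokit("both classes required for ROC/AUC")
  r <- rank(scores)  # midranks
  auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(scores >= t & truth == 0) / n0, 0)),
    tpr = c(0, vapply(thr, function(t) sum(scores >= t & truth == 1) / n1, 0)))
  list(auc = auc, curve = curve)
}

#' Multi-class evaluation report
#'
#' Argmax assignment (probability ties go to the type with the larger
#' training prevalence, passed via `prevalence`), then the full battery:
#' per-type one-vs-rest metrics from the argmax tables, overall accuracy,
#' micro F1 (pooled one-vs-rest tables; equals accuracy for single-label
#' assignment), macro F1 (unweighted mean of defined per-type F1), and the
#' 4x4 confusion matrix.
#'
#' @param probabilities samples x 4 matrix with columns `O, A, B, AB`.
#' @param serotypes true types.
#' @param prevalence optional named prevalences for tie-breaking (defaults
#'   to the observed distribution of `serotypes`).
#' @return Object of class `classification_report`: `per_type` data.frame,
#'   `accuracy`, `f1_micro`, `f1_macro`, `confusion`.
#' @export
multiclass_metrics <- function(probabilities, serotypes, prevalence = NULL) {
  sero <- factor(as.character(serotypes), levels = ABO_LEVELS)
  prev <- prevalence %||%
    setNames(as.numeric(prop.table(table(sero))), ABO_LEVELS)
  pr <- probabilities[, ABO_LEVELS, drop = FALSE]
  # argmax with prevalence tie-break
  assigned <- apply(pr, 1, function(row) {
    best <- which(row == max(row))
    if (length(best) > 1) best <- best[which.max(prev[ABO_LEVELS[best]])]
    ABO_LEVELS[best]
  })
  assigned <- factor(assigned, levels = ABO_LEVELS)
  confusion <- table(truth = sero, predicted = assigned)
  acc <- sum(diag(confusion)) / sum(confusion)
  per_type <- do.call(rbind, lapply(ABO_LEVELS, function(t) {
    truth <- as.integer(sero == t)
    pred <- as.integer(assigned == t)
    tp <- sum(pred & truth); fn <- sum(!pred & truth)
    fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
    rat <- function(num, den) if (den == 0) NA_real_ else num / den
    sens <- rat(tp, tp + fn); ppv <- rat(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_ else
      2 * ppv * sens / (ppv + sens)
    auc <- if (length(unique(truth)) < 2) NA_real_ else roc_auc(pr[, t], truth)$auc
    data.frame(type = t, tp = tp, fn = fn, fp = fp, tn = tn,
               accuracy = (tp + tn) / length(truth), sensitivity = sens,
               specificity = rat(tn, tn + fp), ppv = ppv,
               npv = rat(tn, tn + fn), f1 = f1, auc = auc,
               stringsAsFactors = FALSE)
  }))
  tp_all <- sum(per_type$tp); fp_all <- sum(per_type$fp); fn_all <- sum(per_type$fn)
  f1_micro <- 2 * tp_all / (2 * tp_all + fp_all + fn_all)
  f1_defined <- per_type$f1[!is.na(per_type$f1)]
  if (length(f1_defined) < nrow(per_type)) {
    warning("macro F1 averages only the defined per-type F1 values")
  }
  structure(list(per_type = per_type, accuracy = acc, f1_micro = f1_micro,
                 f1_macro = mean(f1_defined), confusion = confusion,
                 assigned = assigned),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f, F1 micro %.3f, F1 macro %.3f\n",
              x$accuracy, x$f1_micro, x$f1_macro))
  print(x$confusion)
  invisible(x)
}

#' Predicted-probability pattern table
#'
#' One row per observed joint genotype combination of the model's SNPs
#' (at most 3^k for k biallelic SNPs), with the predicted type
#' probabilities, the argmax call, and the observed count. Combinations
#' absent from the supplied data simply do not appear; scoring them is
#' extrapolation.
#'
#' @param model an `abo_classifier`.
#' @param dosages matrix of dosages over the model's SNPs.
#' @return Data.frame: one column per SNP, `n_obs`, `pO`, `pA`, `pB`,
#'   `pAB`, `predicted`.
#' @export
probability_pattern_table <- function(model, dosages) {
  dosages <- as.matrix(dosages)
  colnames(dosages) <- colnames(dosages) %||% model$snp_subset
  key <- apply(dosages, 1, paste, collapse = "/")
  combos <- unique(as.data.frame(dosages))
  combos <- combos[order(apply(combos, 1, paste, collapse = "/")), , drop = FALSE]
  pr <- predict_probabilities(model, as.matrix(combos))
  counts <- table(key)
  combo_key <- apply(combos, 1, paste, collapse = "/")
  out <- cbind(combos,
               n_obs = as.integer(counts[combo_key]),
               setNames(as.data.frame(pr), paste0("p", ABO_LEVELS)),
               predicted = ABO_LEVELS[max.col(pr, ties.method = "first")])
  rownames(out) <- NULL
  out
}

#' Table-1-style evaluation of a SNP set
#'
#' Fits the multinomial classifier on the given SNP subset and reports the
#' per-type prevalence-threshold binary battery plus the multi-class
#' report, in the standard column order (accuracy, sensitivity,
#' specificity, PPV, NPV, F1, AUC).
#'
#' @param geno a [geno_matrix()].
#' @param samples sample table with `serotype`.
#' @param snp_set character vector of SNP ids.
#' @param ridge classifier penalty.
#' @return List with `model`, `report` (multi-class), `binary` (per-type
#'   data.frame using the type probability from the multinomial model).
#' @export
evaluate_snp_set <- function(geno, samples, snp_set, ridge = 1e-4) {
  coded <- code_additive(subset_geno(geno, snps = snp_set))
  dos <- coded$dosage
  keep <- stats::complete.cases(dos) & !is.na(samples$serotype)
  dos <- dos[keep, , drop = FALSE]
  sero <- samples$serotype[keep]
  model <- fit_abo_classifier(dos, sero, ridge = ridge)
  pr <- predict_probabilities(model, dos)
  report <- multiclass_metrics(pr, sero, prevalence = model$train_prevalence)
  binary <- do.call(rbind, lapply(ABO_LEVELS, function(t) {
    truth <- as.integer(sero == t)
    cbind(type = t, binary_metrics(pr[, t], truth))
  }))
  list(model = model, report = report, binary = binary)
}

#' Binary one-vs-rest SNP classifier
#'
#' Logistic model of a blood-type indicator on one or more SNP dosages,
#' with the same ridge-on-separation contract as the association fits
#' (perfect tags separate the classes, so the ridge-stabilised fit is the
#' norm rather than the exception). Used for the by-type binary
#' classification batteries.
#'
#' @param dosages numeric vector or matrix of dosages.
#' @param indicator 0/1 truth for the type.
#' @param ridge penalty applied when separation is detected.
#' @return Object of class `binary_tag_model`: `coef`, `converged`,
#'   `prevalence` (training prevalence of the positive class).
#' @export
fit_binary_classifier <- function(dosages, indicator, ridge = 1e-6) {
  dosages <- as.matrix(dosages)
  keep <- stats::complete.cases(dosages) & !is.na(indicator)
  X <- cbind(`(Intercept)` = 1, dosages[keep, , drop = FALSE])
  y <- as.integer(indicator)[keep]
  if (length(unique(y)) < 2) stop_abokit("indicator has a single class")
  fit <- fit_logistic_core(X, y, ridge = 0)
  converged <- TRUE
  if (looks_separated(fit)) {
    fit <- fit_logistic_core(X, y, ridge = ridge)
    converged <- FALSE
  }
  structure(list(coef = setNames(fit$coef, colnames(X)),
                 converged = converged, prevalence = mean(y)),
            class = "binary_tag_model")
}

#' @rdname fit_binary_classifier
#' @param model a `binary_tag_model`.
#' @param newdata dosage vector/matrix with the same columns as training.
#' @return Predicted probabilities of the positive class.
#' @export
predict_binary_probability <- function(model, newdata) {
  X <- cbind(1, as.matrix(newdata))
  if (ncol(X) != length(model$coef)) {
    stop_abokit("newdata has %d dosage column(s); model expects %d",
                ncol(X) - 1, length(model$coef) - 1)
  }
  drop(1 / (1 + exp(-X %*% model$coef)))
}
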