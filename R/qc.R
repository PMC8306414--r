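#' Sample- and SNP-level call-rate filtering
#'
#' Samples with call rate below `sample_threshold` are removed first, then
#' SNPs with call rate (over retained samples) below `snp_threshold`.
#'
#' @param geno a [geno_matrix()].
#' @param sample_threshold,snp_threshold minimum call rates in (0, 1].
#' @return List with elements `geno` (filtered matrix) and `report` (a
#'   `qc_report`: counts, per-sample call rates, dropped ids with reasons).
#' @export
filter_call_rate <- function(geno, sample_threshold = 0.95, snp_threshold = 0.95) {
  if (sample_threshold <= 0 || sample_threshold > 1 ||
      snp_threshold <= 0 || snp_threshold > 1) {
    stop_abokit("call-rate thresholds must lie in (0, 1]")
  }
  dos <- geno$dosage
  n_input <- nrow(dos)
  sample_cr <- if (ncol(dos)) rowMeans(!is.na(dos)) else rep(1, n_input)
  keep_s <- sample_cr >= sample_threshold
  if (!any(keep_s)) stop_abokit("call-rate filter would remove every sample")
  dropped <- rownames(dos)[!keep_s]
  dos2 <- dos[keep_s, , drop = FALSE]
  snp_cr <- if (nrow(dos2)) colMeans(!is.na(dos2)) else rep(1, ncol(dos2))
  keep_v <- snp_cr >= snp_threshold
  out <- geno_matrix(dos2[, keep_v, drop = FALSE],
                     geno$snp_info[keep_v, , drop = FALSE])
  report <- structure(list(
    n_input = n_input,
    n_dropped_callrate = sum(!keep_s),
    n_dropped_relatedness = 0L,
    n_retained = sum(keep_s),
    n_snps_input = ncol(dos),
    n_snps_dropped = sum(!keep_v),
    sample_call_rate = setNames(sample_cr, rownames(dos)),
    dropped = data.frame(sample_id = dropped,
                         reason = rep("low_call_rate", length(dropped)),
                         stringsAsFactors = FALSE)),
    class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d in, %d dropped (call rate), %d dropped (relatedness), %d retained\n",
    x$n_input, x$n_dropped_callrate, x$n_dropped_relatedness, x$n_retained))
  invisible(x)
}

#' Method-of-moments identity-by-descent estimation
#'
#' PLINK-style IBS-to-IBD moment estimator: for each sample pair, observed
#' identity-by-state counts are combined with the expected IBS distribution
#' given allele frequencies to estimate P(IBD = 0, 1, 2), and
#' `pi-hat = P(IBD=2) + P(IBD=1)/2`, clamped to [0, 1]. Intended to run on
#' an approximately independent SNP set (the null background); warns below
#' 100 SNPs.
#'
#' @param geno a [geno_matrix()].
#' @param maf optional per-SNP allele-1 frequencies; estimated from the
#'   data when omitted.
#' @return Symmetric matrix of pi-hat values with sample-id dimnames.
#' @export
estimate_ibd <- function(geno, maf = NULL) {
  dos <- geno$dosage
  p <- maf %||% alt_freq(dos)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop_abokit("all SNPs are monomorphic; IBD undefined")
  dos <- dos[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(dos) < 100) {
    warning("fewer than 100 SNPs for IBD estimation; pi-hat will be noisy")
  }
  q <- 1 - p
  # expected per-SNP IBS probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- 2 * p * q
  e2_ibd1 <- 1 - e1_ibd1
  n <- nrow(dos)
  ids <- rownames(dos)
  obs <- (!is.na(dos)) * 1
  a0 <- (!is.na(dos) & dos == 0) * 1
  a1 <- (!is.na(dos) & dos == 1) * 1
  a2 <- (!is.na(dos) & dos == 2) * 1
  # pairwise IBS counts over jointly observed SNPs, by matrix products
  n_ibs0 <- a0 %*% t(a2) + a2 %*% t(a0)
  n_ibs1 <- a1 %*% t(a0 + a2) + (a0 + a2) %*% t(a1)
  m_obs <- obs %*% t(obs)
  n_ibs2 <- m_obs - n_ibs0 - n_ibs1
  # expected IBS counts conditional on IBD state, restricted per pair to
  # the jointly observed SNPs: S_ij = sum_k obs_ik obs_jk e_k
  esum <- function(e) obs %*% t(sweep(obs, 2, e, `*`))
  s0 <- esum(e0_ibd0); s1_0 <- esum(e1_ibd0); s2_0 <- esum(e2_ibd0)
  s1_1 <- esum(e1_ibd1); s2_1 <- esum(e2_ibd1)
  p0 <- ifelse(s0 > 0, n_ibs0 / s0, 0)
  p1 <- ifelse(s1_1 > 0, (n_ibs1 - p0 * s1_0) / s1_1, 0)
  p2 <- ifelse(m_obs > 0, (n_ibs2 - p0 * s2_0 - p1 * s2_1) / m_obs, 0)
  # only the final pi-hat is clamped; clamping the per-state
  # probabilities would rectify sampling noise into upward bias
  pihat <- pmin(pmax(p2 + 0.5 * p1, 0), 1)
  diag(pihat) <- 0
  dimnames(pihat) <- list(ids, ids)
  pihat
}

#' Greedy relatedness pruning
#'
#' While any retained pair exceeds the pi-hat threshold, drops the member
#' of the worst pair with the greater genotype missingness (ties broken by
#' the lexicographically larger sample id). Guarantees no retained pair
#' exceeds the threshold.
#'
#' @param pihat symmetric pi-hat matrix with sample-id dimnames.
#' @param threshold pi-hat cutoff in (0, 1); pairs at or above it are
#'   considered related. Default 0.1875, midway between the expectations
#'   for second- and third-degree relatives.
#' @param missingness optional named per-sample missingness fractions used
#'   for the drop rule (default all zero).
#' @return List with `keep` (retained sample ids) and `report`
#'   (`qc_report` with relatedness drop counts and reasons).
#' @export
prune_related <- function(pihat, threshold = 0.1875, missingness = NULL) {
  if (threshold <= 0 || threshold >= 1) stop_abokit("threshold must be in (0, 1)")
  ids <- rownames(pihat)
  miss <- missingness %||% setNames(rep(0, length(ids)), ids)
  active <- rep(TRUE, length(ids))
  names(active) <- ids
  dropped <- character(0)
  repeat {
    sub <- pihat[active, active, drop = FALSE]
    diag(sub) <- 0
    if (!length(sub) || max(sub) < threshold) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- rownames(sub)[w[1]]; b <- colnames(sub)[w[2]]
    victim <- if (miss[a] > miss[b]) a
              else if (miss[b] > miss[a]) b
              else max(a, b)
    active[victim] <- FALSE
    dropped <- c(dropped, victim)
  }
  report <- structure(list(
    n_input = length(ids),
    n_dropped_callrate = 0L,
    n_dropped_relatedness = length(dropped),
    n_retained = sum(active),
    sample_call_rate = NULL,
    dropped = data.frame(sample_id = dropped,
                         reason = rep("relatedness", length(dropped)),
                         stringsAsFactors = FALSE)),
    class = "qc_report")
  list(keep = ids[active], report = report)
}

# Window-free greedy LD pruning: walk SNPs in decreasing-MAF order, keep a
# SNP iff its dosage r2 with every already-kept SNP is below the threshold.
ld_prune_greedy <- function(dos, r2_threshold) {
  maf <- snp_maf(dos)
  ord <- order(-maf, colnames(dos))
  # mean-impute once and standardise so candidate-vs-kept correlations are
  # single matrix-vector products (missingness only feeds the PCA prep)
  cm <- colMeans(dos, na.rm = TRUE)
  X <- dos
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- cm[j]
  }
  sds <- apply(X, 2, sd)
  Z <- X
  ok_sd <- !is.na(sds) & sds > 0
  Z[, ok_sd] <- scale(X[, ok_sd, drop = FALSE])
  n <- nrow(Z)
  kept <- integer(0)
  for (j in ord) {
    if (!ok_sd[j]) next
    if (length(kept)) {
      r <- crossprod(Z[, kept, drop = FALSE], Z[, j]) / (n - 1)
      if (max(r^2, na.rm = TRUE) >= r2_threshold) next
    }
    kept <- c(kept, j)
  }
  sort(kept)
}

#' Principal components of the genotype matrix
#'
#' LD-prunes SNPs (greedy, MAF-ordered, window-free) at `ld_prune_r2`,
#' mean-imputes missing dosages, column-standardises, and eigendecomposes
#' the sample covariance. Components follow a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param geno a [geno_matrix()].
#' @param k number of components (default 10, the usual GWAS adjustment).
#' @param ld_prune_r2 r-squared threshold for pre-PCA pruning.
#' @return An object of class `pc_set`: `scores` (samples x k), `loadings`
#'   (SNPs x k), `explained` (variance fractions), `snp_ids` (SNPs used).
#' @export
compute_pcs <- function(geno, k = 10, ld_prune_r2 = 0.2) {
  dos <- geno$dosage
  kept <- ld_prune_greedy(dos, ld_prune_r2)
  dos <- dos[, kept, drop = FALSE]
  if (k > min(dim(dos))) {
    stop_abokit("k = %d exceeds min(samples, pruned SNPs) = %d", k, min(dim(dos)))
  }
  # mean-impute for PCA only; association fits never see imputed values
  cm <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos))) {
    nas <- is.na(dos[, j])
    if (any(nas)) dos[nas, j] <- cm[j]
  }
  sds <- apply(dos, 2, sd)
  use <- sds > 0
  x <- scale(dos[, use, drop = FALSE])
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(scores) <- list(rownames(geno$dosage), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  structure(list(scores = scores, loadings = loadings, explained = explained,
                 snp_ids = colnames(x)),
            class = "pc_set")
}

#' @export
print.pc_set <- function(x, ...) {
  cat(sprintf("pc_set: %d samples x %d PCs over %d SNPs; PC1 explains %.1f%%\n",
              nrow(x$scores), ncol(x$scores), length(x$snp_ids),
              100 * x$explained[1]))
  invisible(x)
}

#' One-stop cohort QC
#'
#' Call-rate filtering followed by IBD estimation on the null background
#' and greedy relatedness pruning; returns the QC'd genotypes, the merged
#' report and the retained sample ids.
#'
#' @param cohort an `abo_cohort`.
#' @param sample_threshold,snp_threshold call-rate cutoffs.
#' @param pihat_threshold relatedness cutoff.
#' @return List with `geno`, `samples` (filtered sample table), `report`,
#'   `pihat`.
#' @export
qc_cohort <- function(cohort, sample_threshold = 0.95, snp_threshold = 0.95,
                      pihat_threshold = 0.1875) {
  cr <- filter_call_rate(cohort$genotypes, sample_threshold, snp_threshold)
  null_ids <- cr$geno$snp_info$snp_id[cr$geno$snp_info$chrom != "9"]
  pihat <- estimate_ibd(subset_geno(cr$geno, snps = null_ids))
  miss <- rowMeans(is.na(cr$geno$dosage))
  pr <- prune_related(pihat, pihat_threshold, missingness = miss)
  geno <- subset_geno(cr$geno, samples = pr$keep)
  report <- cr$report
  report$n_dropped_relatedness <- pr$report$n_dropped_relatedness
  report$n_retained <- length(pr$keep)
  report$dropped <- rbind(cr$report$dropped, pr$report$dropped)
  samples <- cohort$samples[match(pr$keep, cohort$samples$sample_id), ,
                            drop = FALSE]
  rownames(samples) <- NULL
  list(geno = geno, samples = samples, report = report, pihat = pihat)
}
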