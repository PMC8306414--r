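#' Composite LD between two dosage vectors
#'
#' Squared Pearson correlation of genotype dosages (composite LD), the
#' standard unphased approximation to haplotype-level r-squared; the two
#' coincide in expectation under Hardy-Weinberg equilibrium.
#'
#' @param dosage_a,dosage_b aligned numeric dosage vectors; pairwise
#'   complete observations are used.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop_abokit("LD undefined: constant dosage vector")
  }
  stats::cor(a, b)^2
}

#' Pairwise LD matrix
#'
#' @param geno a [geno_matrix()] (or plain dosage matrix with SNP column
#'   names).
#' @return Object of class `ld_matrix`: symmetric r-squared matrix with
#'   unit diagonal and SNP-id dimnames. Pairs where LD is undefined
#'   (constant vector) are `NA`.
#' @export
ld_matrix <- function(geno) {
  dos <- if (inherits(geno, "geno_matrix")) geno$dosage else geno
  r <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Iterative LD-aware hit selection
#'
#' The greedy selection rule used after screening: walk the hits in
#' ascending-p order and accept a SNP iff its r-squared with every
#' already-selected SNP is below the threshold. Deterministic given the
#' hit ordering (see [screen_hits()] for the tie-breaks).
#'
#' @param hits association table sorted ascending by p (one row per SNP;
#'   if several contrasts are present, pre-filter to one).
#' @param ld an [ld_matrix()] covering every hit SNP.
#' @param r2_threshold LD cutoff (default 0.8): pairs at or above it are
#'   considered redundant.
#' @return Character vector of selected SNP ids, in acceptance order.
#' @export
iterative_select <- function(hits, ld, r2_threshold = 0.8) {
  snp_ids <- unique(hits$snp_id)
  missing <- setdiff(snp_ids, rownames(ld))
  if (length(missing)) {
    stop_abokit("SNP(s) missing from LD matrix: %s", paste(missing, collapse = ", "))
  }
  selected <- character(0)
  for (sid in snp_ids) {
    if (all(ld[sid, selected] < r2_threshold)) selected <- c(selected, sid)
  }
  selected
}

#' Common-tag replacement
#'
#' When two selected SNPs are themselves in high LD (each tagging the same
#' functional variant), a single candidate SNP in high LD with both — and
#' in low LD with every other selected SNP — replaces the pair. Among
#' eligible candidates the one with the larger `min(r2(X,Z), r2(Y,Z))`
#' wins; remaining ties go to the candidate with smaller p (if `hit_p`
#' given) then lexicographically smaller id.
#'
#' @param selected character vector of selected SNP ids.
#' @param candidates character vector of candidate replacement ids.
#' @param ld an [ld_matrix()] covering all of the above.
#' @param high_r2 LD level treated as "same signal" (default 0.9).
#' @param low_r2 LD level treated as independent (default 0.8).
#' @param hit_p optional named p-values for tie-breaking.
#' @return List with `selected` (revised vector) and `replacements`
#'   (data.frame log of pair -> tag substitutions; empty if none).
#' @export
find_common_tag <- function(selected, candidates, ld, high_r2 = 0.9,
                            low_r2 = 0.8, hit_p = NULL) {
  if (high_r2 < low_r2) stop_abokit("high_r2 must be >= low_r2")
  log_rows <- list()
  failed <- character(0)
  repeat {
    pair <- NULL
    for (i in seq_along(selected)) {
      for (j in seq_len(i - 1)) {
        key <- paste(sort(c(selected[i], selected[j])), collapse = "|")
        if (ld[selected[i], selected[j]] >= high_r2 && !(key %in% failed)) {
          pair <- c(selected[j], selected[i]); break
        }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) break
    x <- pair[1]; y <- pair[2]
    others <- setdiff(selected, pair)
    elig <- Filter(function(z) {
      z %in% rownames(ld) && !(z %in% selected) &&
        ld[x, z] >= high_r2 && ld[y, z] >= high_r2 &&
        (length(others) == 0 || all(ld[z, others] < low_r2))
    }, setdiff(candidates, selected))
    if (!length(elig)) {
      # no replacement possible for this pair: leave it, log, move on
      failed <- c(failed, paste(sort(c(x, y)), collapse = "|"))
      log_rows[[length(log_rows) + 1]] <-
        data.frame(snp_x = x, snp_y = y, replacement = NA_character_,
                   stringsAsFactors = FALSE)
      next
    }
    score <- vapply(elig, function(z) min(ld[x, z], ld[y, z]), numeric(1))
    best <- elig[score == max(score)]
    if (length(best) > 1 && !is.null(hit_p)) {
      pv <- hit_p[best]
      pv[is.na(pv)] <- Inf
      best <- best[pv == min(pv)]
    }
    best <- sort(unlist(best))[1]
    log_rows[[length(log_rows) + 1]] <-
      data.frame(snp_x = x, snp_y = y, replacement = best,
                 stringsAsFactors = FALSE)
    selected <- c(setdiff(selected, pair), best)
  }
  replacements <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(snp_x = character(0), snp_y = character(0),
               replacement = character(0), stringsAsFactors = FALSE)
  list(selected = selected, replacements = replacements)
}

#' Full instrument-selection pipeline
#'
#' Screens hits, takes the best p per SNP across contrasts, applies
#' [iterative_select()] and then [find_common_tag()] over all hit SNPs as
#' candidates.
#'
#' @param results scan table from [run_scan()].
#' @param geno a [geno_matrix()] providing dosages for LD.
#' @param alpha significance threshold for screening.
#' @param r2_threshold,high_r2,low_r2 LD thresholds.
#' @return List with `selected`, `hits`, `ld`, `replacements`.
#' @export
select_instruments <- function(results, geno, alpha = 5e-8, r2_threshold = 0.8,
                               high_r2 = 0.9, low_r2 = 0.8) {
  hits <- screen_hits(results, alpha)
  if (nrow(hits) == 0) {
    return(list(selected = character(0), hits = hits, ld = NULL,
                replacements = NULL))
  }
  # best row per SNP (table is already p-ordered)
  first <- hits[!duplicated(hits$snp_id), , drop = FALSE]
  ld <- ld_matrix(subset_geno(geno, snps = unique(first$snp_id)))
  sel <- iterative_select(first, ld, r2_threshold)
  pvals <- setNames(first$p, first$snp_id)
  rep_out <- find_common_tag(sel, first$snp_id, ld, high_r2, low_r2, hit_p = pvals)
  list(selected = rep_out$selected, hits = hits, ld = ld,
       replacements = rep_out$replacements)
}
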