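#' Genotype matrix container
#'
#' Holds minor/alternate-allele dosages (0/1/2, `NA` for missing) for a set
#' of samples at a set of biallelic SNPs, together with per-SNP metadata.
#' Dosages count copies of the `alt` allele as stored; association code
#' re-orients to the minor allele via [code_additive()].
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns. Row names
#'   are sample ids, column names SNP ids.
#' @param snp_info data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per column of `dosage`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, snp_info) {
  stopifnot(is.matrix(dosage))
  if (ncol(dosage) != nrow(snp_info)) {
    stop_abokit("dosage has %d SNP columns but snp_info has %d rows",
                ncol(dosage), nrow(snp_info))
  }
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(snp_info))
  if (length(missing_cols)) {
    stop_abokit("snp_info lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (ncol(dosage) > 0) {
    bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
    if (length(bad)) stop_abokit("dosages must be 0, 1, 2 or NA")
    colnames(dosage) <- snp_info$snp_id
  }
  snp_info <- as.data.frame(snp_info, stringsAsFactors = FALSE)
  rownames(snp_info) <- NULL
  structure(list(dosage = dosage, snp_info = snp_info), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              if (length(x$dosage)) 100 * mean(is.na(x$dosage)) else 0))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param geno a [geno_matrix()].
#' @param samples sample ids or row indices to keep (`NULL` = all).
#' @param snps SNP ids or column indices to keep (`NULL` = all).
#' @return A `geno_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  dos <- geno$dosage
  info <- geno$snp_info
  if (!is.null(samples)) dos <- dos[samples, , drop = FALSE]
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, info$snp_id) else snps
    if (anyNA(idx)) {
      stop_abokit("unknown SNP id(s): %s",
                  paste(snps[is.na(idx)], collapse = ", "))
    }
    dos <- dos[, idx, drop = FALSE]
    info <- info[idx, , drop = FALSE]
  }
  geno_matrix(dos, info)
}

#' Combine two genotype matrices over the same samples
#'
#' @param a,b `geno_matrix` objects with identical sample rows.
#' @return A `geno_matrix` with the SNP columns of both.
#' @export
cbind_geno <- function(a, b) {
  if (ncol(a$dosage) == 0) return(b)
  if (ncol(b$dosage) == 0) return(a)
  stopifnot(nrow(a$dosage) == nrow(b$dosage))
  cols <- union(names(a$snp_info), names(b$snp_info))
  pad <- function(df) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    df[, cols, drop = FALSE]
  }
  geno_matrix(cbind(a$dosage, b$dosage),
              rbind(pad(a$snp_info), pad(b$snp_info)))
}

# Alt-allele frequency per SNP from dosages, NA-aware.
alt_freq <- function(dosage) colMeans(dosage, na.rm = TRUE) / 2

# Minor-allele frequency per SNP.
snp_maf <- function(dosage) {
  f <- alt_freq(dosage)
  pmin(f, 1 - f)
}
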