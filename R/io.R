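#' Write genotypes to VCF v4.2
#'
#' Plain-text VCF with a single GT FORMAT field; dosage 0/1/2 becomes
#' `0/0`, `0/1`, `1/1` and missing becomes `./.`. Positions are 1-based.
#'
#' @param geno a [geno_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  info <- geno$snp_info
  dos <- geno$dosage
  gt <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=abokit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(nrow(info)), function(j) {
    calls <- ifelse(is.na(dos[, j]), "./.", gt[dos[, j] + 1L])
    paste(c(info$chrom[j], info$pos[j], info$snp_id[j], info$ref[j],
            info$alt[j], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from VCF or PLINK-style text
#'
#' VCF: parses the GT field, accepting phased (`|`) and unphased (`/`)
#' separators; `./.` becomes missing; multi-allelic records are rejected
#' with their line number. PLINK-style text (`plink_text`): a TSV with
#' columns `snp_id`, `chrom`, `pos`, `ref`, `alt` then one dosage column
#' per sample.
#'
#' @param path input file.
#' @param format `"vcf"` or `"plink_text"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_abokit("file not found: %s", path)
  if (format == "plink_text") return(read_plink_text(path))
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_abokit("%s: no #CHROM header line", path)
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10) stop_abokit("%s: VCF has no sample columns", path)
  sample_ids <- header[-(1:9)]
  body_idx <- seq(hdr + 1, length(lines))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  n_snps <- length(body_idx)
  dos <- matrix(NA_integer_, length(sample_ids), n_snps,
                dimnames = list(sample_ids, NULL))
  info <- data.frame(snp_id = character(n_snps), chrom = character(n_snps),
                     pos = integer(n_snps), ref = character(n_snps),
                     alt = character(n_snps), stringsAsFactors = FALSE)
  for (k in seq_len(n_snps)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      stop_abokit("%s line %d: %d fields, expected %d", path, ln, length(f),
                  length(header))
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      stop_abokit("%s line %d: multi-allelic record (%s) not supported",
                  path, ln, f[3])
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop_abokit("%s line %d: no GT in FORMAT", path, ln)
    calls <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[[`, "", gt_idx)
    alleles <- strsplit(calls, "[/|]")
    d <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      ai <- suppressWarnings(as.integer(a))
      if (anyNA(ai) || any(ai > 1)) return(-1L)
      sum(ai)
    }, integer(1))
    if (any(!is.na(d) & d < 0)) {
      stop_abokit("%s line %d: malformed or multi-allelic GT", path, ln)
    }
    dos[, k] <- d
    info$snp_id[k] <- f[3]; info$chrom[k] <- f[1]
    info$pos[k] <- as.integer(f[2]); info$ref[k] <- f[4]; info$alt[k] <- f[5]
  }
  geno_matrix(dos, info)
}

#' Write genotypes as PLINK-style text dosages
#'
#' @param geno a [geno_matrix()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_plink_text <- function(geno, path) {
  tab <- cbind(geno$snp_info[, c("snp_id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(geno$dosage)))
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

read_plink_text <- function(path) {
  tab <- data.table::fread(path, sep = "\t", na.strings = "NA",
                           data.table = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    stop_abokit("%s: PLINK-text table needs columns %s", path,
                paste(meta_cols, collapse = ", "))
  }
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  storage.mode(dos) <- "integer"
  info <- tab[, meta_cols]
  info$chrom <- as.character(info$chrom)
  geno_matrix(dos, info)
}

#' Write and read the phenotype table
#'
#' TSV with columns `sample_id`, `sex`, `age`, `abo`, `sbp`, `dbp` and
#' optionally `outcome`. On reading, `abo` values are validated against
#' `{O, A, B, AB}` and, when genotype sample ids are supplied, the two
#' sources are reconciled by id with mismatches reported.
#'
#' @param samples sample table (column `serotype` is written as `abo`).
#' @param path file path.
#' @return `path` invisibly (writer); list with `samples` and
#'   `reconciliation` (reader).
#' @export
write_phenotypes <- function(samples, path) {
  out <- samples
  names(out)[names(out) == "serotype"] <- "abo"
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @param geno_sample_ids optional genotype sample ids to reconcile with.
#' @export
read_phenotypes <- function(path, geno_sample_ids = NULL) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("sample_id", "abo") %in% names(tab))) {
    stop_abokit("%s: phenotype table needs at least sample_id and abo", path)
  }
  bad <- !(tab$abo %in% c("O", "A", "B", "AB"))
  if (any(bad)) {
    stop_abokit("%s: invalid abo value(s) '%s' at row(s) %s", path,
                paste(unique(tab$abo[bad]), collapse = ","),
                paste(which(bad), collapse = ","))
  }
  names(tab)[names(tab) == "abo"] <- "serotype"
  reconciliation <- NULL
  if (!is.null(geno_sample_ids)) {
    reconciliation <- list(
      pheno_only = setdiff(tab$sample_id, geno_sample_ids),
      geno_only = setdiff(geno_sample_ids, tab$sample_id))
    shared <- intersect(geno_sample_ids, tab$sample_id)
    tab <- tab[match(shared, tab$sample_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(samples = tab, reconciliation = reconciliation)
}

#' Flat key=value simulation config files
#'
#' Serialises the scalar fields of a [sim_config()] (allele frequencies,
#' cohort size, contaminant counts, seed, ...) to `key = value` lines and
#' back; every field keeps its default when absent from the file, so the
#' round trip is lossless for files the writer produced.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `path` invisibly (writer); a `sim_config` (reader).
#' @export
write_sim_config <- function(config, path) {
  kv <- c(
    n_samples = config$n_samples,
    freq_O = config$allele_sys$freqs[["O"]],
    freq_A = config$allele_sys$freqs[["A"]],
    freq_B = config$allele_sys$freqs[["B"]],
    n_null_snps = config$n_null_snps,
    null_maf_min = config$null_maf_range[1],
    null_maf_max = config$null_maf_range[2],
    typing_error_rate = config$typing_error_rate,
    n_duplicate_pairs = config$n_duplicate_pairs,
    n_sib_pairs = config$n_sib_pairs,
    missing_rate = config$missing_rate,
    n_low_callrate_samples = config$n_low_callrate_samples,
    low_callrate_missing_frac = config$low_callrate_missing_frac,
    rng_seed = config$rng_seed)
  writeLines(sprintf("%s = %.15g", names(kv), as.numeric(kv)), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  kv <- setNames(as.numeric(trimws(vapply(parts, `[[`, "", 2))),
                 trimws(vapply(parts, `[[`, "", 1)))
  g <- function(key, default) if (key %in% names(kv)) kv[[key]] else default
  asys <- allele_system(g("freq_O", 0.55), g("freq_A", 0.22), g("freq_B", 0.23))
  sim_config(
    n_samples = g("n_samples", 1008),
    allele_sys = asys,
    tag_specs = default_tag_specs(asys),
    n_null_snps = g("n_null_snps", 2000),
    null_maf_range = c(g("null_maf_min", 0.05), g("null_maf_max", 0.5)),
    typing_error_rate = g("typing_error_rate", 0),
    n_duplicate_pairs = g("n_duplicate_pairs", 40),
    n_sib_pairs = g("n_sib_pairs", 39),
    missing_rate = g("missing_rate", 0.002),
    n_low_callrate_samples = g("n_low_callrate_samples", 1),
    low_callrate_missing_frac = g("low_callrate_missing_frac", 0.10),
    rng_seed = g("rng_seed", 1))
}

#' Write cohort ground truth
#'
#' Diplotypes and injected relative pairs as TSVs, for downstream
#' validation of QC and prediction.
#'
#' @param cohort an `abo_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth_tables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$truth$diplotypes,
                     file.path(dir, "truth_diplotypes.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth$relatives,
                     file.path(dir, "truth_relatives.tsv"), sep = "\t")
  invisible(dir)
}
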