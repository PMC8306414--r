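# Shared fixture builders: everything is generated in code at test time.

# Clean study-style cohort: no typing error, no relatives, no missingness,
# three perfect tags (+ two redundant O tags unless trimmed).
clean_config <- function(n = 921, seed = 421, n_null = 0, tags = NULL,
                         ...) {
  asys <- allele_system()
  sim_config(n_samples = n, allele_sys = asys,
             tag_specs = tags %||% default_tag_specs(asys),
             n_null_snps = n_null, typing_error_rate = 0,
             n_duplicate_pairs = 0, n_sib_pairs = 0,
             missing_rate = 0, n_low_callrate_samples = 0,
             rng_seed = seed, ...)
}

three_tag_specs <- function() {
  list(tag_snp_spec("tagO", "O", target_r2 = 1),
       tag_snp_spec("tagA", "A", target_r2 = 1),
       tag_snp_spec("tagB", "B", target_r2 = 1))
}

# Minor-allele-coded dosages of the named tags from a cohort.
tag_dosages <- function(cohort, tags) {
  code_additive(subset_geno(cohort$genotypes, snps = tags))$dosage
}

# Plain geno_matrix from a dosage matrix (metadata filled with defaults).
quick_geno <- function(dos, chrom = "1") {
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("S%04d", seq_len(nrow(dos)))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("snp%03d", seq_len(ncol(dos)))
  geno_matrix(dos, data.frame(snp_id = colnames(dos), chrom = chrom,
                              pos = seq_len(ncol(dos)) * 1000L,
                              ref = "A", alt = "G", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
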