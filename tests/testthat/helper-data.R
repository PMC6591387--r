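# Small deterministic builders shared across the test files.

# a variant table with sensible defaults, overridable per column
tiny_variants <- function(n = 1, chrom = "1", pos = seq_len(n) * 100,
                          ref = "A", alt = "G", gene = "GENE1",
                          consequence = "missense", cadd_phred = 25,
                          ref_af = NA_real_, ref_ac = NA_real_,
                          call_rate = 1) {
  df <- data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    gene = rep_len(gene, n), consequence = rep_len(consequence, n),
    protein_change = paste0("p.Test", seq_len(n)),
    cadd_phred = rep_len(cadd_phred, n),
    ref_af = rep_len(ref_af, n), ref_ac = rep_len(ref_ac, n),
    call_rate = rep_len(call_rate, n),
    stringsAsFactors = FALSE
  )
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df[, c("chrom", "pos", "ref", "alt", "key", "gene", "consequence",
         "protein_change", "cadd_phred", "ref_af", "ref_ac", "call_rate")]
}

# dosage matrix from a vector/matrix, with default names matching
# tiny_variants()
tiny_gm <- function(dosages, variants, samples = NULL) {
  m <- as.matrix(dosages)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(m)))
  dimnames(m) <- list(samples, variants$key)
  m
}

# write a literal VCF for parser tests
write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# cohort design with the study layout scaled down
tiny_cohorts <- function(n_fam = 2, n_spor = 2, n_ctrl = 2) {
  cohort_design(
    c(sprintf("FAM%02d", seq_len(n_fam)), sprintf("SPO%02d", seq_len(n_spor)),
      sprintf("CTL%02d", seq_len(n_ctrl))),
    c(rep("MSFAM", n_fam), rep("MSS", n_spor), rep("CTRL", n_ctrl))
  )
}

# filtered analysis-ready pieces from a simulated dataset
sim_filtered <- function(cfg) {
  sim <- simulate_dataset(cfg)
  afs <- dataset_af(sim$genotypes)
  v <- prefilter_rare_protein_altering(filter_call_rate(sim$variants), afs)
  gm <- align_genotypes(sim$genotypes, v)
  list(variants = v, genotypes = gm, cohorts = sim$cohorts,
       panel = sim$panel, sim = sim)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration, the
# independent oracle for fisher_vs_reference()
fisher_p_enum <- function(a, b, c, d) {
  row1 <- a + b
  row2 <- c + d
  k <- a + c
  x <- max(0, k - row2):min(row1, k)
  probs <- dhyper(x, row1, row2, k)
  p_obs <- dhyper(a, row1, row2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
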