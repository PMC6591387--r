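# Pre-analysis variant filters: genotyping rate, dataset/reference MAF and
# protein-altering consequence. All filters act on the variant table and are
# order independent; align_genotypes() keeps the dosage matrix in step.

#' Per-variant call rate from a dosage matrix
#'
#' @param genotypes Samples x variants dosage matrix.
#' @return Named numeric vector, one minus the missing fraction per variant.
#' @export
variant_call_rates <- function(genotypes) {
  colMeans(!is.na(genotypes))
}

#' Per-variant alternate-allele frequency within the dataset
#'
#' Computed as alternate-allele count over `2 x` the number of genotyped
#' individuals; missing genotypes are excluded from the denominator.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @return Named numeric vector of within-dataset allele frequencies.
#' @export
dataset_af <- function(genotypes) {
  called <- colSums(!is.na(genotypes))
  ac <- colSums(genotypes, na.rm = TRUE)
  af <- ifelse(called > 0, ac / (2 * called), 0)
  setNames(af, colnames(genotypes))
}

#' Filter variants on genotyping rate
#'
#' Retains variants genotyped in strictly more than `threshold` of the
#' probands (computed over the full three-cohort sample set). The strict
#' inequality reads "over 95%" literally; pass a slightly smaller
#' threshold to make the boundary inclusive.
#'
#' @param variants Variant table with a populated `call_rate` column.
#' @param threshold Retention threshold in `(0, 1]`; default 0.95.
#' @return Filtered variant table.
#' @export
filter_call_rate <- function(variants, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]")
  }
  variants[!is.na(variants$call_rate) & variants$call_rate > threshold, ,
           drop = FALSE]
}

#' Filter to rare protein-altering variants
#'
#' Removes synonymous and non-coding variants and variants common in either
#' the reference database or the dataset itself: retained records satisfy
#' `consequence` protein altering, `ref_af <= max_af` (absent reference
#' frequency passes — database-absent variants are analysed throughout) and
#' `dataset_af <= max_af`.
#'
#' @param variants Annotated variant table.
#' @param dataset_af Named vector of within-dataset allele frequencies (see
#'   [dataset_af()]); names must cover the variant keys.
#' @param max_af Frequency ceiling, default 0.05.
#' @return Filtered variant table.
#' @export
prefilter_rare_protein_altering <- function(variants, dataset_af,
                                            max_af = 0.05) {
  af <- dataset_af[variants$key]
  if (any(is.na(af))) {
    stop("dataset_af is missing entries for: ",
         paste(utils::head(variants$key[is.na(af)]), collapse = ", "))
  }
  keep <- variants$consequence %in% rv_protein_altering() &
    (is.na(variants$ref_af) | variants$ref_af <= max_af) &
    af <= max_af
  variants[keep, , drop = FALSE]
}

#' Align a dosage matrix with a filtered variant table
#'
#' Drops genotype columns whose variant was removed and checks that every
#' retained variant still has a genotype column, so that matrix and record
#' key sets coincide after any filter sequence.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param variants Variant table.
#' @return The matrix restricted (and ordered) to `variants$key`.
#' @export
align_genotypes <- function(genotypes, variants) {
  missing <- setdiff(variants$key, colnames(genotypes))
  if (length(missing) > 0L) {
    stop("variants without genotype columns: ",
         paste(utils::head(missing), collapse = ", "))
  }
  genotypes[, variants$key, drop = FALSE]
}
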