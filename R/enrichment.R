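# Per-variant Fisher enrichment against a reference allele-frequency
# database, the two-stage enriched / population-specific classification, the
# database-absent chi-square, the haplotype-pooled replication test and the
# aggregate selected-allele frequency.

#' Reconstruct reference allele numbers from frequency/count pairs
#'
#' A reference database reports per-variant allele frequency (`ref_af`) and
#' allele count (`ref_ac`); the allele number follows as
#' `round(ref_ac / ref_af)`. Database-absent variants (both fields absent,
#' or `ref_ac = 0`) fall back to `default_an` with `ref_ac = 0`. The
#' default of 246,000 alleles is the value implied by printed
#' frequency/count pairs such as an allele count of 2 at frequency 8.1e-6.
#'
#' @param ref_af,ref_ac Numeric vectors (NA = absent).
#' @param default_an Allele number assumed for database-absent variants.
#' @return Data frame with columns `ref_ac` and `ref_an`.
#' @export
reconstruct_ref_an <- function(ref_af, ref_ac, default_an = 246000) {
  if (any(!is.na(ref_af) & ref_af == 0 & !is.na(ref_ac) & ref_ac > 0)) {
    stop("ref_af of 0 with a positive ref_ac is inconsistent")
  }
  present <- !is.na(ref_af) & !is.na(ref_ac) & ref_ac >= 1
  an <- ifelse(present, round(ref_ac / ref_af), default_an)
  ac <- ifelse(present, ref_ac, 0)
  data.frame(ref_ac = ac, ref_an = an)
}

#' Fisher exact test of cohort allele counts against the reference database
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[cohort_ac, cohort_an - cohort_ac], [ref_ac, ref_an - ref_ac]]`,
#' comparing the proportion of alternate alleles in a cohort with the
#' proportion in the reference database. The odds ratio is the conditional
#' maximum-likelihood estimate reported by [stats::fisher.test()].
#'
#' @param cohort_ac Alternate alleles observed in the cohort.
#' @param cohort_an Total cohort alleles (2 x cohort size).
#' @param ref_ac,ref_an Reference allele count and number (vectors recycle
#'   to the cohort length).
#' @param alternative Sidedness passed to [stats::fisher.test()];
#'   two-sided by default.
#' @return Data frame with columns `p_value` and `odds_ratio`.
#' @export
fisher_vs_reference <- function(cohort_ac, cohort_an, ref_ac, ref_an,
                                alternative = "two.sided") {
  n <- max(length(cohort_ac), length(ref_ac))
  cohort_ac <- rep_len(cohort_ac, n)
  cohort_an <- rep_len(cohort_an, n)
  ref_ac <- rep_len(ref_ac, n)
  ref_an <- rep_len(ref_an, n)
  if (any(cohort_ac > cohort_an)) {
    stop("cohort_ac exceeds cohort_an")
  }
  if (any(ref_ac > ref_an)) stop("ref_ac exceeds ref_an")
  out <- vapply(seq_len(n), function(i) {
    tab <- matrix(c(cohort_ac[i], cohort_an[i] - cohort_ac[i],
                    ref_ac[i], ref_an[i] - ref_ac[i]),
                  nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = alternative)
    c(ft$p.value, unname(ft$estimate))
  }, numeric(2))
  data.frame(p_value = out[1, ], odds_ratio = out[2, ])
}

#' Two-stage enrichment classification of a multi-proband variant
#'
#' Stage one compares the combined case-cohort allele proportion to the
#' reference database; stage two repeats the test for the control cohort to
#' eliminate populationally specific variants. A variant carried by fewer
#' than two case probands is `not_multiproband`; otherwise it is
#' `ms_enriched` when the case test attains `p < alpha` while the control
#' test does not, `population_specific` when the control test attains
#' `p < alpha`, and `neither` otherwise. The carrier threshold counts
#' probands, not alleles, so a single homozygote does not qualify alone.
#'
#' @param ms_ac,ms_an Case alternate-allele count and total alleles.
#' @param ctrl_ac,ctrl_an Control alternate-allele count and total alleles.
#' @param ref_ac,ref_an Reference counts, e.g. from [reconstruct_ref_an()].
#' @param ms_carriers Number of case probands carrying the variant;
#'   defaults to `ms_ac` (exact when all carriers are heterozygous).
#' @param alpha Nominal per-variant significance level, default 0.01.
#' @return Data frame with `p_case`, `p_ctrl`, `odds_ratio_case` and
#'   `classification` (factor with levels `ms_enriched`,
#'   `population_specific`, `neither`, `not_multiproband`).
#' @export
classify_two_stage <- function(ms_ac, ms_an, ctrl_ac, ctrl_an,
                               ref_ac, ref_an, ms_carriers = ms_ac,
                               alpha = 0.01) {
  case <- fisher_vs_reference(ms_ac, ms_an, ref_ac, ref_an)
  ctrl <- fisher_vs_reference(ctrl_ac, ctrl_an, ref_ac, ref_an)
  cls <- ifelse(ms_carriers < 2, "not_multiproband",
         ifelse(ctrl$p_value < alpha, "population_specific",
         ifelse(case$p_value < alpha, "ms_enriched", "neither")))
  data.frame(
    p_case = case$p_value,
    p_ctrl = ctrl$p_value,
    odds_ratio_case = case$odds_ratio,
    classification = factor(cls, levels = c("ms_enriched",
                                            "population_specific",
                                            "neither", "not_multiproband"))
  )
}

#' Per-variant enrichment report for a dataset
#'
#' Computes case/control allele counts and case carrier counts from the
#' genotype matrix, reconstructs the reference allele numbers, applies the
#' two-stage classification and flags selected variants.
#'
#' @param variants Annotated, filtered variant table.
#' @param genotypes Samples x variants dosage matrix.
#' @param cohorts Cohort design.
#' @param default_an Fallback reference allele number.
#' @param alpha Per-variant significance level.
#' @param criteria Selection criteria, see [selection_criteria()].
#' @return Data frame with one row per variant: annotation fields,
#'   reference counts, cohort counts, Fisher p-values, classification and
#'   the `selected` flag.
#' @export
variant_enrichment <- function(variants, genotypes, cohorts,
                               default_an = 246000, alpha = 0.01,
                               criteria = selection_criteria()) {
  gm <- align_genotypes(genotypes, variants)
  ms <- case_samples(cohorts, "MS_combined")
  ctrl <- control_samples(cohorts)
  ms_ac <- allele_counts_for(gm, ms)
  ctrl_ac <- allele_counts_for(gm, ctrl)
  ms_carriers <- colSums(gm[ms, , drop = FALSE] > 0, na.rm = TRUE)
  ref <- reconstruct_ref_an(variants$ref_af, variants$ref_ac, default_an)
  two_stage <- classify_two_stage(ms_ac, 2 * length(ms),
                                  ctrl_ac, 2 * length(ctrl),
                                  ref$ref_ac, ref$ref_an,
                                  ms_carriers = ms_carriers, alpha = alpha)
  data.frame(
    variants[, c("key", "gene", "protein_change", "consequence",
                 "cadd_phred", "ref_af")],
    ref_ac = ref$ref_ac, ref_an = ref$ref_an,
    ms_ac = as.numeric(ms_ac), ctrl_ac = as.numeric(ctrl_ac),
    ms_carriers = as.numeric(ms_carriers),
    two_stage,
    selected = as.logical(classify_selected(variants, criteria)),
    row.names = NULL
  )
}

#' Chi-square test for over-representation of database-absent variants
#'
#' Yates-corrected Pearson chi-square on the 2x2 table of database-absent
#' versus database-present variant counts in cases and controls, using the
#' total number of variants identified in each cohort as the background.
#' Counts are variant counts, not allele counts.
#'
#' @param n_absent_case,n_total_case Absent and total variant counts among
#'   cases.
#' @param n_absent_ctrl,n_total_ctrl Same for controls.
#' @return List with `statistic` and `p_value`.
#' @export
absent_variant_chisq <- function(n_absent_case, n_total_case,
                                 n_absent_ctrl, n_total_ctrl) {
  tab <- matrix(c(n_absent_case, n_total_case - n_absent_case,
                  n_absent_ctrl, n_total_ctrl - n_absent_ctrl),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent counts: absent exceeds total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a margin of the 2x2 table is zero; both cohorts need at least ",
         "one absent and one present variant to test over-representation")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Fisher test for a haplotype of perfectly co-occurring variants
#'
#' Variants observed in the same probands with (near) identical reference
#' frequencies can be treated as a single haplotype: one representative
#' count enters a single Fisher test rather than summing the per-variant
#' counts. The per-variant cohort and reference counts must therefore
#' agree; discordant counts raise an error asking for an explicit
#' representative.
#'
#' @param ms_ac Per-variant case haplotype/allele counts (one per pooled
#'   variant).
#' @param ms_an Total case alleles.
#' @param ref_ac Per-variant reference allele counts.
#' @param ref_an Reference allele number (scalar or per variant; must
#'   agree).
#' @param representative Optional list with elements `ms_ac` and `ref_ac`
#'   overriding the equal-count requirement.
#' @return Data frame with `p_value` and `odds_ratio` (one row).
#' @export
haplotype_pool_test <- function(ms_ac, ms_an, ref_ac, ref_an,
                                representative = NULL) {
  if (is.null(representative)) {
    if (length(unique(ms_ac)) > 1L || length(unique(ref_ac)) > 1L ||
        length(unique(ref_an)) > 1L) {
      stop("per-variant counts differ; the variants do not form a clean ",
           "haplotype - supply an explicit `representative` count")
    }
    representative <- list(ms_ac = ms_ac[1], ref_ac = ref_ac[1])
  }
  fisher_vs_reference(representative$ms_ac, ms_an,
                      representative$ref_ac, ref_an[1])
}

#' Aggregate allele frequency of the selected variants in one cohort
#'
#' Sums alternate alleles over the selected variants and divides by twice
#' the cohort size.
#'
#' @param allele_counts Per-variant alternate-allele counts for the cohort
#'   (already restricted to selected variants).
#' @param n_cohort Cohort size in individuals, `> 0`.
#' @return List with `exact` and `reported` (rounded to two decimals, the
#'   precision used in summary tables).
#' @export
aggregate_selected_frequency <- function(allele_counts, n_cohort) {
  if (n_cohort <= 0) stop("empty cohort")
  exact <- sum(allele_counts) / (2 * n_cohort)
  list(exact = exact, reported = round(exact, 2))
}
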