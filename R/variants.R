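# Domain vocabulary shared across modules.

#' Consequence classes recognised by the variant table
#'
#' `rv_consequences()` returns the controlled vocabulary for the
#' `consequence` column of a variant table; `rv_protein_altering()` returns
#' the subset that counts as protein altering (everything except synonymous
#' and non-coding classes). CADD-phred may be absent only for frameshift and
#' in-frame indel variants, which the scoring algorithm cannot assess.
#'
#' @return Character vector of consequence labels.
#' @export
rv_consequences <- function() {
  c("missense", "stop_gained", "stop_lost", "start_lost", "splice_site",
    "frameshift", "inframe_indel", "synonymous", "non_coding")
}

#' @rdname rv_consequences
#' @export
rv_protein_altering <- function() {
  setdiff(rv_consequences(), c("synonymous", "non_coding"))
}

# consequences for which an absent CADD-phred score is tolerated
cadd_optional_consequences <- function() c("frameshift", "inframe_indel")

#' Cohort labels used by the package
#'
#' Three cohorts are modelled: familial cases (`MSFAM`), sporadic cases
#' (`MSS`) and controls (`CTRL`). Case sets for two-group contrasts are
#' `MSFAM`, `MSS` or `MS_combined` (both case cohorts pooled).
#'
#' @return Character vector of cohort labels.
#' @export
rv_cohort_levels <- function() c("MSFAM", "MSS", "CTRL")

#' Build a variant key from locus and alleles
#'
#' Keys have the form `chrom_pos_ref_alt` and identify a biallelic variant
#' site throughout the package (genotype matrix columns, annotation joins,
#' report rows).
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings (`"-"` allowed for
#'   indel shorthand).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

# Required columns of a variant table. Annotation columns may be NA until
# join_annotations() has run.
variant_columns <- function() {
  c("chrom", "pos", "ref", "alt", "key", "gene", "consequence",
    "protein_change", "cadd_phred", "ref_af", "ref_ac", "call_rate")
}

#' Validate a variant table
#'
#' Checks the structural invariants of a variant table: required columns,
#' positive positions, unique keys, consequence vocabulary, CADD-phred
#' present for every consequence outside the frameshift/in-frame indel
#' exemption, and reference allele frequency/count consistency (a present
#' `ref_af` implies `ref_ac >= 1`; a database-absent variant is recorded
#' with `ref_ac` 0 or NA and `ref_af` NA).
#'
#' @param variants Data frame with the columns of [variant_columns()].
#' @param check_annotations If `TRUE`, enforce the annotation invariants
#'   (gene/consequence/CADD present); use `FALSE` for freshly read
#'   genotype records that have not been joined yet.
#' @return `variants`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_variants <- function(variants, check_annotations = TRUE) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(variant_columns(), names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0L) return(invisible(variants))
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant keys: ",
         paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "))
  }
  if (check_annotations) {
    known <- is.na(variants$consequence) |
      variants$consequence %in% rv_consequences()
    if (!all(known)) {
      stop("unknown consequence labels: ",
           paste(unique(variants$consequence[!known]), collapse = ", "))
    }
    needs_cadd <- !is.na(variants$consequence) &
      !(variants$consequence %in% cadd_optional_consequences())
    if (any(needs_cadd & is.na(variants$cadd_phred) & !is.na(variants$gene))) {
      bad <- variants$key[needs_cadd & is.na(variants$cadd_phred) &
                            !is.na(variants$gene)]
      stop("CADD-phred absent for non-indel consequence at: ",
           paste(bad, collapse = ", "))
    }
    af_present <- !is.na(variants$ref_af)
    if (any(af_present & (is.na(variants$ref_ac) | variants$ref_ac < 1))) {
      stop("ref_af present without a positive ref_ac")
    }
    if (any(!af_present & !is.na(variants$ref_ac) & variants$ref_ac > 0)) {
      stop("positive ref_ac without ref_af")
    }
  }
  invisible(variants)
}

#' Construct a cohort design
#'
#' Maps sample identifiers to the three cohort labels and validates that the
#' labels are exhaustive.
#'
#' @param sample_id Character vector of unique proband identifiers.
#' @param cohort Character vector of labels in [rv_cohort_levels()].
#' @return Data frame with columns `sample_id` and `cohort` (class
#'   `rv_cohorts`).
#' @export
cohort_design <- function(sample_id, cohort) {
  if (length(sample_id) != length(cohort)) {
    stop("sample_id and cohort must have equal length")
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample identifiers")
  bad <- setdiff(unique(cohort), rv_cohort_levels())
  if (length(bad) > 0L) {
    stop("unknown cohort labels: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    cohort = as.character(cohort),
                    stringsAsFactors = FALSE)
  class(out) <- c("rv_cohorts", "data.frame")
  out
}

#' Cohort sizes, including the combined case cohort
#'
#' @param cohorts A cohort design from [cohort_design()].
#' @return Named numeric vector with `MSFAM`, `MSS`, `CTRL` and
#'   `MS_combined` counts.
#' @export
cohort_sizes <- function(cohorts) {
  n <- vapply(rv_cohort_levels(),
              function(l) sum(cohorts$cohort == l), numeric(1))
  c(n, MS_combined = unname(n[["MSFAM"]] + n[["MSS"]]))
}

#' Sample identifiers belonging to a case set or the control cohort
#'
#' @param cohorts A cohort design.
#' @param case_set One of `"MSFAM"`, `"MSS"`, `"MS_combined"`.
#' @return Character vector of sample identifiers.
#' @export
case_samples <- function(cohorts, case_set = "MS_combined") {
  case_set <- match.arg(case_set, c("MSFAM", "MSS", "MS_combined"))
  labels <- if (case_set == "MS_combined") c("MSFAM", "MSS") else case_set
  cohorts$sample_id[cohorts$cohort %in% labels]
}

#' @rdname case_samples
#' @export
control_samples <- function(cohorts) {
  cohorts$sample_id[cohorts$cohort == "CTRL"]
}

#' Construct a gene panel
#'
#' @param genes Character vector of gene symbols; duplicates are an error.
#' @param name Panel name used in reports.
#' @return List with elements `name` and `genes` (class `rv_gene_panel`).
#' @export
gene_panel <- function(genes, name = "panel") {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene panel contains duplicate symbols")
  structure(list(name = name, genes = genes), class = "rv_gene_panel")
}

#' @export
print.rv_gene_panel <- function(x, ...) {
  cat("<rv_gene_panel>", x$name, "with", length(x$genes), "genes\n")
  invisible(x)
}

panel_gene_set <- function(panel) {
  if (inherits(panel, "rv_gene_panel")) panel$genes else as.character(panel)
}
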