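# Readers and writers for the standard inputs: multi-sample VCF, annotation
# TSV, BED capture regions, cohort assignment TSV and gene panel TSV.

gt_dosage_lookup <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
                      "./." = NA_real_, "." = NA_real_,
                      "0/." = NA_real_, "./0" = NA_real_,
                      "1/." = NA_real_, "./1" = NA_real_,
                      "0" = 0, "1" = 1)

#' Read a multi-sample VCF into a dosage matrix and variant records
#'
#' Reads a VCF (v4.2 subset; only the GT format field is required) and
#' returns alternate-allele dosages per sample and site. Sites must be
#' biallelic: a multiallelic ALT is an error rather than being silently
#' split. Missing genotypes (`./.`) become `NA` and feed the per-variant
#' call rate.
#'
#' @param vcf_path Path to a VCF file.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples returned.
#' @return List with `genotypes` (samples x variants numeric matrix of
#'   dosages in `{0,1,2,NA}`, columns named by variant key) and `variants`
#'   (a variant table with annotation columns still `NA`; `call_rate` is
#'   filled from the matrix).
#' @export
read_genotypes <- function(vcf_path, samples = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multiallelic ALT alleles are not supported; split or reject upstream: ",
         paste(utils::head(fix[grepl(",", alt, fixed = TRUE), "POS"]), collapse = ", "))
  }
  keys <- variant_key(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], alt)
  if (anyDuplicated(keys)) {
    stop("duplicate variant records in VCF: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(keys))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  known <- gt %in% names(gt_dosage_lookup) | is.na(gt)
  if (!all(known)) {
    stop("unparseable GT values: ",
         paste(unique(gt[!known]), collapse = ", "))
  }
  dos <- matrix(gt_dosage_lookup[gt], nrow = nrow(gt))
  dimnames(dos) <- list(keys, colnames(vcf@gt)[-1])
  dos <- t(dos)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(dos))
    if (length(missing) > 0L) {
      stop("samples absent from VCF: ", paste(missing, collapse = ", "))
    }
    dos <- dos[samples, , drop = FALSE]
  }
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    key = keys,
    gene = NA_character_,
    consequence = NA_character_,
    protein_change = NA_character_,
    cadd_phred = NA_real_,
    ref_af = NA_real_,
    ref_ac = NA_real_,
    call_rate = colMeans(!is.na(dos)),
    stringsAsFactors = FALSE
  )
  rownames(variants) <- NULL
  validate_variants(variants, check_annotations = FALSE)
  list(genotypes = dos, variants = variants)
}

#' Write a dosage matrix as a minimal VCF v4.2 file
#'
#' Inverse of [read_genotypes()] for round-tripping simulated cohorts:
#' dosages 0/1/2 become `0/0`, `0/1`, `1/1` and `NA` becomes `./.`.
#'
#' @param genotypes Samples x variants dosage matrix with variant keys as
#'   column names.
#' @param variants Variant table aligned with the matrix columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, variants, path) {
  stopifnot(identical(colnames(genotypes), variants$key))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  gt <- matrix(gt_code[genotypes + 1L], nrow = nrow(genotypes))
  gt[is.na(genotypes)] <- "./."
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Join a variant annotation table onto genotype records
#'
#' The annotation source is a TSV (or an equivalent data frame) keyed by
#' `(chrom, pos, ref, alt)` with columns `gene`, `consequence`,
#' `protein_change`, `cadd_phred`, `ref_af`, `ref_ac`; empty cells mean
#' absent. Records without a matching annotation row are retained with all
#' annotation fields absent and reported in a warning.
#'
#' @param variants Variant table from [read_genotypes()].
#' @param annotations Path to the annotation TSV, or a data frame with the
#'   same columns.
#' @return The variant table with annotation columns populated.
#' @export
join_annotations <- function(variants, annotations) {
  ann <- if (is.data.frame(annotations)) {
    annotations
  } else {
    read.delim(annotations, stringsAsFactors = FALSE,
               colClasses = list(chrom = "character", ref = "character",
                                 alt = "character"))
  }
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "protein_change", "cadd_phred", "ref_af", "ref_ac")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("cadd_phred", "ref_af", "ref_ac")) {
    val <- ann[[col]]
    if (is.character(val)) {
      val[val == ""] <- NA
      num <- suppressWarnings(as.numeric(val))
      if (any(!is.na(val) & is.na(num))) {
        stop("non-numeric values in annotation column ", col, ": ",
             paste(unique(val[!is.na(val) & is.na(num)]), collapse = ", "))
      }
      ann[[col]] <- num
    }
  }
  ann_key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann_key)) {
    stop("annotation key collision: ",
         paste(unique(ann_key[duplicated(ann_key)]), collapse = ", "))
  }
  idx <- match(variants$key, ann_key)
  unmatched <- variants$key[is.na(idx)]
  if (length(unmatched) > 0L) {
    warning(length(unmatched), " variant(s) had no annotation row: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) " ...")
  }
  for (col in c("gene", "consequence", "protein_change",
                "cadd_phred", "ref_af", "ref_ac")) {
    variants[[col]] <- ann[[col]][idx]
  }
  validate_variants(variants)
  variants
}

#' Keep only variants inside the intersection of capture regions
#'
#' Restricts a variant table to the positions captured by every kit, i.e.
#' to loci inside all supplied BED interval sets. BED files are 0-based
#' half-open; variant positions are 1-based (conversion handled by the BED
#' importer).
#'
#' @param variants Variant table.
#' @param bed_paths Character vector of one or more BED3 file paths.
#' @return The subset of `variants` present in every BED file; an empty
#'   intersection produces an empty table and a warning, not an error.
#' @export
intersect_captured <- function(variants, bed_paths) {
  if (length(bed_paths) < 1L) stop("at least one BED file is required")
  pos_gr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  keep <- rep(TRUE, nrow(variants))
  for (bed in bed_paths) {
    gr <- rtracklayer::import(bed, format = "BED")
    keep <- keep & suppressWarnings(
      IRanges::overlapsAny(pos_gr, gr)
    )
  }
  if (!any(keep) && nrow(variants) > 0L) {
    warning("no variants fall inside the capture intersection")
  }
  variants[keep, , drop = FALSE]
}

#' Read a cohort assignment TSV
#'
#' Expects columns `sample_id` and `cohort`.
#'
#' @param path TSV path.
#' @return A cohort design (see [cohort_design()]).
#' @export
read_cohorts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(tab))) {
    stop("cohort table needs columns sample_id, cohort")
  }
  cohort_design(tab$sample_id, tab$cohort)
}

#' Read a gene panel TSV
#'
#' Expects a column `gene` (one symbol per row).
#'
#' @param path TSV path.
#' @param name Panel name.
#' @return An `rv_gene_panel`.
#' @export
read_panel <- function(path, name = basename(path)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab)) stop("panel table needs a 'gene' column")
  gene_panel(tab$gene, name = name)
}
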