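# Loaders for the packaged reference tables: the 62-gene inflammasome
# regulation panel and the printed selected / enriched variant tables
# (transcribed to TSV under inst/extdata).

fixture_path <- function(file) {
  system.file("extdata", file, package = "rvburden", mustWork = TRUE)
}

split_hg19_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             ref = vapply(parts, `[`, "", 3L),
             alt = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' The 62-gene inflammasome regulation panel
#'
#' Genes coding for the essential NLRP1/NLRP3 inflammasome constituents
#' (NLRP1, NLRP3, PYCARD, CASP1) and the regulators of inflammasome
#' priming, sequestration, post-translational modification /
#' auto-mitophagy and the associated protein tyrosine phosphatases.
#'
#' @return An `rv_gene_panel` with 62 genes.
#' @export
panel_genes <- function() {
  read_panel(fixture_path("panel_62_genes.tsv"),
             name = "inflammasome_regulation_62")
}

# shared fixture parsing: split the hg19 key and coerce to the variant
# table layout, keeping the cohort count columns alongside
load_variant_fixture <- function(file, extra_cols) {
  tab <- read.delim(fixture_path(file), stringsAsFactors = FALSE)
  locus <- split_hg19_key(tab$hg19)
  out <- data.frame(
    locus,
    key = tab$hg19,
    gene = tab$gene,
    consequence = tab$consequence,
    protein_change = tab$protein_change,
    cadd_phred = as.numeric(tab$cadd_phred),
    ref_af = as.numeric(tab$ref_af),
    ref_ac = as.numeric(tab$ref_ac),
    call_rate = 1,
    tab[, extra_cols, drop = FALSE],
    stringsAsFactors = FALSE
  )
  validate_variants(out)
  out
}

#' Selected-variant reference table
#'
#' The 29 prioritised variants (effective reference MAF below 1e-5, CADD
#' above 20 or frameshift) with their reference allele frequency/count
#' (`ref_af`/`ref_ac`), CADD-phred, combined-case (`ms_ac`, n = 175) and
#' control (`ctrl_ac`, n = 144) alternate-allele counts, and the
#' `ms_enriched` flag marking the two variants that also met the
#' multi-proband enrichment criteria. All rows are heterozygous carriers.
#'
#' @return Data frame with one row per selected variant.
#' @export
selected_variants <- function() {
  load_variant_fixture("selected_variants.tsv",
                       c("ms_ac", "ctrl_ac", "ms_enriched"))
}

#' Enriched-variant reference table
#'
#' The 15 additional multi-proband variants meeting the enrichment
#' criteria (the two that were also selected live in
#' [selected_variants()]). Total allele counts are split from the
#' homozygote-contributed alleles, which the source reports in brackets:
#' `*_ac` columns are totals, `*_ac_hom` the part contributed by
#' homozygous probands.
#'
#' @return Data frame with one row per enriched variant.
#' @export
enriched_variants <- function() {
  load_variant_fixture("enriched_variants.tsv",
                       c("ref_ac_hom", "ms_ac", "ms_ac_hom",
                         "ctrl_ac", "ctrl_ac_hom"))
}
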