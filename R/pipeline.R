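# End-to-end orchestration: filters -> burden contrasts -> cutoff sweeps ->
# gene-panel Monte Carlo null -> per-variant enrichment, with TSV/JSON
# reports and a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold in one validated
#' list. Thresholds default to the package's standard analysis: call rate
#' over 0.95, MAF at most 0.05 in reference and dataset, selection at
#' (MAF < 1e-5, CADD > 20), burden family alpha 0.01 over three contrasts,
#' per-variant Fisher alpha 0.01 and a reference allele number of 246,000.
#'
#' @param vcf,annotations,cohorts,panel Input file paths (see
#'   [read_genotypes()], [join_annotations()], [read_cohorts()],
#'   [read_panel()]).
#' @param bed Optional character vector of capture BED paths.
#' @param out_dir Report directory.
#' @param call_rate_threshold,max_af Filter thresholds.
#' @param maf_cut,cadd_cut Selection criteria.
#' @param n_cutoffs,maf_range,cadd_range Sweep grid specification.
#' @param n_random_panels Panels for the Monte Carlo null.
#' @param n_permutations Permutations when `burden_method` is
#'   `"permutation"`.
#' @param burden_method `"score"` or `"permutation"`.
#' @param burden_alpha Family-wise alpha over the three burden contrasts.
#' @param variant_alpha Per-variant Fisher alpha.
#' @param default_an Reference allele number for database-absent variants.
#' @param seed Integer seed for every stochastic stage.
#' @return List of class `rv_run_config`.
#' @export
run_config <- function(vcf, annotations, cohorts, panel, bed = NULL,
                       out_dir = "rvburden_run",
                       call_rate_threshold = 0.95, max_af = 0.05,
                       maf_cut = 1e-5, cadd_cut = 20,
                       n_cutoffs = 300, maf_range = c(1e-6, 0.05),
                       cadd_range = c(0, 40),
                       n_random_panels = 100000, n_permutations = 10000,
                       burden_method = "score",
                       burden_alpha = 0.01, variant_alpha = 0.01,
                       default_an = 246000, seed = 1) {
  cfg <- list(vcf = vcf, annotations = annotations, cohorts = cohorts,
              panel = panel, bed = bed, out_dir = out_dir,
              call_rate_threshold = call_rate_threshold, max_af = max_af,
              maf_cut = maf_cut, cadd_cut = cadd_cut,
              n_cutoffs = n_cutoffs, maf_range = maf_range,
              cadd_range = cadd_range,
              n_random_panels = n_random_panels,
              n_permutations = n_permutations,
              burden_method = match.arg(burden_method,
                                        c("score", "permutation")),
              burden_alpha = burden_alpha, variant_alpha = variant_alpha,
              default_an = default_an, seed = as.integer(seed))
  stopifnot(cfg$call_rate_threshold > 0, cfg$call_rate_threshold <= 1,
            cfg$max_af > 0, cfg$max_af <= 1,
            cfg$burden_alpha > 0, cfg$burden_alpha < 1,
            cfg$variant_alpha > 0, cfg$variant_alpha < 1,
            length(cfg$seed) == 1L, !is.na(cfg$seed))
  class(cfg) <- "rv_run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return An `rv_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (k in c("maf_range", "cadd_range")) {
    if (!is.null(vals[[k]])) vals[[k]] <- as.numeric(unlist(vals[[k]]))
  }
  if (!is.null(vals$bed)) vals$bed <- as.character(unlist(vals$bed))
  do.call(run_config, vals)
}

pipeline_log <- function(...) message("[rvburden] ", ...)

#' Run the full analysis pipeline
#'
#' Executes, in order: genotype/annotation loading, capture intersection,
#' call-rate filter, rare protein-altering prefilter, the three burden
#' contrasts (familial, sporadic and combined cases against controls,
#' judged against the Bonferroni-corrected family threshold), the MAF and
#' CADD burden sweeps, the gene-panel Monte Carlo null on both axes, and
#' the per-variant enrichment classification. Reports (TSV/JSON) and a
#' manifest recording the configuration, seed, package version and the
#' per-filter variant ledger are written under `config$out_dir`.
#'
#' @param config An [run_config()] object.
#' @return List with the in-memory results (`variants`, `burden`,
#'   `sweeps`, `panel_null`, `enrichment`, `filter_ledger`, `manifest`),
#'   invisibly writable via the report files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rv_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pipeline_log("reading genotypes from ", config$vcf)
  geno <- read_genotypes(config$vcf)
  variants <- join_annotations(geno$variants, config$annotations)
  cohorts <- read_cohorts(config$cohorts)
  panel <- if (inherits(config$panel, "rv_gene_panel")) config$panel
           else read_panel(config$panel)
  gm <- geno$genotypes[cohorts$sample_id, , drop = FALSE]
  variants$call_rate <- unname(variant_call_rates(gm))
  ledger <- c(input = nrow(variants))

  if (!is.null(config$bed)) {
    variants <- intersect_captured(variants, config$bed)
  }
  ledger <- c(ledger, captured = nrow(variants))
  variants <- filter_call_rate(variants, config$call_rate_threshold)
  ledger <- c(ledger, call_rate = nrow(variants))
  afs <- dataset_af(gm)
  variants <- prefilter_rare_protein_altering(variants, afs, config$max_af)
  ledger <- c(ledger, rare_protein_altering = nrow(variants))
  pipeline_log("retained ", nrow(variants), " of ", ledger[["input"]],
               " variants after filtering")
  if (nrow(variants) == 0L) stop("no variants survive the filters")
  gm <- align_genotypes(gm, variants)

  threshold <- bonferroni_threshold(config$burden_alpha, 3)
  contrasts <- c("MSFAM", "MSS", "MS_combined")
  burden <- lapply(setNames(contrasts, contrasts), function(cs) {
    res <- burden_test(gm, variants, cohorts, panel, case_set = cs,
                       method = config$burden_method,
                       n_perm = config$n_permutations, seed = config$seed)
    pipeline_log("burden ", cs, ": p = ", signif(res$p_value, 3))
    list(case_set = cs, statistic = res$statistic, p_value = res$p_value,
         method = res$method, n_variants = res$n_variants,
         significant = res$p_value < threshold$reported)
  })

  criteria <- selection_criteria(config$maf_cut, config$cadd_cut)
  sweeps <- list(
    maf = sweep_burden(variants, gm, cohorts, "maf", "MS_combined",
                       config$n_cutoffs, config$maf_range,
                       config$cadd_range),
    cadd = sweep_burden(variants, gm, cohorts, "cadd", "MS_combined",
                        config$n_cutoffs, config$maf_range,
                        config$cadd_range)
  )
  null_tests <- lapply(setNames(c("maf", "cadd"), c("maf", "cadd")),
    function(ax) {
      res <- panel_null_test(variants, gm, cohorts, panel, axis = ax,
                             n_panels = config$n_random_panels,
                             seed = config$seed,
                             n_cutoffs = config$n_cutoffs,
                             maf_range = config$maf_range,
                             cadd_range = config$cadd_range)
      pipeline_log("panel null (", ax, "): p = ", signif(res$p_value, 3))
      res
    })

  # selection and enrichment are reported for the panel, as in the
  # candidate-gene analysis the pipeline reproduces
  panel_variants <- variants[!is.na(variants$gene) &
                               variants$gene %in% panel_gene_set(panel), ,
                             drop = FALSE]
  enrichment <- variant_enrichment(panel_variants, gm, cohorts,
                                   default_an = config$default_an,
                                   alpha = config$variant_alpha,
                                   criteria = criteria)
  sizes <- cohort_sizes(cohorts)
  sel <- enrichment$selected
  freq <- list(
    ms = aggregate_selected_frequency(enrichment$ms_ac[sel],
                                      sizes[["MS_combined"]]),
    ctrl = aggregate_selected_frequency(enrichment$ctrl_ac[sel],
                                        sizes[["CTRL"]])
  )

  manifest <- list(
    package_version = as.character(packageVersion("rvburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    filter_ledger = as.list(ledger),
    cohort_sizes = as.list(sizes),
    bonferroni = threshold
  )

  out <- config$out_dir
  write.table(variants, file.path(out, "variants_filtered.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(threshold = threshold, contrasts = burden),
    file.path(out, "burden.json"), auto_unbox = TRUE, digits = NA)
  for (ax in names(sweeps)) {
    write.table(sweeps[[ax]], file.path(out, paste0("sweep_", ax, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(null_tests, function(x) {
      x <- unclass(x)
      x$null_slopes <- NULL  # full dump omitted from the summary report
      x
    }),
    file.path(out, "panel_null.json"), auto_unbox = TRUE, digits = NA)
  write.table(enrichment, file.path(out, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(selected_frequency = freq),
    file.path(out, "selected_frequency.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(variants = variants, burden = burden, sweeps = sweeps,
                 panel_null = null_tests, enrichment = enrichment,
                 selected_frequency = freq, filter_ledger = ledger,
                 manifest = manifest))
}
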