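# Seeded synthetic-data generator: a reference allele-frequency database
# (gnomAD-like allele counts over a fixed allele number) and three-cohort
# case/control genotypes with an optional enrichment effect planted in a
# designated gene panel at the rare / high-CADD end.

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the study conditions the package is designed
#' around: 86 familial cases, 89 sporadic cases and 144 controls; a site
#' frequency spectrum dominated by exceedingly rare alleles (a point mass
#' of ultra-rare, mostly database-absent sites plus a log-uniform component
#' up to MAF 0.05); a reference database of 246,000 alleles; per-consequence
#' CADD-phred distributions with frameshift and in-frame indels unscored;
#' and a multiplicative case-enrichment factor confined to panel variants
#' below `maf_enrich_cut` with CADD above `cadd_enrich_cut` (frameshifts,
#' being unscored, count as damaging). `enrichment = 1` is the null.
#'
#' The spectrum is a pragmatic mixture, not a population-genetic site
#' frequency spectrum: it is sufficient to exercise the statistics. Site
#' counts are per *possible* site; sites with no alternate allele in the
#' cohort are dropped by default (`drop_unobserved`), as in a real
#' variant-calling output, so the number of observed variants is far
#' smaller than `n_genes * n_variants_per_gene`.
#'
#' @param n_fam_cases,n_sporadic_cases,n_controls Cohort sizes.
#' @param n_genes Genes in the simulated exome.
#' @param panel_size Genes in the designated panel (the first
#'   `panel_size` gene symbols).
#' @param n_variants_per_gene Mean number of candidate sites per gene
#'   (Poisson).
#' @param p_ultra_rare Mixture weight of the ultra-rare point mass.
#' @param ultra_rare_maf True MAF of point-mass sites.
#' @param maf_range Bounds of the log-uniform MAF component.
#' @param reference_an Reference-database allele number.
#' @param consequence_probs Named sampling probabilities over
#'   [rv_consequences()].
#' @param cadd_mean,cadd_sd Named per-consequence normal CADD-phred
#'   parameters (truncated at 0); consequences missing from `cadd_mean`
#'   are left unscored.
#' @param enrichment Multiplicative case odds factor (`>= 1`) applied to
#'   qualifying panel variants; case MAF is capped at 0.5.
#' @param maf_enrich_cut,cadd_enrich_cut Cuts defining which panel
#'   variants carry the planted effect.
#' @param missing_rate Per-genotype missingness probability.
#' @param drop_unobserved Drop sites with no alternate allele in the
#'   cohort.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return List of class `rv_sim_config`.
#' @export
sim_config <- function(n_fam_cases = 86, n_sporadic_cases = 89,
                       n_controls = 144,
                       n_genes = 1000, panel_size = 62,
                       n_variants_per_gene = 60,
                       p_ultra_rare = 0.6, ultra_rare_maf = 8e-6,
                       maf_range = c(1e-6, 0.05),
                       reference_an = 246000,
                       consequence_probs = c(
                         missense = 0.62, synonymous = 0.15,
                         stop_gained = 0.04, stop_lost = 0.01,
                         start_lost = 0.01, splice_site = 0.05,
                         frameshift = 0.06, inframe_indel = 0.03,
                         non_coding = 0.03),
                       cadd_mean = c(missense = 15, stop_gained = 36,
                                     stop_lost = 32, start_lost = 22,
                                     splice_site = 24, synonymous = 6,
                                     non_coding = 3),
                       cadd_sd = c(missense = 7, stop_gained = 4,
                                   stop_lost = 5, start_lost = 6,
                                   splice_site = 8, synonymous = 4,
                                   non_coding = 3),
                       enrichment = 1, maf_enrich_cut = 1e-4,
                       cadd_enrich_cut = 20,
                       missing_rate = 0.003, drop_unobserved = TRUE,
                       seed = 1) {
  stopifnot(panel_size <= n_genes, enrichment >= 1,
            missing_rate >= 0, missing_rate < 1,
            p_ultra_rare >= 0, p_ultra_rare <= 1,
            maf_range[1] > 0, maf_range[1] < maf_range[2],
            reference_an > 0)
  bad <- setdiff(names(consequence_probs), rv_consequences())
  if (length(bad) > 0L) stop("unknown consequences: ",
                             paste(bad, collapse = ", "))
  structure(list(
    n_fam_cases = n_fam_cases, n_sporadic_cases = n_sporadic_cases,
    n_controls = n_controls, n_genes = n_genes, panel_size = panel_size,
    n_variants_per_gene = n_variants_per_gene,
    p_ultra_rare = p_ultra_rare, ultra_rare_maf = ultra_rare_maf,
    maf_range = maf_range, reference_an = reference_an,
    consequence_probs = consequence_probs,
    cadd_mean = cadd_mean, cadd_sd = cadd_sd,
    enrichment = enrichment, maf_enrich_cut = maf_enrich_cut,
    cadd_enrich_cut = cadd_enrich_cut,
    missing_rate = missing_rate, drop_unobserved = drop_unobserved,
    seed = as.integer(seed)), class = "rv_sim_config")
}

#' Gene symbols and designated panel of a simulation
#'
#' @param config An `rv_sim_config`.
#' @return `sim_genes()`: all gene symbols; `sim_panel()`: the designated
#'   panel as an `rv_gene_panel`.
#' @export
sim_genes <- function(config) sprintf("G%04d", seq_len(config$n_genes))

#' @rdname sim_genes
#' @export
sim_panel <- function(config) {
  gene_panel(sim_genes(config)[seq_len(config$panel_size)],
             name = "simulated_panel")
}

#' Simulate a reference allele-frequency database
#'
#' Draws one true population MAF per candidate site from the configured
#' mixture, then draws the reference allele count binomially with
#' `reference_an` trials; `ref_af = ref_ac / reference_an`, and sites with
#' `ref_ac = 0` are recorded as database absent (`ref_af` NA, `ref_ac` 0).
#' CADD-phred is drawn per consequence; frameshift and in-frame indel
#' sites are left unscored.
#'
#' @param config An [sim_config()] object.
#' @return Variant table with an extra `true_maf` column (the simulation
#'   truth, which downstream analysis never sees).
#' @export
simulate_reference_db <- function(config) {
  set.seed(config$seed)
  genes <- sim_genes(config)
  n_sites <- rpois(config$n_genes, config$n_variants_per_gene)
  gene_idx <- rep(seq_len(config$n_genes), n_sites)
  total <- length(gene_idx)
  if (total == 0L) stop("no sites simulated; increase n_variants_per_gene")
  offset <- sequence(n_sites)
  chrom <- as.character((gene_idx - 1L) %% 22L + 1L)
  pos <- gene_idx * 100000L + offset * 10L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt_shift <- sample.int(3L, total, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L]
  ultra <- runif(total) < config$p_ultra_rare
  log_bounds <- log10(config$maf_range)
  true_maf <- ifelse(ultra, config$ultra_rare_maf,
                     10^runif(total, log_bounds[1], log_bounds[2]))
  cons <- sample(names(config$consequence_probs), total, replace = TRUE,
                 prob = config$consequence_probs)
  cadd <- rep(NA_real_, total)
  scored <- cons %in% names(config$cadd_mean)
  cadd[scored] <- pmax(0, rnorm(sum(scored),
                                config$cadd_mean[cons[scored]],
                                config$cadd_sd[cons[scored]]))
  ref_ac <- rbinom(total, config$reference_an, true_maf)
  ref_af <- ifelse(ref_ac > 0, ref_ac / config$reference_an, NA_real_)
  ref_ac[ref_ac == 0] <- 0
  out <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    key = variant_key(chrom, pos, ref, alt),
    gene = genes[gene_idx], consequence = cons,
    protein_change = paste0("p.Sim", seq_len(total)),
    cadd_phred = cadd, ref_af = ref_af,
    ref_ac = as.numeric(ref_ac),
    call_rate = NA_real_, true_maf = true_maf,
    stringsAsFactors = FALSE
  )
  validate_variants(out)
  out
}

# which sites carry the planted case enrichment
planted_sites <- function(config, refdb) {
  panel <- sim_panel(config)$genes
  damaging <- (!is.na(refdb$cadd_phred) &
                 refdb$cadd_phred > config$cadd_enrich_cut) |
    (refdb$consequence == "frameshift" & is.na(refdb$cadd_phred))
  refdb$gene %in% panel &
    refdb$true_maf < config$maf_enrich_cut &
    damaging &
    refdb$consequence %in% rv_protein_altering()
}

#' Simulate case/control cohort genotypes
#'
#' Per individual and site, the alternate-allele dosage is
#' `Binomial(2, maf)` with `maf` equal to the site's true MAF for controls
#' and `min(0.5, enrichment x true MAF)` for cases when the site carries
#' the planted effect (see [sim_config()]). Genotypes are set missing with
#' probability `missing_rate`, and sites with no alternate allele in the
#' whole cohort are dropped when `drop_unobserved` is set.
#'
#' @param config An [sim_config()] object.
#' @param refdb Reference database from [simulate_reference_db()].
#' @return List with `genotypes` (samples x variants dosage matrix),
#'   `cohorts` (a cohort design) and `variants` (the rows of `refdb`
#'   retained, with `call_rate` filled in).
#' @export
simulate_cohorts <- function(config, refdb) {
  set.seed(config$seed + 1L)
  n_case <- config$n_fam_cases + config$n_sporadic_cases
  n_ctrl <- config$n_controls
  sample_id <- c(sprintf("FAM%03d", seq_len(config$n_fam_cases)),
                 sprintf("SPO%03d", seq_len(config$n_sporadic_cases)),
                 sprintf("CTL%03d", seq_len(n_ctrl)))
  cohorts <- cohort_design(sample_id,
                           c(rep("MSFAM", config$n_fam_cases),
                             rep("MSS", config$n_sporadic_cases),
                             rep("CTRL", n_ctrl)))
  nv <- nrow(refdb)
  planted <- planted_sites(config, refdb)
  maf_ctrl <- refdb$true_maf
  maf_case <- ifelse(planted, pmin(0.5, config$enrichment * maf_ctrl),
                     maf_ctrl)
  case_block <- matrix(rbinom(n_case * nv, 2, rep(maf_case, each = n_case)),
                       nrow = n_case)
  ctrl_block <- matrix(rbinom(n_ctrl * nv, 2, rep(maf_ctrl, each = n_ctrl)),
                       nrow = n_ctrl)
  gm <- rbind(case_block, ctrl_block)
  storage.mode(gm) <- "double"
  dimnames(gm) <- list(sample_id, refdb$key)
  if (config$missing_rate > 0) {
    gm[runif(length(gm)) < config$missing_rate] <- NA
  }
  variants <- refdb
  if (config$drop_unobserved) {
    observed <- colSums(gm, na.rm = TRUE) > 0
    gm <- gm[, observed, drop = FALSE]
    variants <- variants[observed, , drop = FALSE]
  }
  variants$call_rate <- unname(variant_call_rates(gm))
  rownames(variants) <- NULL
  list(genotypes = gm, cohorts = cohorts, variants = variants)
}

#' Simulate a complete dataset
#'
#' Runs [simulate_reference_db()] and [simulate_cohorts()] and bundles the
#' results with the designated panel.
#'
#' @param config An [sim_config()] object.
#' @return List with `variants`, `genotypes`, `cohorts`, `panel`, `refdb`
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  refdb <- simulate_reference_db(config)
  cc <- simulate_cohorts(config, refdb)
  list(variants = cc$variants, genotypes = cc$genotypes,
       cohorts = cc$cohorts, panel = sim_panel(config),
       refdb = refdb, config = config)
}

#' Write a simulated dataset to standard analysis input files
#'
#' Produces the file set consumed by [run_pipeline()]: a multi-sample VCF,
#' an annotation TSV, a cohort TSV, a panel TSV and two overlapping BED
#' capture files spanning all simulated loci.
#'
#' @param sim Value of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    cohorts = file.path(dir, "cohorts.tsv"),
    panel = file.path(dir, "panel.tsv"),
    bed = c(file.path(dir, "capture_a.bed"), file.path(dir, "capture_b.bed"))
  )
  write_genotype_vcf(sim$genotypes, sim$variants, paths$vcf)
  ann <- sim$variants[, c("chrom", "pos", "ref", "alt", "gene",
                          "consequence", "protein_change", "cadd_phred",
                          "ref_af", "ref_ac")]
  write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(as.data.frame(sim$cohorts), paths$cohorts, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = sim$panel$genes), paths$panel, sep = "\t",
              quote = FALSE, row.names = FALSE)
  spans <- do.call(rbind, lapply(split(sim$variants$pos, sim$variants$chrom),
                                 range))
  bed <- data.frame(chrom = rownames(spans),
                    start = pmax(0L, spans[, 1] - 10L),  # 0-based half-open
                    end = spans[, 2] + 10L)
  bed <- bed[order(bed$chrom), ]
  for (p in paths$bed) {
    write.table(bed, p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
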