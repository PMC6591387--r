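test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_genes = 25, n_variants_per_gene = 6, panel_size = 8,
                    seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$refdb, b$refdb)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cohorts, b$cohorts)
  cfg2 <- sim_config(n_genes = 25, n_variants_per_gene = 6, panel_size = 8,
                     seed = 100)
  expect_false(identical(simulate_dataset(cfg2)$genotypes, a$genotypes))
})

test_that("database absence matches the binomial zero probability", {
  # true MAF 1e-6 over 246,000 alleles: P(ref_ac = 0) = (1 - 1e-6)^246000
  cfg <- sim_config(n_genes = 200, n_variants_per_gene = 25,
                    panel_size = 10, p_ultra_rare = 1, ultra_rare_maf = 1e-6,
                    seed = 21)
  refdb <- simulate_reference_db(cfg)
  p0 <- (1 - 1e-6)^246000
  expect_equal(p0, 0.782, tolerance = 0.001)
  frac_absent <- mean(is.na(refdb$ref_af))
  se <- sqrt(p0 * (1 - p0) / nrow(refdb))
  expect_lt(abs(frac_absent - p0), 3 * se)
})

test_that("reference frequencies are unbiased for the true MAF", {
  cfg <- sim_config(n_genes = 100, n_variants_per_gene = 12,
                    panel_size = 10, p_ultra_rare = 1, ultra_rare_maf = 1e-3,
                    seed = 22)
  refdb <- simulate_reference_db(cfg)
  # at MAF 1e-3 essentially every site is in the database
  expect_lt(mean(is.na(refdb$ref_af)), 0.001)
  se <- sqrt(1e-3 / 246000 / nrow(refdb))
  expect_lt(abs(mean(refdb$ref_af) - 1e-3), 3 * se)
})

test_that("unscored CADD is confined to frameshift and in-frame indels", {
  cfg <- sim_config(n_genes = 60, n_variants_per_gene = 10, panel_size = 10,
                    seed = 23)
  refdb <- simulate_reference_db(cfg)
  unscored <- refdb$consequence[is.na(refdb$cadd_phred)]
  expect_true(all(unscored %in% c("frameshift", "inframe_indel")))
  expect_true(all(refdb$cadd_phred >= 0, na.rm = TRUE))
})

test_that("under the null, case and control panel burdens are exchangeable", {
  cfg <- sim_config(n_fam_cases = 60, n_sporadic_cases = 60,
                    n_controls = 120, n_genes = 50, panel_size = 15,
                    n_variants_per_gene = 10, enrichment = 1,
                    missing_rate = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  panel_keys <- sim$variants$key[sim$variants$gene %in% sim$panel$genes]
  cases <- case_samples(sim$cohorts)
  ctrls <- control_samples(sim$cohorts)
  a_case <- sum(sim$genotypes[cases, panel_keys])
  a_ctrl <- sum(sim$genotypes[ctrls, panel_keys])
  # equal per-allele rates and equal cohort allele numbers here: the case
  # share of panel alleles is Binomial(total, 1/2)
  bt <- binom.test(a_case, a_case + a_ctrl, 0.5)
  expect_gt(bt$p.value, 1e-4)
})

test_that("planted case alleles match the enrichment arithmetic", {
  # every site planted: panel = all genes, point mass MAF 1e-5, all
  # missense forced above the CADD cut
  n_case <- 175
  cfg <- sim_config(n_fam_cases = 86, n_sporadic_cases = 89,
                    n_controls = 144, n_genes = 50, panel_size = 50,
                    n_variants_per_gene = 10, p_ultra_rare = 1,
                    ultra_rare_maf = 1e-5, enrichment = 20,
                    consequence_probs = c(missense = 1),
                    cadd_mean = c(missense = 30),
                    cadd_sd = c(missense = 0.1),
                    missing_rate = 0, drop_unobserved = FALSE, seed = 41)
  sim <- simulate_dataset(cfg)
  nv <- nrow(sim$variants)
  cases <- case_samples(sim$cohorts)
  got <- sum(sim$genotypes[cases, ])
  lambda <- 2 * n_case * 20 * 1e-5 * nv
  expect_lt(abs(got - lambda), 4 * sqrt(lambda))
  # controls stay at the base rate
  ctrls <- control_samples(sim$cohorts)
  got_ctrl <- sum(sim$genotypes[ctrls, ])
  lambda_ctrl <- 2 * 144 * 1e-5 * nv
  expect_lt(abs(got_ctrl - lambda_ctrl), 4 * sqrt(lambda_ctrl) + 1)
})

test_that("missingness matches its configured rate", {
  cfg <- sim_config(n_fam_cases = 50, n_sporadic_cases = 50,
                    n_controls = 50, n_genes = 40, panel_size = 10,
                    n_variants_per_gene = 10, missing_rate = 0.02,
                    drop_unobserved = FALSE, seed = 51)
  sim <- simulate_dataset(cfg)
  frac <- mean(is.na(sim$genotypes))
  se <- sqrt(0.02 * 0.98 / length(sim$genotypes))
  expect_lt(abs(frac - 0.02), 3 * se)
})

test_that("cohort files round-trip through the standard formats", {
  cfg <- sim_config(n_fam_cases = 10, n_sporadic_cases = 10,
                    n_controls = 12, n_genes = 15, panel_size = 5,
                    n_variants_per_gene = 6, seed = 61)
  sim <- simulate_dataset(cfg)
  dir <- tempfile("simout")
  paths <- write_cohort_files(sim, dir)
  geno <- read_genotypes(paths$vcf)
  joined <- join_annotations(geno$variants, paths$annotations)
  expect_identical(joined$gene, sim$variants$gene)
  expect_identical(joined$consequence, sim$variants$consequence)
  expect_equal(joined$ref_af, sim$variants$ref_af)
  cohorts <- read_cohorts(paths$cohorts)
  expect_identical(cohorts$sample_id, sim$cohorts$sample_id)
  panel <- read_panel(paths$panel)
  expect_identical(panel$genes, sim$panel$genes)
  kept <- intersect_captured(joined, paths$bed)
  expect_equal(nrow(kept), nrow(joined))  # capture spans all loci
})
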