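test_that("the selected-variant classifier applies the printed criteria", {
  v <- tiny_variants(6, pos = 1:6 * 10,
                     consequence = c("missense", "missense", "frameshift",
                                     "missense", "inframe_indel",
                                     "synonymous"),
                     cadd_phred = c(32, 22.7, NA, 18, NA, 25),
                     ref_af = c(NA, 0.022276, 4.10e-6, 5e-6, 1e-6, NA),
                     ref_ac = c(NA, 5480, 1, 1, 1, NA))
  sel <- classify_selected(v)
  # absent-reference missense with CADD 32 (the strongest candidate gene
  # pattern) passes; a MAF-common missense fails; an ultra-rare frameshift
  # passes on MAF alone; CADD 18 fails; unscored in-frame indels and
  # synonymous variants never qualify
  expect_identical(as.logical(sel), c(TRUE, FALSE, TRUE, FALSE, FALSE,
                                      FALSE))
  expect_identical(as.logical(attr(sel, "frameshift_only")),
                   c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  v_bad <- tiny_variants(1, consequence = "missense", cadd_phred = NA)
  expect_error(classify_selected(v_bad), "missing CADD")
  expect_error(selection_criteria(maf_cut = 0.2), "maf_cut")
})

test_that("all transcribed selected variants satisfy the criteria", {
  sv <- selected_variants()
  sel <- classify_selected(sv)
  expect_equal(sum(sel), 29)
  expect_equal(sum(attr(sel, "frameshift_only")), 3)
})

test_that("relative burden normalises allele counts to cohort sizes", {
  # 175 cases carrying 29 alleles vs 144 controls carrying 3:
  # ((29 + 0.5) / 175) / ((3 + 0.5) / 144)
  v <- tiny_variants(1, ref_af = NA, ref_ac = NA)
  cohorts <- cohort_design(
    c(sprintf("MS%03d", 1:175), sprintf("CT%03d", 1:144)),
    c(rep("MSFAM", 86), rep("MSS", 89), rep("CTRL", 144))
  )
  dos <- c(rep(1, 29), rep(0, 146), rep(1, 3), rep(0, 141))
  gm <- tiny_gm(cbind(dos), v, samples = cohorts$sample_id)
  rb <- relative_burden(v, gm, cohorts)
  expect_equal(as.numeric(rb), (29.5 / 175) / (3.5 / 144))
  expect_equal(as.numeric(rb), 6.9357, tolerance = 1e-4)
  expect_equal(attr(rb, "case_alleles"), 29)
  expect_equal(attr(rb, "ctrl_alleles"), 3)
})

test_that("identical cohorts give unit relative burden across the grid", {
  v <- tiny_variants(5, pos = 1:5 * 10, ref_af = 10^seq(-5.5, -2, length.out = 5),
                     ref_ac = 100)
  cohorts <- tiny_cohorts(5, 5, 10)
  set.seed(55)
  block <- matrix(rbinom(50, 2, 0.3), nrow = 10)  # 10 samples x 5 variants
  gm <- tiny_gm(rbind(block, block), v, samples = cohorts$sample_id)
  sw <- sweep_burden(v, gm, cohorts, "maf", n_cutoffs = 50)
  same <- sw$case_alleles / 10 - sw$ctrl_alleles / 10
  expect_true(all(same == 0))
  expect_true(all(abs(sw$relative_burden - 1) < 0.2))  # pseudocount wobble
})

test_that("sweep grids are lax-to-stringent with the documented spacing", {
  g_maf <- sweep_grid("maf")
  expect_length(g_maf, 300)
  expect_equal(g_maf[1], 0.05)
  expect_equal(g_maf[300], 1e-6)
  expect_equal(diff(log10(g_maf))[1], diff(log10(g_maf))[250])
  g_cadd <- sweep_grid("cadd")
  expect_length(g_cadd, 300)
  expect_equal(g_cadd[1], 0)
  expect_equal(g_cadd[300], 40)
  expect_error(sweep_grid("maf", maf_range = c(0.05, 1e-6)), "inverted")
})

test_that("the laxest cutoff reproduces the unrestricted burden", {
  cfg <- sim_config(n_fam_cases = 15, n_sporadic_cases = 15,
                    n_controls = 20, n_genes = 20, panel_size = 8,
                    n_variants_per_gene = 8, seed = 77)
  d <- sim_filtered(cfg)
  # drop unscored variants so the CADD axis covers every variant at cutoff 0
  v <- d$variants[!is.na(d$variants$cadd_phred) &
                    d$variants$cadd_phred > 0, ]
  gm <- align_genotypes(d$genotypes, v)
  sw_maf <- sweep_burden(v, gm, d$cohorts, "maf", n_cutoffs = 60)
  sw_cadd <- sweep_burden(v, gm, d$cohorts, "cadd", n_cutoffs = 60)
  rb_all <- relative_burden(v, gm, d$cohorts)
  expect_equal(sw_maf$relative_burden[1], as.numeric(rb_all))
  expect_equal(sw_cadd$relative_burden[1], as.numeric(rb_all))
  # qualifying counts never grow as either cutoff tightens
  expect_true(all(diff(sw_maf$case_alleles) <= 0))
  expect_true(all(diff(sw_maf$ctrl_alleles) <= 0))
  expect_true(all(diff(sw_cadd$case_alleles) <= 0))
})

test_that("a degenerate annotation produces a step-function curve", {
  v <- tiny_variants(4, pos = 1:4 * 10, ref_af = 1e-4, ref_ac = 25)
  cohorts <- tiny_cohorts(2, 2, 4)
  gm <- tiny_gm(matrix(c(1, 1, 0, 0, 1, 0, 1, 0,
                         0, 1, 0, 0, 0, 0, 1, 1,
                         1, 0, 0, 1, 0, 1, 0, 0,
                         0, 0, 1, 0, 1, 0, 0, 1), ncol = 4), v,
                samples = cohorts$sample_id)
  sw <- sweep_burden(v, gm, cohorts, "maf", n_cutoffs = 40)
  vals <- unique(sw$relative_burden)
  expect_length(vals, 2)   # constant on each side of the shared MAF
  expect_identical(sw$relative_burden,
                   ifelse(sw$cutoff > 1e-4, vals[1], vals[2]))
})

test_that("the joint grid matches brute-force recounts and the classifier", {
  cfg <- sim_config(n_fam_cases = 20, n_sporadic_cases = 20,
                    n_controls = 25, n_genes = 25, panel_size = 10,
                    n_variants_per_gene = 10, enrichment = 15, seed = 83)
  d <- sim_filtered(cfg)
  maf_grid <- sort(c(sweep_grid("maf", 30), 1e-5), decreasing = TRUE)
  cadd_grid <- sort(c(sweep_grid("cadd", 30), 20))
  jg <- joint_grid(d$variants, d$genotypes, d$cohorts,
                   maf_grid = maf_grid, cadd_grid = cadd_grid)
  A_case <- attr(jg, "case_alleles")
  cases <- case_samples(d$cohorts)
  ctrls <- control_samples(d$cohorts)
  a_case <- colSums(d$genotypes[cases, , drop = FALSE], na.rm = TRUE)
  a_ctrl <- colSums(d$genotypes[ctrls, , drop = FALSE], na.rm = TRUE)
  eff <- effective_ref_maf(d$variants$ref_af)
  fs <- d$variants$consequence == "frameshift" & is.na(d$variants$cadd_phred)
  set.seed(1)
  for (cell in seq_len(5)) {
    i <- sample(length(maf_grid), 1)
    j <- sample(length(cadd_grid), 1)
    qual <- eff < maf_grid[i] &
      (fs | (!is.na(d$variants$cadd_phred) &
               d$variants$cadd_phred > cadd_grid[j]))
    expect_equal(A_case[i, j], sum(a_case[qual]))
  }
  # corner at the laxest cell equals the MAF-only qualifying set at 0.05
  expect_equal(A_case[1, 1], sum(a_case[eff < maf_grid[1] &
                                          (fs | d$variants$cadd_phred > 0)]))
  # classifier/grid coherence at the (1e-5, 20) cell
  i <- which(maf_grid == 1e-5)
  j <- which(cadd_grid == 20)
  sel <- classify_selected(d$variants)
  expect_equal(A_case[i, j], sum(a_case[sel]))
  ms_ratio <- jg[i, j]
  expect_equal(as.numeric(ms_ratio),
               ((sum(a_case[sel]) + 0.5) / length(cases)) /
                 ((sum(a_ctrl[sel]) + 0.5) / length(ctrls)))
})

test_that("planted enrichment concentrates burden at stringent cutoffs", {
  cfg <- sim_config(seed = 91, enrichment = 20, n_genes = 150,
                    n_variants_per_gene = 30, panel_size = 62)
  d <- sim_filtered(cfg)
  pv <- d$variants[d$variants$gene %in% d$panel$genes, ]
  gm <- align_genotypes(d$genotypes, pv)
  sw <- sweep_burden(pv, gm, d$cohorts, "maf", n_cutoffs = 100)
  lax <- mean(sw$relative_burden[1:20])
  stringent <- mean(sw$relative_burden[70:90])
  expect_gt(stringent, lax)
})
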