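test_that("reference allele numbers reconstruct from printed AF/AC pairs", {
  expect_equal(reconstruct_ref_an(8.14e-6, 2)$ref_an, 245700)
  expect_equal(reconstruct_ref_an(4.06e-6, 1)$ref_an, 246305)
  absent <- reconstruct_ref_an(NA, 0)
  expect_equal(absent$ref_an, 246000)
  expect_equal(absent$ref_ac, 0)
  expect_error(reconstruct_ref_an(0, 5), "inconsistent")
})

test_that("Fisher tests against the reference match enumeration", {
  expect_equal(fisher_vs_reference(1, 100, 10, 1000)$p_value, 1)
  set.seed(29)
  for (i in 1:20) {
    a <- sample(0:10, 1); b <- sample(1:25, 1)
    c <- sample(0:10, 1); d <- sample(1:25, 1)
    got <- fisher_vs_reference(a, a + b, c, c + d)$p_value
    expect_equal(got, fisher_p_enum(a, b, c, d), tolerance = 1e-12)
  }
  expect_error(fisher_vs_reference(5, 4, 1, 100), "exceeds")
})

test_that("Fisher p decreases as the cohort count grows", {
  ps <- fisher_vs_reference(0:6, 350, 2, 245700)$p_value
  expect_true(all(diff(ps[-1]) < 0))  # monotone once the excess direction is set
})

test_that("two or more case alleles at reference-rare sites reach p < 0.01", {
  # printed counts: 2 of 350 case alleles vs 2 reference alleles at 8.14e-6
  ref <- reconstruct_ref_an(8.14e-6, 2)
  res <- fisher_vs_reference(2, 350, ref$ref_ac, ref$ref_an)
  expect_lt(res$p_value, 0.01)
})

test_that("the two-stage rule separates enrichment from population effects", {
  # absent-reference variant in two case probands, absent in controls
  res <- classify_two_stage(2, 350, 0, 288, 0, 246000)
  expect_equal(as.character(res$classification), "ms_enriched")
  expect_gte(res$p_ctrl, 0.01)
  # a case singleton never qualifies regardless of significance
  res1 <- classify_two_stage(1, 350, 0, 288, 0, 246000)
  expect_equal(as.character(res1$classification), "not_multiproband")
  # control excess marks a population-specific variant even when cases hit
  res2 <- classify_two_stage(6, 350, 8, 288, 4, 246000)
  expect_lt(res2$p_case, 0.01)
  expect_equal(as.character(res2$classification), "population_specific")
  # mutual exclusion: ms_enriched never co-occurs with control p < alpha
  set.seed(31)
  ms_ac <- sample(0:8, 50, replace = TRUE)
  ct_ac <- sample(0:8, 50, replace = TRUE)
  ref_ac <- sample(0:20, 50, replace = TRUE)
  res3 <- classify_two_stage(ms_ac, 350, ct_ac, 288, ref_ac, 246000)
  enr <- res3$classification == "ms_enriched"
  expect_true(all(res3$p_ctrl[enr] >= 0.01))
})

test_that("the starred fixtures classify as both selected and enriched", {
  sv <- selected_variants()
  ref <- reconstruct_ref_an(sv$ref_af, sv$ref_ac)
  res <- classify_two_stage(sv$ms_ac, 350, sv$ctrl_ac, 288,
                            ref$ref_ac, ref$ref_an)
  starred <- sv$protein_change %in% c("p.Met619Val", "p.Pro194Ser")
  expect_identical(sv$gene[starred], c("IFIH1", "RIPK2"))
  expect_true(all(res$classification[starred] == "ms_enriched"))
  expect_true(all(classify_selected(sv)[starred]))
})

test_that("the absent-variant chi-square matches the Yates formula", {
  same <- absent_variant_chisq(10, 100, 10, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  got <- absent_variant_chisq(25, 200, 5, 200)
  tab <- matrix(c(25, 175, 5, 195), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - expected) - 0.5)^2 / expected)
  expect_equal(got$statistic, stat)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE))
  expect_error(absent_variant_chisq(0, 100, 0, 100), "margin")
  expect_error(absent_variant_chisq(30, 20, 5, 100), "inconsistent")
})

test_that("the absent-variant chi-square holds its level", {
  set.seed(37)
  rejections <- mean(vapply(1:400, function(i) {
    a <- rbinom(1, 120, 0.15)
    b <- rbinom(1, 120, 0.15)
    absent_variant_chisq(a, 120, b, 120)$p_value < 0.05
  }, logical(1)))
  expect_lt(rejections, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("haplotype pooling uses one representative count", {
  single <- haplotype_pool_test(2, 700, 1, 246000)
  expect_equal(single$p_value,
               fisher_vs_reference(2, 700, 1, 246000)$p_value)
  # two perfectly co-occurring variants: one test on the shared counts
  pooled <- haplotype_pool_test(c(2, 2), 700, c(1, 1), c(246000, 246000))
  expect_lt(pooled$p_value, 0.01)
  expect_equal(pooled$p_value, single$p_value)
  expect_error(haplotype_pool_test(c(2, 3), 700, c(1, 1), 246000),
               "representative")
  forced <- haplotype_pool_test(c(2, 3), 700, c(1, 1), 246000,
                                representative = list(ms_ac = 2, ref_ac = 1))
  expect_equal(forced$p_value, single$p_value)
})

test_that("aggregate selected frequencies follow the printed arithmetic", {
  sv <- selected_variants()
  ms <- aggregate_selected_frequency(sv$ms_ac, 175)
  expect_equal(ms$exact, 29 / 350)
  expect_equal(ms$reported, 0.08)
  ctrl <- aggregate_selected_frequency(sv$ctrl_ac, 144)
  expect_equal(ctrl$exact, 3 / 288)
  expect_equal(ctrl$reported, 0.01)
  expect_equal(aggregate_selected_frequency(numeric(0), 50)$exact, 0)
  expect_error(aggregate_selected_frequency(1, 0), "empty cohort")
})

test_that("variant enrichment reports align with the genotype matrix", {
  v <- tiny_variants(3, pos = 1:3 * 10,
                     ref_af = c(NA, 8.14e-6, 0.04),
                     ref_ac = c(NA, 2, 10000),
                     cadd_phred = c(32, 24.4, 10))
  cohorts <- tiny_cohorts(3, 3, 4)
  gm <- tiny_gm(rbind(
    c(1, 1, 0), c(1, 0, 1), c(0, 1, 0),   # MSFAM
    c(0, 0, 2), c(0, 0, 0), c(0, 0, 0),   # MSS
    c(0, 0, 1), c(0, 0, 0), c(0, 0, 1), c(0, 0, 0)  # CTRL
  ), v, samples = cohorts$sample_id)
  res <- variant_enrichment(v, gm, cohorts)
  expect_equal(res$ms_ac, c(2, 2, 3))
  expect_equal(res$ctrl_ac, c(0, 0, 2))
  expect_equal(res$ms_carriers, c(2, 2, 2))
  expect_true(all(res$selected == c(TRUE, TRUE, FALSE)))
  expect_equal(res$ref_an[1], 246000)
})
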