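# rvburden

Aggregate rare-variant burden and enrichment analysis for case-control
exome cohorts organised around a candidate gene panel.

## The problem

Alleles with population frequency below ~1e-4 — zero, one or two copies
in a quarter-million-allele reference database such as gnomAD — carry a
substantial share of human coding variation but are invisible to
array-based association studies and underpowered one-variant-at-a-time.
The standard remedy is *aggregation*: collapse the rare protein-altering
variants of a biologically motivated gene panel into a single weighted
burden score per individual and compare cases with controls. rvburden
implements this analysis for a three-cohort design (familial cases,
sporadic cases, controls) and ships the 62-gene NLRP1/NLRP3 inflammasome
regulation panel it was built around, together with a seeded synthetic
cohort generator so that every stage runs and is tested without access to
protected genotypes.

## The statistics

* **Weighted burden test.** Per-individual score
  `s_i = Σ_j w_j G_ij` with Madsen–Browning weights
  `w_j = 1/sqrt(m_j (1 − m_j))`, where `m_j` is the variant's reference
  MAF, floored at 1e-6 for database-absent variants. Association via a
  burden-mode score test `U = Σ_i s_i (y_i − ȳ)` with permutation
  variance, or an exact-level label-permutation test (recommended below a
  few thousand samples). Three contrasts (familial / sporadic / combined
  vs controls) against a Bonferroni family threshold of 0.003.
* **Cutoff sweeps.** Relative case/control burden
  `((A_case+0.5)/n_case) / ((A_ctrl+0.5)/n_ctrl)` across 300 MAF cutoffs
  (log-spaced over [1e-6, 0.05], qualify below) and 300 CADD-phred
  cutoffs (linear over [0, 40], qualify above), plus the joint grid.
  *Selected* variants: effective reference MAF < 1e-5 and CADD > 20
  (frameshifts by the MAF criterion alone).
* **Gene-panel Monte Carlo null.** OLS slope of the sweep curve compared
  with slopes of random same-size gene panels; one-sided add-one
  empirical p-value.
* **Per-variant enrichment.** Two-sided Fisher exact tests of cohort
  allele counts against reconstructed reference counts
  (`AN = round(AC/AF)`, default 246,000 when absent); variants in ≥2 case
  probands classify as *MS enriched* (case test p < 0.01, control test
  not) or *population specific* (control test p < 0.01). Yates-corrected
  chi-square for the over-representation of database-absent variants and
  a haplotype-pooled Fisher test for perfectly co-occurring variants.

## Worked example

Simulate a study-scale cohort with a 20-fold enrichment planted in the
panel's rare, high-CADD variants, then run the analysis:

```r
library(rvburden)

cfg <- sim_config(seed = 42, enrichment = 20)
sim <- simulate_dataset(cfg)

variants <- prefilter_rare_protein_altering(
  filter_call_rate(sim$variants),
  dataset_af(sim$genotypes))
gm <- align_genotypes(sim$genotypes, variants)

burden_test(gm, variants, sim$cohorts, sim$panel)
#> <rv_burden_result> score test: statistic = 4.828 p = 1.38e-06

panel_null_test(variants, gm, sim$cohorts, sim$panel,
                axis = "maf", n_panels = 10000, seed = 42)
#> <rv_panel_null> maf axis: observed slope = 4.656 empirical p = 0.0262
#>   over 10000 panels
```

The burden p-value far below the 0.003 family threshold says the panel's
rare-variant burden differs between cases and controls; the Monte Carlo
p-value says a trend this strong toward rare cutoffs appears in only
about 2.6% of random same-size gene panels, i.e. the signal is largely
specific to the panel rather than a cohort-wide artifact.

The packaged reference tables reproduce the printed summary arithmetic:

```r
sv <- selected_variants()                       # 29 prioritised variants
aggregate_selected_frequency(sv$ms_ac, 175)$reported    #> 0.08
aggregate_selected_frequency(sv$ctrl_ac, 144)$reported  #> 0.01

row <- sv[sv$gene == "IFIH1", ]
ref <- reconstruct_ref_an(row$ref_af, row$ref_ac)       # AN = 245700
fisher_vs_reference(row$ms_ac, 350, ref$ref_ac, ref$ref_an)$p_value
#> 1.208316e-05
```

A full run over files (VCF + annotation TSV + cohort TSV + panel TSV +
capture BEDs) goes through `run_config()` / `run_pipeline()`, which
writes TSV/JSON reports and a reproducibility manifest;
`read_run_config()` accepts the same configuration as YAML.

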