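---
title: "Weighted rare-variant burden and enrichment analysis with rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rare-variant burden and enrichment analysis with rvburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The problem

Case-control exome studies of complex disease increasingly point at
*exceedingly rare* coding variants — alleles with population frequency
below about 1e-4, i.e. none, one or two copies in a reference database of
roughly a quarter-million alleles. Any single such variant is hopeless to
test on its own in a few hundred probands, so the standard device is
aggregation: collapse the rare protein-altering variants of a candidate
gene panel into one burden score per individual and test whether that
score differs between cases and controls. rvburden implements this
analysis for a three-cohort design (familial cases `MSFAM`, sporadic
cases `MSS`, controls `CTRL`), organised around a 62-gene panel covering
the NLRP1/NLRP3 inflammasome and its regulatory network, which ships with
the package (`panel_genes()`); any other panel can be supplied.

The package covers five stages, each usable on its own:

1. **Filtering** (`intersect_captured()`, `filter_call_rate()`,
   `prefilter_rare_protein_altering()`): restrict to universally captured
   loci, genotyping rate strictly above 95%, protein-altering
   consequences, and MAF at most 0.05 in both the reference database and
   the dataset itself. The filters commute, and
   `align_genotypes()` keeps the dosage matrix in step with the variant
   table.
2. **Weighted burden test** (`burden_score()`, `burden_association()`,
   `burden_test()`).
3. **Cutoff sweeps** (`sweep_burden()`, `joint_grid()`,
   `classify_selected()`): relative case/control burden as MAF and
   CADD-phred cutoffs tighten, and the *selected*-variant rule.
4. **Gene-panel Monte Carlo null** (`panel_null_test()`): is the burden
   trend specific to the panel, or would any same-size gene set show it?
5. **Per-variant enrichment** (`variant_enrichment()`,
   `classify_two_stage()`, `absent_variant_chisq()`,
   `haplotype_pool_test()`): Fisher exact comparison of cohort allele
   counts against reference-database counts, with a two-stage rule that
   separates case enrichment from population-specific frequency shifts.

`run_pipeline()` chains all five from a VCF, an annotation TSV, a cohort
TSV, a panel TSV and optional capture BEDs, and writes TSV/JSON reports
plus a manifest (configuration, seed, versions, per-filter variant
ledger) sufficient to reproduce the run.

## The burden model

Let $G_{ij} \in \{0,1,2\}$ be the alternate-allele dosage of individual
$i$ at panel variant $j$, and let $m_j$ be the variant's *effective
reference MAF*: the reference-database frequency when the variant is in
the database, and $10^{-6}$ otherwise. The extrapolated floor mirrors the
database's resolution — allele counts of 2 and 1 correspond to reported
frequencies of about $8\times10^{-6}$ and $4\times10^{-6}$, so an
unobserved allele sits just below — and gives database-absent variants
the largest weight. The per-individual score uses Madsen–Browning
weights:

$$ s_i = \sum_j w_j G_{ij}, \qquad w_j = \frac{1}{\sqrt{m_j(1-m_j)}}. $$

Missing dosages are imputed to the variant's mean observed dosage (common
burden-test practice). For a binary phenotype $y$ the score statistic is

$$ U = \sum_i s_i (y_i - \bar y), \qquad
   \widehat{\mathrm{Var}}(U) = \bar y (1 - \bar y) \sum_i (s_i - \bar s)^2, $$

with a two-sided normal tail for $U/\sqrt{\widehat{\mathrm{Var}}(U)}$
(`method = "score"`; this is the burden-mode score test with an
intercept-only null, no covariates). Because the weights are heavy-tailed
— one database-absent singleton carries $w \approx 1000$ — the normal
approximation degrades in small cohorts, where the score test becomes
conservative. The package therefore also provides
`method = "permutation"`, an add-one label permutation test that is
exact in level, and **recommends it below a few thousand samples**; the
test suite checks its calibration directly and checks that the two
methods agree where the score approximation is reasonable.

Three contrasts are run (familial, sporadic, combined cases vs controls);
with a family-wise alpha of 0.01, `bonferroni_threshold(0.01, 3)` reports
the conventional 0.003 cutoff.

## Cutoff sweeps and the selected-variant rule

`sweep_burden()` evaluates the size-normalised burden ratio

$$ R(c) = \frac{(A_\text{case}(c) + 0.5)/n_\text{case}}
               {(A_\text{ctrl}(c) + 0.5)/n_\text{ctrl}} $$

over 300 cutoffs, where $A(c)$ sums alternate-allele dosages over
variants qualifying at cutoff $c$ (alleles, not carriers). MAF cutoffs
are spaced equally in $\log_{10}$ over $[10^{-6}, 0.05]$ — the
frequencies span almost five orders of magnitude and all the structure
sits at the rare end, so linear spacing would waste the grid — and
variants qualify strictly *below* the cutoff. CADD cutoffs are linear
over $[0, 40]$ with qualification strictly *above*. The 0.5 pseudocount
keeps ratios finite when a cohort carries no qualifying allele; the
report flags cells where both cohorts are empty. `joint_grid()` crosses
both criteria; frameshift variants, which the CADD algorithm cannot
score, qualify through the MAF coordinate alone.

A variant is **selected** (`classify_selected()`) when its effective
reference MAF is below $10^{-5}$ and its CADD-phred exceeds 20
(frameshifts: MAF criterion only). An unscored in-frame indel cannot meet
the CADD criterion and is classified not selected; an unscored variant of
any other consequence violates the annotation contract and raises an
error. The classifier is coherent with the joint grid: a variant is
selected exactly when it qualifies at the $(10^{-5}, 20)$ cell.

## The gene-panel Monte Carlo null

The sweep curve of the candidate panel trends upward toward stringent
cutoffs; the question is whether that trend is specific to the panel.
`trend_slope()` fits an OLS slope to the curve against its rank position
rescaled to $[0,1]$ (so the slope is unit-free), and
`panel_null_test()` compares the observed slope to slopes of random
same-size gene panels drawn uniformly from the universe of genes with at
least one retained variant, reusing the same genotype data. The
one-sided empirical p-value uses the add-one convention
$p = (1 + \#\{b : \beta_b \ge \beta_\text{obs}\})/(B+1)$, one-sided
because the alternative is an *excess* trend toward rare/damaging
variants. Slopes are taken on the raw ratio curve; we evaluated a
log-scale and a baseline-normalised variant during design and both
discriminated less well on synthetic data.

By default the random panels are drawn from the universe *excluding* the
tested panel's genes. With a genome-scale universe this is a no-op (a
62-gene panel overlaps a random draw from ~18,000 genes in well under
one gene on average), but in compact simulated exomes overlapping draws
would leak any true panel signal into the null distribution and bias the
test conservative. The flip side: when the panel is a *large* fraction
of the universe (say a fifth or more), exclusion itself distorts the
null — in that regime pass `exclude_panel = FALSE`. The package's test
suite checks calibration at the geometry the method is meant for (panel
around 5% of the universe).

## Per-variant enrichment against the reference database

For variants carried by two or more case probands (carriers, not alleles
— a single homozygote does not qualify), `classify_two_stage()` runs two
two-sided Fisher exact tests of allele proportions: combined cases vs
the reference database, and controls vs the reference database. With
nominal alpha 0.01 (no multiplicity correction, by design): case test
significant and control test not → `ms_enriched`; control test
significant → `population_specific`; otherwise `neither`. Reference
allele numbers are reconstructed per variant as
$\mathrm{round}(\mathrm{AC}/\mathrm{AF})$; database-absent variants use a
default allele number of 246,000, the value implied by printed AF/AC
pairs such as AC 2 at AF $8.1\times10^{-6}$.

Two auxiliary tests round out the stage: `absent_variant_chisq()`, a
Yates-corrected chi-square asking whether database-absent variants (as
variant counts, with each cohort's total discovered variants as
background) are over-represented among cases; and
`haplotype_pool_test()`, which treats perfectly co-occurring variants of
near-identical reference frequency as a single haplotype and runs one
Fisher test on a representative count rather than summing — summing
would double-count the same chromosomes.

`aggregate_selected_frequency()` reports the summed selected-variant
allele frequency per cohort (exact, and rounded to two decimals as in
summary tables). On the packaged reference table of 29 selected variants
this gives 0.08 for the combined cases ($n=175$) and 0.01 for controls
($n=144$).

## The synthetic-data generator

No genotype data are distributable for this design, so `sim_config()` /
`simulate_dataset()` generate cohorts with the statistical structure the
analysis assumes, and every stage of the package is tested against them.

* **Reference database**: each candidate site gets a true population MAF
  from a two-component mixture — a point mass (weight 0.6) of ultra-rare
  sites at $8\times10^{-6}$ and a log-uniform component over
  $[10^{-6}, 0.05]$. The reference allele count is
  $\mathrm{Binomial}(246{,}000, \mathrm{MAF})$; sites drawing zero are
  database-absent. This is a pragmatic mixture, not a population-genetic
  site frequency spectrum; it reproduces the features the statistics
  exercise (a dominant ultra-rare mass, database-absent alleles,
  reconstructable AF/AC pairs), not linkage, demography or selection.
* **Cohorts**: 86 familial cases, 89 sporadic cases, 144 controls;
  dosages $\mathrm{Binomial}(2, \mathrm{MAF})$ per site and individual,
  independent across sites (no LD, no relatedness), missing with
  probability 0.003 (the design's 99.7% genotyping rate). Sites with no
  alternate allele in the cohort are dropped, as in real variant-calling
  output.
* **Planted effect**: case MAF is multiplied by a configurable
  `enrichment` factor (capped at 0.5) on panel sites with true MAF below
  $10^{-4}$ and CADD above 20 (unscored frameshifts count as damaging).
  `enrichment = 1` is the exact null.
* **CADD model**: per-consequence truncated normals (missense 15 ± 7,
  stop-gain 36 ± 4, splice 24 ± 8, ...); frameshift and in-frame indels
  are left unscored, as the scoring algorithm cannot assess them.

The scale defaults — 1000 genes with a mean of 60 candidate sites each —
were chosen so that (i) the designated 62-gene panel is a small fraction
of the gene universe, as in a real exome; (ii) the discovery density is
realistic (about five observed variants per gene, matching a 300-variant
panel yield); and (iii) at `enrichment = 20` the synthetic cohorts
reproduce the magnitude of effect the analysis is designed to detect: an
aggregate selected-variant frequency on the order of a few percent in
cases against an order of magnitude less in controls, with an excess of
database-absent variants among cases (`scripts/acceptance.R` recomputes
these quantities on a fresh simulation). All generator randomness flows from the single `seed`; equal
configurations are bit-reproducible.

Because the generator is independent across sites, passing tests say
nothing about robustness to LD, cryptic relatedness, capture-kit batch
effects correlated with phenotype, or ancestry mismatch between cohort
and reference database — all of which matter in real data and are out of
scope here.

## Numerical and design choices

* "Genotyped in over 95%" is read as a strict inequality; the boundary
  case (call rate exactly 0.95) is dropped. Configurable.
* Dataset MAF = alternate alleles / (2 × genotyped individuals); missing
  genotypes leave the denominator.
* Multiallelic VCF records are rejected with an error rather than
  silently split — the safer contract when the upstream normalisation is
  unknown.
* X-chromosome dosages are counted as coded; no hemizygosity correction
  is applied, and no sex-specific modelling is attempted.
* Fisher tests are two-sided (the conventional default); sidedness is an
  argument. The burden-family threshold is reported at three decimals
  (0.003) alongside the exact value.
* Test problem sizes: the null-calibration properties run 1000 burden
  replicates at $n=300$ and 200 panel-null replicates at 500 random
  panels; the planted-effect property runs 50 study-scale replicates.
  These sizes give Monte Carlo standard errors small enough for
  2-standard-error acceptance bands while keeping the default suite
  quick to run.

## Known limitations

* The score test is conservative for small $n$ with heavy
  Madsen–Browning weights; use the permutation method there (the
  package's default recommendation below a few thousand samples).
* The SKAT family's small-sample moment adjustments are deliberately not
  replicated; the permutation test is the package's exact-level answer.
* No covariate adjustment, no kinship correction, no variance-component
  (SKAT-proper or SKAT-O) test.
* Reference-database comparisons assume the cohort's ancestry is
  reasonably represented by the overall reference frequencies; the
  two-stage control comparison catches gross population specificity but
  is no substitute for ancestry-matched references.
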