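# Monte Carlo gene-panel null for the burden-trend slope: the slope of the
# observed panel's relative-burden curve is compared to slopes of random
# same-size gene panels drawn from the genes carrying retained variants.

#' Ordinary least squares slope of a burden curve
#'
#' The abscissa is the curve's rank position rescaled to `[0, 1]` (lax to
#' stringent), so the slope measures how strongly the relative burden grows
#' toward rare / damaging cutoffs irrespective of the cutoff units.
#'
#' @param curve An `rv_sweep_curve`, or a numeric vector of relative
#'   burdens ordered lax to stringent.
#' @return The OLS slope (numeric scalar).
#' @export
trend_slope <- function(curve) {
  y <- if (is.data.frame(curve)) curve$relative_burden else as.numeric(curve)
  n <- length(y)
  if (n < 3L) stop("at least 3 curve points are required")
  x <- seq(0, 1, length.out = n)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Draw random gene panels from a gene universe
#'
#' Panels are drawn uniformly without replacement within a panel and
#' independently across panels.
#'
#' @param gene_universe Character vector of candidate genes (typically all
#'   genes with at least one retained variant).
#' @param size Panel size; must not exceed the universe size.
#' @param n_panels Number of panels.
#' @param seed Integer seed.
#' @return Character matrix with `n_panels` rows and `size` columns; each
#'   row is one panel.
#' @export
sample_random_panels <- function(gene_universe, size, n_panels, seed = 1) {
  gene_universe <- as.character(gene_universe)
  if (size > length(gene_universe)) {
    stop("panel size exceeds the gene universe (",
         length(gene_universe), " genes)")
  }
  set.seed(seed)
  idx <- vapply(seq_len(n_panels),
                function(i) sample.int(length(gene_universe), size),
                integer(size))
  idx <- if (size == 1L) matrix(idx, ncol = 1L) else t(idx)
  matrix(gene_universe[idx], nrow = n_panels)
}

#' One-sided empirical p-value against a Monte Carlo null
#'
#' Add-one permutation convention: `p = (1 + #{null >= observed}) /
#' (n + 1)`, one-sided because the alternative is an excess burden trend
#' toward rare/damaging variants (a larger slope).
#'
#' @param observed_slope Observed statistic.
#' @param null_slopes Numeric vector of null statistics.
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed_slope, null_slopes) {
  if (length(null_slopes) == 0L) stop("empty null distribution")
  (1 + sum(null_slopes >= observed_slope)) / (length(null_slopes) + 1)
}

# Per-gene qualifying allele counts across a cutoff grid:
# returns genes x cutoffs matrices of summed case / control dosages.
gene_cutoff_counts <- function(variants, genotypes, cohorts,
                               axis = c("maf", "cadd"),
                               case_set = "MS_combined", n_cutoffs = 300,
                               maf_range = c(1e-6, 0.05),
                               cadd_range = c(0, 40)) {
  axis <- match.arg(axis)
  grid <- sweep_grid(axis, n_cutoffs, maf_range, cadd_range)
  keep <- !is.na(variants$gene)
  variants <- variants[keep, , drop = FALSE]
  gm <- align_genotypes(genotypes, variants)
  cases <- case_samples(cohorts, case_set)
  controls <- control_samples(cohorts)
  a_case <- allele_counts_for(gm, cases)
  a_ctrl <- allele_counts_for(gm, controls)
  if (axis == "maf") {
    eff <- effective_ref_maf(variants$ref_af)
    mask <- outer(eff, grid, "<")
  } else {
    cadd <- ifelse(is.na(variants$cadd_phred), -Inf, variants$cadd_phred)
    mask <- outer(cadd, grid, ">")
  }
  gene <- factor(variants$gene)
  case_mat <- rowsum(mask * a_case, gene)
  ctrl_mat <- rowsum(mask * a_ctrl, gene)
  list(case = case_mat, ctrl = ctrl_mat, genes = levels(gene),
       cutoffs = grid, n_case = length(cases), n_ctrl = length(controls),
       axis = axis, case_set = case_set)
}

# slopes of relative-burden curves for many panels, vectorised through a
# sparse panel-membership matrix; counts is the gene_cutoff_counts() value
panel_slopes <- function(counts, panel_matrix) {
  n_cut <- length(counts$cutoffs)
  x <- seq(0, 1, length.out = n_cut)
  wx <- (x - mean(x)) / sum((x - mean(x))^2)
  gene_index <- match(panel_matrix, counts$genes)
  dim(gene_index) <- dim(panel_matrix)
  if (anyNA(gene_index)) stop("panel gene outside the universe")
  n_panels <- nrow(panel_matrix)
  slopes <- numeric(n_panels)
  chunk <- 10000L
  for (start in seq(1L, n_panels, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_panels)
    ind <- Matrix::sparseMatrix(
      i = rep(seq_along(rows), times = ncol(gene_index)),
      j = as.vector(gene_index[rows, , drop = FALSE]),
      x = 1,
      dims = c(length(rows), length(counts$genes))
    )
    A_case <- as.matrix(ind %*% counts$case)
    A_ctrl <- as.matrix(ind %*% counts$ctrl)
    y <- ((A_case + 0.5) / counts$n_case) /
      ((A_ctrl + 0.5) / counts$n_ctrl)
    yc <- y - rowMeans(y)
    slopes[rows] <- drop(yc %*% wx)
  }
  slopes
}

#' Monte Carlo gene-panel null for the burden-trend slope
#'
#' Computes the OLS slope of the observed panel's relative-burden curve
#' along one cutoff axis and compares it to slopes obtained for random
#' same-size gene panels drawn from the universe of genes with at least one
#' retained variant (the random panels reuse the same genotype data). The
#' one-sided empirical p-value uses the add-one convention.
#'
#' @param variants Annotated, filtered variant table.
#' @param genotypes Samples x variants dosage matrix.
#' @param cohorts Cohort design.
#' @param panel `rv_gene_panel` or character vector; genes without retained
#'   variants are ignored and the random panels match the effective size.
#' @param axis `"maf"` or `"cadd"`.
#' @param n_panels Number of random panels, default 100000.
#' @param seed Integer seed for the panel draw.
#' @param case_set Case set for the burden ratio.
#' @param n_cutoffs,maf_range,cadd_range Grid specification, see
#'   [sweep_grid()].
#' @param exclude_panel Draw the random panels from the universe with the
#'   tested panel's genes removed (default `TRUE`). With a genome-scale
#'   universe the distinction is negligible, but when the universe is
#'   small relative to the panel, overlapping draws would leak any true
#'   panel signal into the null distribution and bias the test
#'   conservative.
#' @return List of class `rv_panel_null` with `observed_slope`,
#'   `null_slopes`, `p_value`, `n_panels`, `panel_size`, `axis`, `seed`.
#' @export
panel_null_test <- function(variants, genotypes, cohorts, panel,
                            axis = c("maf", "cadd"), n_panels = 100000,
                            seed = 1, case_set = "MS_combined",
                            n_cutoffs = 300, maf_range = c(1e-6, 0.05),
                            cadd_range = c(0, 40), exclude_panel = TRUE) {
  axis <- match.arg(axis)
  counts <- gene_cutoff_counts(variants, genotypes, cohorts, axis,
                               case_set, n_cutoffs, maf_range, cadd_range)
  genes <- intersect(panel_gene_set(panel), counts$genes)
  if (length(genes) == 0L) stop("no panel gene carries a retained variant")
  observed <- panel_slopes(counts, matrix(genes, nrow = 1))
  universe <- if (exclude_panel) setdiff(counts$genes, genes)
              else counts$genes
  panels <- sample_random_panels(universe, length(genes), n_panels,
                                 seed = seed)
  null_slopes <- panel_slopes(counts, panels)
  structure(list(observed_slope = observed,
                 null_slopes = null_slopes,
                 p_value = empirical_p(observed, null_slopes),
                 n_panels = n_panels, panel_size = length(genes),
                 axis = axis, seed = seed, case_set = case_set),
            class = "rv_panel_null")
}

#' @export
print.rv_panel_null <- function(x, ...) {
  cat("<rv_panel_null>", x$axis, "axis: observed slope =",
      signif(x$observed_slope, 4), "empirical p =",
      signif(x$p_value, 3), "over", x$n_panels, "panels\n")
  invisible(x)
}
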