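# Relative case/control burden across MAF and CADD cutoff grids, the joint
# two-dimensional grid, and the selected-variant classifier.

#' Selection criteria for prioritised variants
#'
#' A protein-altering variant is *selected* when its effective reference MAF
#' is below `maf_cut` and its CADD-phred exceeds `cadd_cut`; frameshift
#' variants, which the CADD algorithm cannot score, qualify on the MAF
#' criterion alone when `frameshift_by_maf_only` is set.
#'
#' @param maf_cut MAF cutoff in `(0, 0.05]`, default `1e-5` (none, one or
#'   two alleles in a ~246,000-allele reference database).
#' @param cadd_cut CADD-phred cutoff, default 20 (top 1% most deleterious).
#' @param frameshift_by_maf_only Apply the frameshift exemption; default
#'   `TRUE`.
#' @return List of class `rv_selection_criteria`.
#' @export
selection_criteria <- function(maf_cut = 1e-5, cadd_cut = 20,
                               frameshift_by_maf_only = TRUE) {
  if (maf_cut <= 0 || maf_cut > 0.05) stop("maf_cut must lie in (0, 0.05]")
  if (cadd_cut < 0) stop("cadd_cut must be >= 0")
  structure(list(maf_cut = maf_cut, cadd_cut = cadd_cut,
                 frameshift_by_maf_only = isTRUE(frameshift_by_maf_only)),
            class = "rv_selection_criteria")
}

#' Classify variants against the selection criteria
#'
#' @param variants Annotated variant table.
#' @param criteria An [selection_criteria()] object.
#' @return Logical vector, one entry per variant, with attribute
#'   `frameshift_only` marking variants that qualified solely through the
#'   frameshift MAF rule. A missing CADD score on a consequence other than
#'   frameshift or in-frame indel is an annotation contract violation and
#'   raises an error; an in-frame indel without a CADD score cannot meet
#'   the CADD criterion and is classified not selected.
#' @export
classify_selected <- function(variants, criteria = selection_criteria()) {
  eff <- effective_ref_maf(variants$ref_af)
  cons <- variants$consequence
  bad <- is.na(variants$cadd_phred) &
    !(cons %in% cadd_optional_consequences())
  if (any(bad)) {
    stop("missing CADD-phred for non-indel consequence at: ",
         paste(variants$key[bad], collapse = ", "))
  }
  protein <- cons %in% rv_protein_altering()
  rare <- eff < criteria$maf_cut
  is_fs <- cons == "frameshift"
  damaging <- !is.na(variants$cadd_phred) &
    variants$cadd_phred > criteria$cadd_cut
  selected <- protein & rare &
    ifelse(is_fs & criteria$frameshift_by_maf_only, TRUE, damaging)
  attr(selected, "frameshift_only") <- selected & is_fs &
    criteria$frameshift_by_maf_only & !damaging
  selected
}

# per-variant summed alternate-allele dosages over a sample subset
allele_counts_for <- function(genotypes, samples) {
  colSums(genotypes[samples, , drop = FALSE], na.rm = TRUE)
}

# qualifying mask at a single (maf_cut, cadd_cut) pair; NULL disables a
# criterion. Frameshift variants without CADD qualify through the MAF
# coordinate alone when both criteria are active.
qualifying_mask <- function(variants, maf_cut = NULL, cadd_cut = NULL,
                            frameshift_by_maf_only = TRUE) {
  eff <- effective_ref_maf(variants$ref_af)
  ok <- rep(TRUE, nrow(variants))
  if (!is.null(maf_cut)) ok <- ok & eff < maf_cut
  if (!is.null(cadd_cut)) {
    pass_cadd <- !is.na(variants$cadd_phred) &
      variants$cadd_phred > cadd_cut
    if (frameshift_by_maf_only && !is.null(maf_cut)) {
      pass_cadd <- pass_cadd | (variants$consequence == "frameshift" &
                                  is.na(variants$cadd_phred))
    }
    ok <- ok & pass_cadd
  }
  ok
}

#' Relative case/control variant burden at one cutoff pair
#'
#' Sums alternate-allele dosages over qualifying variants in the case set
#' and the control cohort and forms the size-normalised ratio
#' `((A_case + 0.5) / n_case) / ((A_ctrl + 0.5) / n_ctrl)`. The 0.5
#' pseudocount keeps the ratio finite when one cohort carries no qualifying
#' alleles; the result carries attribute `pseudocount_only = TRUE` when
#' neither cohort had a qualifying allele.
#'
#' @param variants Annotated variant table.
#' @param genotypes Samples x variants dosage matrix.
#' @param cohorts Cohort design.
#' @param maf_cut,cadd_cut Cutoffs; `NULL` disables the criterion.
#' @param case_set `"MSFAM"`, `"MSS"` or `"MS_combined"`.
#' @return Numeric ratio with attributes `case_alleles` and `ctrl_alleles`.
#' @export
relative_burden <- function(variants, genotypes, cohorts,
                            maf_cut = NULL, cadd_cut = NULL,
                            case_set = "MS_combined") {
  ok <- qualifying_mask(variants, maf_cut, cadd_cut)
  cases <- case_samples(cohorts, case_set)
  controls <- control_samples(cohorts)
  gm <- align_genotypes(genotypes, variants)
  a_case <- sum(allele_counts_for(gm, cases)[ok])
  a_ctrl <- sum(allele_counts_for(gm, controls)[ok])
  ratio <- ((a_case + 0.5) / length(cases)) /
    ((a_ctrl + 0.5) / length(controls))
  structure(ratio, case_alleles = a_case, ctrl_alleles = a_ctrl,
            pseudocount_only = (a_case + a_ctrl) == 0)
}

#' Cutoff grids for the burden sweep
#'
#' MAF cutoffs are equally spaced in `log10(MAF)` between the grid bounds
#' (frequencies span several orders of magnitude, and all of the structure
#' sits at the rare end); CADD cutoffs are equally spaced linearly. Both
#' grids are returned ordered lax to stringent: descending for MAF
#' (variants qualify *below* the cutoff), ascending for CADD (variants
#' qualify *above* it).
#'
#' @param axis `"maf"` or `"cadd"`.
#' @param n Number of cutoffs, default 300.
#' @param maf_range,cadd_range Grid bounds.
#' @return Numeric vector of cutoffs ordered lax to stringent.
#' @export
sweep_grid <- function(axis = c("maf", "cadd"), n = 300,
                       maf_range = c(1e-6, 0.05), cadd_range = c(0, 40)) {
  axis <- match.arg(axis)
  if (axis == "maf") {
    if (maf_range[1] >= maf_range[2]) stop("inverted maf_range bounds")
    10^seq(log10(maf_range[2]), log10(maf_range[1]), length.out = n)
  } else {
    if (cadd_range[1] >= cadd_range[2]) stop("inverted cadd_range bounds")
    seq(cadd_range[1], cadd_range[2], length.out = n)
  }
}

#' Relative burden across a one-dimensional cutoff grid
#'
#' Evaluates [relative_burden()] at every cutoff of a MAF or CADD grid
#' (the other criterion disabled), ordered lax to stringent.
#'
#' @inheritParams relative_burden
#' @param axis `"maf"` or `"cadd"`.
#' @param n_cutoffs Grid length, default 300.
#' @param maf_range,cadd_range Grid bounds, see [sweep_grid()].
#' @return Data frame of class `rv_sweep_curve` with columns `cutoff`,
#'   `case_alleles`, `ctrl_alleles`, `relative_burden` and attributes
#'   `axis` and `case_set`.
#' @export
sweep_burden <- function(variants, genotypes, cohorts,
                         axis = c("maf", "cadd"),
                         case_set = "MS_combined", n_cutoffs = 300,
                         maf_range = c(1e-6, 0.05), cadd_range = c(0, 40)) {
  axis <- match.arg(axis)
  grid <- sweep_grid(axis, n_cutoffs, maf_range, cadd_range)
  cases <- case_samples(cohorts, case_set)
  controls <- control_samples(cohorts)
  gm <- align_genotypes(genotypes, variants)
  a_case <- allele_counts_for(gm, cases)
  a_ctrl <- allele_counts_for(gm, controls)
  if (axis == "maf") {
    eff <- effective_ref_maf(variants$ref_af)
    mask <- outer(eff, grid, "<")          # n_variants x n_cutoffs
  } else {
    cadd <- variants$cadd_phred
    mask <- outer(ifelse(is.na(cadd), -Inf, cadd), grid, ">")
  }
  A_case <- drop(crossprod(mask, a_case))
  A_ctrl <- drop(crossprod(mask, a_ctrl))
  out <- data.frame(
    cutoff = grid,
    case_alleles = A_case,
    ctrl_alleles = A_ctrl,
    relative_burden = ((A_case + 0.5) / length(cases)) /
      ((A_ctrl + 0.5) / length(controls))
  )
  attr(out, "axis") <- axis
  attr(out, "case_set") <- case_set
  class(out) <- c("rv_sweep_curve", "data.frame")
  out
}

#' Relative burden over the joint MAF x CADD grid
#'
#' Evaluates the size-normalised burden ratio over the cross product of a
#' MAF grid and a CADD grid. A variant qualifies at cell `(m, c)` when its
#' effective reference MAF is below `m` and its CADD-phred above `c`;
#' frameshift variants without a CADD score qualify through the MAF
#' coordinate alone.
#'
#' @inheritParams relative_burden
#' @param maf_grid,cadd_grid Cutoff vectors; defaults from [sweep_grid()].
#' @return Matrix of relative burdens with MAF cutoffs as rows and CADD
#'   cutoffs as columns, and attributes `case_alleles` / `ctrl_alleles`
#'   holding the corresponding count matrices.
#' @export
joint_grid <- function(variants, genotypes, cohorts,
                       maf_grid = sweep_grid("maf"),
                       cadd_grid = sweep_grid("cadd"),
                       case_set = "MS_combined") {
  cases <- case_samples(cohorts, case_set)
  controls <- control_samples(cohorts)
  gm <- align_genotypes(genotypes, variants)
  a_case <- allele_counts_for(gm, cases)
  a_ctrl <- allele_counts_for(gm, controls)
  eff <- effective_ref_maf(variants$ref_af)
  maf_mask <- outer(maf_grid, eff, ">")     # n_maf x n_variants
  cadd <- ifelse(is.na(variants$cadd_phred), -Inf, variants$cadd_phred)
  cadd_mask <- outer(cadd, cadd_grid, ">")  # n_variants x n_cadd
  fs <- variants$consequence == "frameshift" & is.na(variants$cadd_phred)
  cadd_mask[fs, ] <- TRUE
  A_case <- maf_mask %*% (a_case * cadd_mask)
  A_ctrl <- maf_mask %*% (a_ctrl * cadd_mask)
  ratio <- ((A_case + 0.5) / length(cases)) /
    ((A_ctrl + 0.5) / length(controls))
  dimnames(ratio) <- list(signif(maf_grid, 6), signif(cadd_grid, 6))
  attr(ratio, "case_alleles") <- A_case
  attr(ratio, "ctrl_alleles") <- A_ctrl
  ratio
}
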