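#' Run the full modifier-scan pipeline on a synthetic cohort
#'
#' End-to-end execution of the analysis on the outputs of
#' [simulate_cohort()]:
#' \enumerate{
#'   \item per gene, build the 30 grid candidate scores on each
#'     expression-tuning cohort's genotypes and select the best
#'     configuration by variance explained in the measured expression
#'     (covariate-residualized), retaining genes with best r2 > 1%;
#'   \item apply each retained gene's best configuration to the target
#'     cohort genotypes and standardize the score over the cohort;
#'   \item annotate CHIP calls against the driver whitelist and derive the
#'     per-sample CHIP variables;
#'   \item run the stratified scan, carry-forward rule, interaction tests
#'     and Benjamini-Hochberg FDR.
#' }
#'
#' @param cohort a `synthetic_cohort`.
#' @param grid candidate configuration grid (default [pt_grid()]).
#' @param chip_variables CHIP variables to scan (default: composite plus
#'   the common per-gene indicators present in the derived table).
#' @param min_overlap tuning overlap floor (see [evaluate_r2()]).
#' @param alpha,rule,fdr_family scan settings (see [modifier_scan()]).
#' @param vaf_min,large_vaf CHIP annotation thresholds.
#' @return list with `tuning` (per-gene tuning results), `scores`
#'   (cohort score table for retained genes), `chip_vars`, and `scan`
#'   (the `scan_result`).
#' @export
run_pipeline <- function(cohort, grid = pt_grid(), chip_variables = NULL,
                         min_overlap = 30, alpha = 0.05,
                         rule = "two_clause", fdr_family = "carried",
                         vaf_min = 0.02, large_vaf = 0.10) {
  assert_that(inherits(cohort, "synthetic_cohort"),
              "cohort must come from simulate_cohort()")
  tuning <- list()
  scores <- data.frame(sample_id = cohort$pheno$sample_id,
                       stringsAsFactors = FALSE)
  for (g in names(cohort$per_gene)) {
    pg <- cohort$per_gene[[g]]
    # overfitting guard: tuning samples must be disjoint from the cohort
    for (v in names(cohort$validation)) {
      assert_that(length(intersect(
        cohort$validation[[v]]$genotypes[[g]]$sample_ids,
        cohort$pheno$sample_id)) == 0,
        "validation samples overlap the target cohort")
    }
    cand_by_cohort <- lapply(cohort$validation, function(vs)
      build_score_grid(vs$genotypes[[g]], pg$sumstats, pg$reference,
                       grid = grid))
    vsets <- lapply(cohort$validation, function(vs)
      list(expression = vs$expression[[g]], covariates = vs$covariates))
    # evaluate every candidate in every cohort; argmax over both
    per_cohort <- lapply(names(vsets), function(v)
      select_best_score(cand_by_cohort[[v]], vsets[v],
                        min_overlap = min_overlap))
    names(per_cohort) <- names(vsets)
    best_i <- which.max(vapply(per_cohort, function(tr) tr$best_r2, 0))
    tr <- per_cohort[[best_i]]
    tr$r2_tables <- NULL
    tuning[[g]] <- tr
    if (isTRUE(tr$retained)) {
      cfg <- grid[grid$config_id == tr$best_config, , drop = FALSE]
      ss <- cis_filter(pg$sumstats)
      ss <- harmonize_alleles(ss, pg$genotypes)
      ss <- ss[is.finite(ss$beta) & is.finite(ss$pvalue), , drop = FALSE]
      cl <- clump(ss, pg$reference, cfg$r2_clump, cfg$window_bp)
      sv <- build_pt_score(pg$genotypes, ss, cl, cfg$p_thresh,
                           gene_id = g, config = cfg)
      sv <- standardize_score(sv)
      if (!sv$degenerate) scores[[g]] <- sv$values[scores$sample_id]
    }
  }
  tuning <- do.call(rbind, tuning)
  calls <- annotate_chip_variants(cohort$chip_calls, vaf_min = vaf_min)
  chip_vars <- derive_chip_variables(calls, cohort$pheno$sample_id,
                                     large_vaf = large_vaf)
  scan <- NULL
  if (ncol(scores) > 1) {
    scan <- modifier_scan(scores, chip_vars, cohort$pheno,
                          chip_variables = chip_variables,
                          alpha = alpha, rule = rule,
                          fdr_family = fdr_family)
  }
  list(tuning = tuning, scores = scores, chip_vars = chip_vars, scan = scan)
}
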