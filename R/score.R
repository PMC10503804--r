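#' Enumerate the pruning-and-thresholding candidate grid
#'
#' The Cartesian product of three clumping r2 levels (0.1, 0.01, 0.001),
#' five P-value thresholds (5e-8, 1e-5, 0.001, 0.01, 0.1) and two clumping
#' window sizes (250 kb and 5 Mb to both sides of the index variant) --
#' 30 candidate configurations per gene, in fixed (r2, p, window)
#' lexicographic order.
#'
#' @return data.frame with columns `config_id`, `r2_clump`, `p_thresh`,
#'   `window_bp`; exactly 30 rows.
#' @export
pt_grid <- function() {
  r2 <- c(0.1, 0.01, 0.001)
  p <- c(5e-8, 1e-5, 1e-3, 1e-2, 0.1)
  w <- c(250000, 5e6)
  g <- expand.grid(window_bp = w, p_thresh = p, r2_clump = r2,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("r2_clump", "p_thresh", "window_bp")]
  g$config_id <- sprintf("r2_%g|p_%g|w_%g", g$r2_clump, g$p_thresh,
                         g$window_bp)
  rownames(g) <- NULL
  g[, c("config_id", "r2_clump", "p_thresh", "window_bp")]
}

#' Restrict summary statistics to the cis window
#'
#' Keeps records within `window_bp` (default 500 kb) of the gene's
#' transcription start site, the cis definition used throughout.
#'
#' @param sumstats summary-statistic records with `pos` and `tss` columns
#'   (or supply `tss` explicitly).
#' @param tss transcription start coordinate; defaults to the records' own
#'   `tss` column.
#' @param window_bp half-width of the cis window.
#' @export
cis_filter <- function(sumstats, tss = NULL, window_bp = 5e5) {
  tss <- tss %||% sumstats$tss
  sumstats[abs(sumstats$pos - tss) <= window_bp, , drop = FALSE]
}

#' Build one pruning-and-thresholding predicted expression score
#'
#' The per-individual score is the weighted sum of counted-allele dosages,
#' `sum_j beta_j * G_ij`, over the clumped index variants whose P value is
#' strictly below `p_thresh`.  Missing dosages are mean-imputed per variant
#' from the cohort.  When no variant passes the threshold the score is an
#' all-zero vector flagged degenerate.
#'
#' @param genotypes target-cohort [dosage_matrix()], aligned to `sumstats`.
#' @param sumstats aligned summary statistics (effect allele = counted
#'   allele; see [harmonize_alleles()]).
#' @param clumped a `clump_result` whose indices are a subset of `sumstats`.
#' @param p_thresh P-value threshold (strict `<`).
#' @param gene_id gene label for the result (default from `sumstats`).
#' @param config optional one-row config data.frame recorded on the result.
#' @return an object of class `score_vector`: fields `gene_id`, `config`,
#'   `values` (named per sample), `n_variants_used`, `variant_ids`,
#'   `standardized`, `degenerate`.
#' @export
build_pt_score <- function(genotypes, sumstats, clumped, p_thresh,
                           gene_id = NULL, config = NULL) {
  assert_that(inherits(clumped, "clump_result"),
              "clumped must come from clump()")
  assert_that(all(clumped$index_variant_ids %in% sumstats$variant_id),
              "clump indices must be a subset of the summary statistics")
  gene_id <- gene_id %||% unique(sumstats$gene_id)[1]
  ss <- sumstats[match(clumped$index_variant_ids, sumstats$variant_id), ,
                 drop = FALSE]
  sel <- is.finite(ss$beta) & is.finite(ss$pvalue) & ss$pvalue < p_thresh
  ss <- ss[sel, , drop = FALSE]
  n <- nrow(genotypes$dosages)
  if (nrow(ss) == 0) {
    return(structure(list(gene_id = gene_id, config = config,
                          values = stats::setNames(rep(0, n),
                                                   genotypes$sample_ids),
                          n_variants_used = 0L, variant_ids = character(0),
                          standardized = FALSE, degenerate = TRUE),
                     class = "score_vector"))
  }
  G <- dosage_col(genotypes, ss$variant_id)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mu[j]
    }
  }
  vals <- as.numeric(G %*% ss$beta)
  structure(list(gene_id = gene_id, config = config,
                 values = stats::setNames(vals, genotypes$sample_ids),
                 n_variants_used = nrow(ss), variant_ids = ss$variant_id,
                 standardized = FALSE, degenerate = FALSE),
            class = "score_vector")
}

#' Standardize a score to zero mean and unit variance
#'
#' Uses the population (divide-by-n) standard deviation computed over the
#' stated population of samples; the standardized values are reported for
#' that population.  A constant (degenerate) score stays all-zero with the
#' degenerate flag set.  Standardization is applied per ancestry stratum in
#' the full pipeline by passing each stratum as `population`.
#'
#' @param score a `score_vector`.
#' @param population sample ids defining the standardization population
#'   (default: all samples in the score).
#' @return the standardized `score_vector`.
#' @export
standardize_score <- function(score, population = NULL) {
  assert_that(inherits(score, "score_vector"), "score must be a score_vector")
  population <- population %||% names(score$values)
  assert_that(length(population) > 0, "population must be nonempty")
  assert_that(all(population %in% names(score$values)),
              "population must be a subset of the score's samples")
  x <- score$values[population]
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) {
    score$values <- stats::setNames(rep(0, length(population)), population)
    score$degenerate <- TRUE
  } else {
    score$values <- (x - mean(x)) / s
  }
  score$standardized <- TRUE
  score
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %s | %s | %d variant(s)%s%s | n = %d\n",
              x$gene_id %||% "?",
              if (is.null(x$config)) "no config" else x$config$config_id,
              x$n_variants_used,
              if (x$standardized) " | standardized" else "",
              if (x$degenerate) " | DEGENERATE" else "",
              length(x$values)))
  invisible(x)
}

#' Build all 30 grid candidate scores for one gene
#'
#' Harmonizes the gene's cis summary statistics to the target cohort, then
#' for each grid configuration clumps against the LD reference, applies the
#' P-value threshold and accumulates the weighted dosage sum.  Clumping
#' precedes thresholding: the indicator is applied inside the clumped set.
#'
#' @param genotypes target-cohort [dosage_matrix()].
#' @param sumstats raw summary statistics for one gene.
#' @param reference LD reference [dosage_matrix()].
#' @param grid configuration grid (default [pt_grid()]).
#' @param standardize standardize each candidate over the cohort
#'   (default TRUE).
#' @param cis_window_bp cis filter half-width applied before scoring.
#' @return named list of `score_vector`s, one per config, in grid order.
#' @export
build_score_grid <- function(genotypes, sumstats, reference,
                             grid = pt_grid(), standardize = TRUE,
                             cis_window_bp = 5e5) {
  ss <- cis_filter(sumstats, window_bp = cis_window_bp)
  ss <- harmonize_alleles(ss, genotypes)
  ss <- ss[is.finite(ss$beta) & is.finite(ss$pvalue), , drop = FALSE]
  out <- vector("list", nrow(grid))
  names(out) <- grid$config_id
  clump_cache <- list()
  for (k in seq_len(nrow(grid))) {
    ckey <- sprintf("%g|%g", grid$r2_clump[k], grid$window_bp[k])
    if (is.null(clump_cache[[ckey]]))
      clump_cache[[ckey]] <- clump(ss, reference, grid$r2_clump[k],
                                   grid$window_bp[k])
    sv <- build_pt_score(genotypes, ss, clump_cache[[ckey]],
                         grid$p_thresh[k],
                         config = grid[k, , drop = FALSE])
    if (standardize) sv <- standardize_score(sv)
    out[[k]] <- sv
  }
  out
}
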