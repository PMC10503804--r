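#' Residualize measured expression on covariates
#'
#' Returns the residuals of a linear adjustment of expression on the
#' supplied covariates, re-standardized to unit (population) variance, so
#' that downstream r2 values measure the explained fraction of the
#' covariate-adjusted variance.  Collinear covariate columns are dropped
#' with a warning.  With no covariates the expression is simply
#' standardized.
#'
#' @param expression named numeric vector (names = sample ids).
#' @param covariates data.frame with `sample_id` plus covariate columns, or
#'   NULL/zero columns for no adjustment.
#' @return named numeric vector of standardized residuals, with attribute
#'   `degenerate` TRUE when the covariates absorb essentially all variance.
#' @export
residualize_expression <- function(expression, covariates = NULL) {
  ids <- names(expression)
  assert_that(!is.null(ids), "expression must be named by sample id")
  if (is.null(covariates) || ncol(covariates) <= 1) {
    out <- standardize(expression)
    names(out) <- ids
    attr(out, "degenerate") <- pop_sd(expression) == 0
    return(out)
  }
  assert_that("sample_id" %in% names(covariates),
              "covariates need a sample_id column")
  i <- match(ids, covariates$sample_id)
  assert_that(!anyNA(i), "covariate table must cover all expression samples")
  X <- covariates[i, setdiff(names(covariates), "sample_id"), drop = FALSE]
  X <- as.data.frame(lapply(X, as.numeric))
  fit <- stats::lm(expression ~ ., data = X)
  if (anyNA(stats::coef(fit)))
    warning("collinear covariate column(s) dropped in residualization")
  res <- stats::residuals(fit)
  s <- pop_sd(res)
  degenerate <- !is.finite(s) || s < 1e-8 * max(pop_sd(expression), 1e-12) ||
    s == 0
  out <- if (degenerate) rep(0, length(res)) else (res - mean(res)) / s
  names(out) <- ids
  attr(out, "degenerate") <- degenerate
  out
}

#' Variance of measured expression explained by a score
#'
#' Squared Pearson correlation between the candidate score and the
#' (adjusted) expression over the overlapping non-missing samples.  A
#' degenerate (constant) score, or an overlap below `min_overlap` samples,
#' yields r2 = 0 with an explanatory flag.
#'
#' @param score a `score_vector`.
#' @param adjusted_expression named numeric vector, e.g. from
#'   [residualize_expression()].
#' @param min_overlap minimum overlapping samples to report r2 (default 30).
#' @return numeric r2 in [0, 1] with attributes `n_overlap` and `flag`
#'   (`"ok"`, `"degenerate"` or `"insufficient_overlap"`).
#' @export
evaluate_r2 <- function(score, adjusted_expression, min_overlap = 30) {
  assert_that(inherits(score, "score_vector"), "score must be a score_vector")
  ids <- intersect(names(score$values), names(adjusted_expression))
  x <- score$values[ids]; y <- adjusted_expression[ids]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  flag <- "ok"
  r2 <- 0
  if (length(x) < min_overlap) {
    flag <- "insufficient_overlap"
  } else if (score$degenerate || pop_sd(x) == 0 || pop_sd(y) == 0) {
    flag <- "degenerate"
  } else {
    r2 <- unname(stats::cor(x, y)^2)
  }
  structure(r2, n_overlap = length(x), flag = flag)
}

#' Select the best-performing candidate score for a gene
#'
#' Evaluates every candidate configuration in every validation set
#' (e.g. a whole-blood-like and a PBMC-like expression cohort) and selects
#' the candidate with the largest r2 across all of them.  Ties break to the
#' earlier candidate in grid enumeration order.  A gene is retained when
#' its best r2 strictly exceeds 1%.
#'
#' @param candidates named list of `score_vector`s (e.g. from
#'   [build_score_grid()]).
#' @param validation_sets named list; each element is a list with elements
#'   `expression` (named numeric) and optionally `covariates` (data.frame
#'   with `sample_id`) used for residualization before evaluation.
#' @param retain_threshold retention rule on best r2 (strict `>`,
#'   default 0.01).
#' @param min_overlap passed to [evaluate_r2()].
#' @return a one-row data.frame of class `tuning_result`: `gene_id`,
#'   `best_config`, `best_cohort`, `best_r2`, `retained`, `reason`; the full
#'   config-by-cohort r2 table is attached as attribute `r2_table`.
#' @export
select_best_score <- function(candidates, validation_sets,
                              retain_threshold = 0.01, min_overlap = 30) {
  assert_that(length(candidates) >= 1, "need at least one candidate")
  assert_that(length(validation_sets) >= 1, "need at least one validation set")
  if (is.null(names(validation_sets)))
    names(validation_sets) <- paste0("cohort", seq_along(validation_sets))
  gene_id <- candidates[[1]]$gene_id
  adj <- lapply(validation_sets, function(vs) {
    residualize_expression(vs$expression, vs$covariates)
  })
  rows <- list()
  for (ci in seq_along(candidates)) {
    for (vi in seq_along(adj)) {
      r2 <- evaluate_r2(candidates[[ci]], adj[[vi]], min_overlap = min_overlap)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id,
        config_id = names(candidates)[ci] %||% as.character(ci),
        cohort = names(adj)[vi],
        r2 = as.numeric(r2),
        n_overlap = attr(r2, "n_overlap"),
        flag = attr(r2, "flag"),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  usable <- tab$flag == "ok"
  if (!any(usable)) {
    out <- data.frame(gene_id = gene_id, best_config = NA_character_,
                      best_cohort = NA_character_, best_r2 = 0,
                      retained = FALSE,
                      reason = "all candidates degenerate or unevaluable",
                      stringsAsFactors = FALSE)
  } else {
    # argmax r2; ties break to grid (then cohort) order, which is the row
    # order of the evaluation table
    best <- which(usable)[which.max(tab$r2[usable])]
    best_r2 <- tab$r2[best]
    out <- data.frame(gene_id = gene_id,
                      best_config = tab$config_id[best],
                      best_cohort = tab$cohort[best],
                      best_r2 = best_r2,
                      retained = best_r2 > retain_threshold,
                      reason = "",
                      stringsAsFactors = FALSE)
  }
  attr(out, "r2_table") <- tab
  class(out) <- c("tuning_result", class(out))
  out
}
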