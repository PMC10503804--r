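#' Default covariate adjustment set
#'
#' Age at enrollment, sex, ancestry indicator, BMI, type-2-diabetes
#' diagnosis, ever-smoker status and the first 10 genetic principal
#' components -- the adjustment used by every survival and trait model in
#' the scan.
#'
#' @return character vector of column names.
#' @export
scan_covariates <- function() {
  c("age", "sex", "ancestry", "bmi", "t2d", "smoker", paste0("pc", 1:10))
}

#' Fit a covariate-adjusted Cox proportional-hazards model
#'
#' Thin wrapper over [survival::coxph()] that assembles the model from
#' column names, restricts to complete cases on the columns used (reporting
#' the removed fraction), uses Efron tie handling by default, and returns a
#' tidy per-term coefficient table with Wald statistics and 95% CIs.
#' Non-convergence or separation (runaway coefficients) is flagged rather
#' than raised so callers can exclude the result downstream.
#'
#' @param data data.frame holding outcome, exposure and covariate columns.
#' @param terms character vector of exposure terms; interactions may be
#'   written `"a:b"` (main effects are NOT added implicitly -- pass them).
#' @param covariates adjustment columns (default [scan_covariates()];
#'   use `character(0)` for none).
#' @param time,event outcome column names.
#' @param ties tie-handling method for the partial likelihood.
#' @return data.frame, one row per model term: `term`, `loghr`, `se`, `z`,
#'   `p`, `hr`, `ci_lo`, `ci_hi`, `converged`, `n`, `n_events`; the
#'   complete-case removed fraction is attached as attribute
#'   `removed_fraction`.
#' @export
fit_cox <- function(data, terms, covariates = scan_covariates(),
                    time = "follow_time", event = "event", ties = "efron") {
  vars_in_terms <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  used <- unique(c(time, event, covariates, vars_in_terms))
  missing_cols <- setdiff(used, names(data))
  assert_that(length(missing_cols) == 0,
              paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  removed <- mean(!cc)
  d <- data[cc, used, drop = FALSE]
  assert_that(sum(d[[event]]) >= 1, "need at least one event")
  assert_that(all(d[[time]] > 0), "follow-up times must be positive")
  for (v in vars_in_terms) {
    assert_that(length(unique(as.numeric(d[[v]]))) > 1,
                paste("constant exposure term:", v))
    d[[v]] <- as.numeric(d[[v]])
  }
  rhs <- paste(c(covariates, terms), collapse = " + ")
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                ") ~ ", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = ties, model = FALSE, x = FALSE,
                    y = FALSE),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|loglik", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (anyNA(co) || any(abs(co) > 15)) converged <- FALSE
  z <- co / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(term = names(co), loghr = unname(co), se = unname(se),
                    z = unname(z), p = unname(p),
                    hr = exp(unname(co)),
                    ci_lo = exp(unname(co - 1.96 * se)),
                    ci_hi = exp(unname(co + 1.96 * se)),
                    converged = converged,
                    n = fit$n, n_events = fit$nevent,
                    stringsAsFactors = FALSE)
  attr(out, "removed_fraction") <- removed
  out
}

# one coefficient row from fit_cox, or NULL with a reason on failure
fit_term_safe <- function(data, terms, want, ...) {
  res <- tryCatch(fit_cox(data, terms, ...), error = function(e) e)
  if (inherits(res, "error")) return(list(row = NULL, reason = conditionMessage(res)))
  row <- res[res$term == want, , drop = FALSE]
  if (nrow(row) != 1) return(list(row = NULL, reason = "term not found in fit"))
  if (!row$converged) return(list(row = row, reason = "non-convergence"))
  list(row = row, reason = "")
}

#' Stratified association scan of gene scores by CHIP status
#'
#' For every (CHIP variable, gene score) pair, fits the covariate-adjusted
#' Cox model of the outcome on the standardized score separately among
#' carriers and non-carriers of the CHIP variable, reporting per-1-SD
#' hazard ratios with 95% CIs in each stratum -- the forest-plot data of
#' the modifier scan.  Strata without events, or fits that fail, are
#' recorded with a reason and skipped downstream.
#'
#' @param scores data.frame: `sample_id` plus one standardized score column
#'   per gene.
#' @param chip_vars data.frame from [derive_chip_variables()].
#' @param pheno phenotype table: `sample_id`, outcome columns and the
#'   adjustment covariates.
#' @param chip_variables CHIP variable columns to scan (default: every
#'   logical indicator in `chip_vars` except `n_drivers`).
#' @param genes gene score columns to scan (default: all non-id columns of
#'   `scores`).
#' @param covariates adjustment set (default [scan_covariates()]).
#' @param ... passed to [fit_cox()] (e.g. `time`, `event`).
#' @return data.frame of class `scan_result`, one row per pair, with
#'   stratified `hr/ci/p` fields, stratum sizes and a `note` for skipped
#'   pairs.
#' @export
stratified_scan <- function(scores, chip_vars, pheno,
                            chip_variables = NULL, genes = NULL,
                            covariates = scan_covariates(), ...) {
  chip_variables <- chip_variables %||%
    setdiff(names(chip_vars)[vapply(chip_vars, is.logical, TRUE)],
            "sample_id")
  genes <- genes %||% setdiff(names(scores), "sample_id")
  d <- merge(merge(pheno, chip_vars, by = "sample_id"), scores,
             by = "sample_id")
  rows <- list()
  for (cv in chip_variables) {
    carrier <- as.logical(d[[cv]])
    for (g in genes) {
      row <- data.frame(chip_variable = cv, gene = g,
                        n_present = sum(carrier), n_absent = sum(!carrier),
                        hr_present = NA_real_, ci_lo_present = NA_real_,
                        ci_hi_present = NA_real_, p_present = NA_real_,
                        hr_absent = NA_real_, ci_lo_absent = NA_real_,
                        ci_hi_absent = NA_real_, p_absent = NA_real_,
                        note = "", stringsAsFactors = FALSE)
      for (stratum in c("present", "absent")) {
        sub <- d[if (stratum == "present") carrier else !carrier, ,
                 drop = FALSE]
        if (nrow(sub) == 0 || sum(sub$event) < 1) {
          row$note <- paste0("empty or event-free ", stratum, " stratum")
          next
        }
        fr <- fit_term_safe(sub, g, g, covariates = covariates, ...)
        if (is.null(fr$row) || fr$reason != "") {
          row$note <- paste0(stratum, ": ", fr$reason)
          next
        }
        row[[paste0("hr_", stratum)]] <- fr$row$hr
        row[[paste0("ci_lo_", stratum)]] <- fr$row$ci_lo
        row[[paste0("ci_hi_", stratum)]] <- fr$row$ci_hi
        row[[paste0("p_", stratum)]] <- fr$row$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", class(out))
  out
}

#' Apply the carry-forward rule to stratified results
#'
#' A (CHIP variable, gene score) pair is carried forward to interaction
#' testing when the score is associated with the outcome only in the
#' presence of the CHIP variable: significant among carriers
#' (`p_present < alpha`) and, under the default two-clause reading, not
#' significant among non-carriers (`p_absent >= alpha`).  The one-clause
#' reading drops the second condition.
#'
#' @param results a `scan_result` from [stratified_scan()].
#' @param alpha significance level (default 0.05).
#' @param rule `"two_clause"` (default) or `"one_clause"`.
#' @return `results` with a logical `carried_forward` column; pairs with
#'   missing stratified P values are never carried.
#' @export
carry_forward <- function(results, alpha = 0.05,
                          rule = c("two_clause", "one_clause")) {
  rule <- match.arg(rule)
  pp <- results$p_present
  pa <- results$p_absent
  flag <- !is.na(pp) & pp < alpha
  if (rule == "two_clause") flag <- flag & !is.na(pa) & pa >= alpha
  results$carried_forward <- flag
  results
}

#' Interaction test for carried-forward pairs
#'
#' For each flagged pair, fits one covariate-adjusted Cox model containing
#' the score, the CHIP indicator and their product (the hierarchical form:
#' main effects always retained alongside the interaction) and reports the
#' product term's Wald z and P -- the heat-map statistics of the modifier
#' scan.
#'
#' @param results a `scan_result` with a `carried_forward` column.
#' @param scores,chip_vars,pheno as in [stratified_scan()].
#' @param covariates adjustment set.
#' @param which_rows `"carried"` (default) to test flagged pairs only, or
#'   `"all"`.
#' @param ... passed to [fit_cox()].
#' @return `results` with `interaction_loghr`, `interaction_se`,
#'   `interaction_z`, `interaction_p` filled for tested pairs.
#' @export
interaction_scan <- function(results, scores, chip_vars, pheno,
                             covariates = scan_covariates(),
                             which_rows = c("carried", "all"), ...) {
  which_rows <- match.arg(which_rows)
  d <- merge(merge(pheno, chip_vars, by = "sample_id"), scores,
             by = "sample_id")
  results$interaction_loghr <- NA_real_
  results$interaction_se <- NA_real_
  results$interaction_z <- NA_real_
  results$interaction_p <- NA_real_
  todo <- if (which_rows == "carried") which(results$carried_forward)
  else seq_len(nrow(results))
  for (i in todo) {
    cv <- results$chip_variable[i]; g <- results$gene[i]
    dd <- d
    dd[[cv]] <- as.numeric(dd[[cv]])
    terms <- c(g, cv, paste0(g, ":", cv))
    fr <- fit_term_safe(dd, terms, paste0(g, ":", cv),
                        covariates = covariates, ...)
    if (is.null(fr$row) || fr$reason != "") {
      results$note[i] <- paste0("interaction: ", fr$reason)
      next
    }
    results$interaction_loghr[i] <- fr$row$loghr
    results$interaction_se[i] <- fr$row$se
    results$interaction_z[i] <- fr$row$z
    results$interaction_p[i] <- fr$row$p
  }
  results
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector in [0, 1] (NAs passed through).
#' @return q-values of the same length; `q >= p` elementwise and monotone
#'   non-decreasing in sorted p.
#' @export
bh_fdr <- function(pvalues) {
  assert_that(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the full modifier scan
#'
#' Stratified associations for every (CHIP variable, gene score) pair,
#' the carry-forward rule, interaction tests for the flagged pairs, and
#' Benjamini-Hochberg FDR over the interaction P values (by default within
#' the carried-forward family).
#'
#' @inheritParams stratified_scan
#' @param alpha carry-forward significance level.
#' @param rule carry-forward rule (see [carry_forward()]).
#' @param fdr_family `"carried"` (default) or `"all"`.
#' @return a `scan_result` data.frame with stratified, carry-forward,
#'   interaction and `interaction_q` columns.
#' @export
modifier_scan <- function(scores, chip_vars, pheno,
                          chip_variables = NULL, genes = NULL,
                          covariates = scan_covariates(), alpha = 0.05,
                          rule = "two_clause", fdr_family = "carried", ...) {
  res <- stratified_scan(scores, chip_vars, pheno,
                         chip_variables = chip_variables, genes = genes,
                         covariates = covariates, ...)
  res <- carry_forward(res, alpha = alpha, rule = rule)
  res <- interaction_scan(res, scores, chip_vars, pheno,
                          covariates = covariates,
                          which_rows = if (fdr_family == "all") "all"
                          else "carried", ...)
  res$interaction_q <- NA_real_
  fam <- if (fdr_family == "all") which(!is.na(res$interaction_p))
  else which(res$carried_forward & !is.na(res$interaction_p))
  if (length(fam) > 0) res$interaction_q[fam] <- bh_fdr(res$interaction_p[fam])
  res
}
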