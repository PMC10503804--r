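#' Transform a quantitative trait for association scanning
#'
#' log2-transforms a strictly positive trait (an additive offset, e.g. +1
#' for C-reactive protein, may be applied first to avoid zeros) and
#' standardizes it to zero mean and unit variance.  Samples non-positive
#' after the offset are dropped and counted; a constant trait is flagged
#' degenerate.
#'
#' @param x numeric trait values.
#' @param offset additive offset applied before the log (default 0).
#' @return numeric vector (NA where dropped) with attributes `n_dropped`
#'   and `degenerate`.
#' @export
transform_trait <- function(x, offset = 0) {
  y <- x + offset
  bad <- !is.na(y) & y <= 0
  y[bad] <- NA
  ly <- log2(y)
  s <- pop_sd(ly)
  degenerate <- !is.finite(s) || s == 0
  out <- if (degenerate) rep(NA_real_, length(ly)) else
    (ly - mean(ly, na.rm = TRUE)) / s
  attr(out, "n_dropped") <- sum(bad)
  attr(out, "degenerate") <- degenerate
  out
}

#' Exploratory trait scan for carried-forward pairs
#'
#' For each flagged (CHIP variable, gene score) pair and each quantitative
#' trait, tests the covariate-adjusted association of the score with the
#' log2-transformed, standardized trait among carriers of the pair's CHIP
#' variable.  Traits are organized in named families (e.g. 31 hematologic
#' indexes and 5 cardiometabolic biomarkers) and Benjamini-Hochberg FDR is
#' applied within each family over all enumerated pair-by-trait tests.
#'
#' Associations use a linear model by default; `method = "cox"` instead
#' treats the (shifted-positive) transformed trait as the time scale of an
#' all-events proportional-hazards model, a rank-based reading retained for
#' comparability.
#'
#' @param pairs data.frame with `chip_variable` and `gene` columns (e.g.
#'   the carried-forward rows of a scan result).
#' @param traits data.frame: `sample_id` plus one column per trait.
#' @param trait_families named list of character vectors partitioning the
#'   trait columns into FDR families.
#' @param scores,chip_vars,pheno as in [stratified_scan()].
#' @param covariates adjustment set (default [scan_covariates()]).
#' @param offsets named numeric additive offsets per trait (e.g.
#'   `c(crp = 1)`).
#' @param method `"linear"` (default) or `"cox"`.
#' @return data.frame, one row per pair-by-trait test: `chip_variable`,
#'   `gene`, `trait`, `family`, `estimate`, `se`, `stat`, `p`, `q`, `n`,
#'   `note`; attribute `family_sizes` records the enumerated test count per
#'   family.
#' @export
trait_scan <- function(pairs, traits, trait_families, scores, chip_vars,
                       pheno, covariates = scan_covariates(),
                       offsets = c(crp = 1),
                       method = c("linear", "cox")) {
  method <- match.arg(method)
  trait_cols <- unlist(trait_families, use.names = FALSE)
  assert_that(all(trait_cols %in% names(traits)),
              "every family trait must be a column of `traits`")
  d <- merge(merge(pheno, chip_vars, by = "sample_id"), scores,
             by = "sample_id")
  d <- merge(d, traits, by = "sample_id")
  fam_of <- rep(names(trait_families), lengths(trait_families))
  names(fam_of) <- trait_cols
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    cv <- pairs$chip_variable[k]; g <- pairs$gene[k]
    sub <- d[as.logical(d[[cv]]), , drop = FALSE]
    for (tr in trait_cols) {
      row <- data.frame(chip_variable = cv, gene = g, trait = tr,
                        family = fam_of[[tr]], estimate = NA_real_,
                        se = NA_real_, stat = NA_real_, p = NA_real_,
                        n = NA_integer_, note = "",
                        stringsAsFactors = FALSE)
      off <- if (tr %in% names(offsets)) offsets[[tr]] else 0
      yt <- transform_trait(sub[[tr]], offset = off)
      y <- as.numeric(yt)
      if (isTRUE(attr(yt, "degenerate"))) {
        row$note <- "degenerate trait"
        rows[[length(rows) + 1L]] <- row
        next
      }
      use <- stats::complete.cases(sub[, c(g, covariates), drop = FALSE]) &
        !is.na(y)
      if (sum(use) < length(covariates) + 3) {
        row$note <- "insufficient samples"
        rows[[length(rows) + 1L]] <- row
        next
      }
      X <- sub[use, c(g, covariates), drop = FALSE]
      X <- as.data.frame(lapply(X, as.numeric))
      if (method == "linear") {
        fit <- stats::lm(y[use] ~ ., data = X)
        cf <- summary(fit)$coefficients
        if (!(g %in% rownames(cf))) {
          row$note <- "collinear score"
        } else {
          row$estimate <- cf[g, 1]; row$se <- cf[g, 2]
          row$stat <- cf[g, 3]; row$p <- cf[g, 4]
          row$n <- sum(use)
        }
      } else {
        tt <- y[use] - min(y[use]) + 1e-3
        X$follow_time <- tt
        X$event <- 1L
        fr <- fit_term_safe(X, g, g, covariates = covariates)
        if (is.null(fr$row) || fr$reason != "") {
          row$note <- fr$reason
        } else {
          row$estimate <- fr$row$loghr; row$se <- fr$row$se
          row$stat <- fr$row$z; row$p <- fr$row$p
          row$n <- sum(use)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (fam in names(trait_families)) {
    i <- which(out$family == fam & !is.na(out$p))
    if (length(i) > 0) out$q[i] <- bh_fdr(out$p[i])
  }
  attr(out, "family_sizes") <- stats::setNames(
    nrow(pairs) * lengths(trait_families), names(trait_families))
  out
}
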