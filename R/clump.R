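#' Squared dosage correlation between two variants
#'
#' Pairwise-complete squared Pearson correlation of allele dosages over the
#' reference samples; symmetric in its arguments.  A monomorphic variant has
#' no defined correlation and raises an error -- the clumping routine treats
#' that case as r2 = 0.
#'
#' @param reference a [dosage_matrix()].
#' @param variant_a,variant_b variant ids present in the reference.
#' @return squared correlation in [0, 1].
#' @export
ld_r2 <- function(reference, variant_a, variant_b) {
  a <- as.numeric(dosage_col(reference, variant_a))
  b <- as.numeric(dosage_col(reference, variant_b))
  ok <- !is.na(a) & !is.na(b)
  if (length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2)
    stop("undefined r2: monomorphic variant", call. = FALSE)
  unname(stats::cor(a[ok], b[ok])^2)
}

# r2 of one index column against many candidate columns, NA-safe and
# vectorized; monomorphic candidates get r2 = 0 (cannot tag anything)
ld_r2_vec <- function(reference, index_id, candidate_ids) {
  if (length(candidate_ids) == 0) return(numeric(0))
  a <- as.numeric(dosage_col(reference, index_id))
  B <- dosage_col(reference, candidate_ids)
  r <- suppressWarnings(stats::cor(a, B, use = "pairwise.complete.obs"))
  r2 <- as.numeric(r)^2
  r2[!is.finite(r2)] <- 0
  r2
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the remaining record with the smallest P value as an
#' index variant and removes every remaining record within `window_bp` of it
#' (both sides, inclusive) whose reference-panel r2 with the index is at
#' least `r2_clump`.  Ties on P value break to the lower `chrom:pos`, so the
#' result does not depend on input order.  When the records carry a
#' `log_pvalue` column the ranking uses it, preserving the significance
#' order even where the linear P has underflowed.  Records absent from the
#' reference are dropped by default (or kept unclumped with a warning).
#'
#' @param sumstats aligned summary-statistic records (finite `pvalue`).
#' @param reference the LD reference [dosage_matrix()].
#' @param r2_clump squared-correlation threshold; candidates with
#'   `r2 >= r2_clump` are absorbed.
#' @param window_bp physical window to each side of the index, inclusive.
#' @param missing_reference `"drop"` (default) or `"keep"` for records whose
#'   variant is absent from the reference panel.
#' @return list of class `clump_result` with `index_variant_ids` (retained
#'   set, in selection order) and `removed` (named character: removed
#'   variant -> absorbing index).
#' @export
clump <- function(sumstats, reference, r2_clump, window_bp,
                  missing_reference = c("drop", "keep")) {
  missing_reference <- match.arg(missing_reference)
  assert_that(all(is.finite(sumstats$pvalue)),
              "all records must carry a finite pvalue")
  in_ref <- sumstats$variant_id %in% reference$variants$variant_id
  kept_unclumped <- character(0)
  if (any(!in_ref)) {
    if (missing_reference == "keep") {
      warning(sum(!in_ref), " variant(s) absent from reference kept unclumped")
      kept_unclumped <- sumstats$variant_id[!in_ref]
    }
    sumstats <- sumstats[in_ref, , drop = FALSE]
  }
  # deterministic order: pvalue, then chrom, then position; a log-scale
  # pvalue column, when present, supplies the ranking below underflow
  rank_p <- if ("log_pvalue" %in% names(sumstats) &&
                all(is.finite(sumstats$log_pvalue)))
    sumstats$log_pvalue else sumstats$pvalue
  o <- order(rank_p, sumstats$chrom, sumstats$pos)
  ss <- sumstats[o, , drop = FALSE]
  remaining <- rep(TRUE, nrow(ss))
  index_ids <- character(0)
  removed <- character(0)
  for (i in seq_len(nrow(ss))) {
    if (!remaining[i]) next
    idx <- ss$variant_id[i]
    index_ids <- c(index_ids, idx)
    remaining[i] <- FALSE
    cand <- which(remaining & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld_r2_vec(reference, idx, ss$variant_id[cand])
      hit <- cand[r2 >= r2_clump]
      if (length(hit) > 0) {
        removed[ss$variant_id[hit]] <- idx
        remaining[hit] <- FALSE
      }
    }
  }
  structure(list(index_variant_ids = c(index_ids, kept_unclumped),
                 removed = removed),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("<clump_result> %d index variant(s), %d removed\n",
              length(x$index_variant_ids), length(x$removed)))
  invisible(x)
}
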