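#' Allele-dosage matrix with variant metadata
#'
#' A light container for individuals-by-variants allele dosages in [0, 2],
#' the shared genotype representation for the LD reference panel, the target
#' cohort, and the expression-tuning cohorts.  Dosages are stored as a plain
#' numeric matrix (samples in rows, variants in columns); variant metadata
#' records, per variant, its identifier (`chrom:pos:ref:alt`), position and
#' the counted allele -- the allele whose copies the dosage counts.
#'
#' @param dosages numeric matrix, samples x variants, values in [0, 2] or NA.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `counted_allele`; one row per column of `dosages`.
#' @param sample_ids character vector, one per row of `dosages`.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  assert_that(nrow(variants) == ncol(dosages),
              "variant metadata rows must match dosage columns")
  assert_that(length(sample_ids) == nrow(dosages),
              "sample_ids length must match dosage rows")
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "counted_allele")
  assert_that(all(need %in% names(variants)),
              paste("variants must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(variants$variant_id),
              "duplicated variant_id in metadata")
  rng <- range(dosages, na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2]")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 sample_ids = sample_ids),
            class = "dosage_matrix")
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants (chrom %s)\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

# dosage column(s) by variant id, with a clear error when absent
dosage_col <- function(x, variant_id) {
  j <- match(variant_id, x$variants$variant_id)
  if (anyNA(j)) stop("variant not present in dosage matrix: ",
                     paste(variant_id[is.na(j)], collapse = ", "), call. = FALSE)
  x$dosages[, j, drop = FALSE]
}

#' Subset a dosage matrix by variant or sample
#' @param x a `dosage_matrix`.
#' @param variants variant ids to keep (default all).
#' @param samples sample ids to keep (default all).
#' @export
subset_dosage <- function(x, variants = NULL, samples = NULL) {
  j <- if (is.null(variants)) seq_len(ncol(x$dosages)) else
    match(variants, x$variants$variant_id)
  i <- if (is.null(samples)) seq_len(nrow(x$dosages)) else
    match(samples, x$sample_ids)
  if (anyNA(j)) stop("unknown variant id in subset", call. = FALSE)
  if (anyNA(i)) stop("unknown sample id in subset", call. = FALSE)
  dosage_matrix(x$dosages[i, j, drop = FALSE],
                x$variants[j, , drop = FALSE],
                x$sample_ids[i])
}
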