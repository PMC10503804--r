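#' Harmonize summary-statistic alleles to a genotype panel
#'
#' Matches summary-statistic records to genotype variants on `chrom:pos`
#' and orients each effect to the genotype's counted allele: records whose
#' effect allele already equals the counted allele pass unchanged; records
#' with swapped alleles have their effect size negated and effect-allele
#' frequency complemented.  Strand-ambiguous variants (A/T or C/G pairs),
#' whose orientation cannot be resolved without strand information, are
#' dropped by default.  Records whose alleles match neither orientation, or
#' whose position is absent from the panel, are dropped and counted.
#'
#' @param sumstats data.frame of summary-statistic records (columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pvalue`, `eaf`, ...).
#' @param genotypes a [dosage_matrix()].
#' @param drop_ambiguous drop A/T and C/G variants (default TRUE).
#' @return the aligned subset of `sumstats`, effect alleles equal to the
#'   genotype counted allele, with an attribute `harmonization_report`
#'   counting records by fate.
#' @export
harmonize_alleles <- function(sumstats, genotypes, drop_ambiguous = TRUE) {
  if (anyDuplicated(sumstats$variant_id))
    stop("duplicated variant ids in summary statistics", call. = FALSE)
  key_ss <- paste(sumstats$chrom, sumstats$pos, sep = ":")
  v <- genotypes$variants
  key_gt <- paste(v$chrom, v$pos, sep = ":")
  if (anyDuplicated(key_gt))
    stop("duplicated chrom:pos in genotype panel", call. = FALSE)
  j <- match(key_ss, key_gt)

  fate <- rep("unmatched", nrow(sumstats))
  matched <- !is.na(j)
  counted <- v$counted_allele[j]
  other_gt <- ifelse(v$counted_allele[j] == v$alt[j], v$ref[j], v$alt[j])

  is_ambig <- function(a, b) {
    p <- paste(pmin(a, b), pmax(a, b))
    p %in% c("A T", "C G")
  }
  same <- matched & sumstats$effect_allele == counted &
    sumstats$other_allele == other_gt
  swap <- matched & sumstats$effect_allele == other_gt &
    sumstats$other_allele == counted
  fate[same] <- "kept"
  fate[swap] <- "flipped"
  fate[matched & !(same | swap)] <- "allele_mismatch"
  if (drop_ambiguous) {
    amb <- (same | swap) &
      is_ambig(sumstats$effect_allele, sumstats$other_allele)
    fate[amb] <- "ambiguous"
  }

  out <- sumstats[fate %in% c("kept", "flipped"), , drop = FALSE]
  fl <- fate[fate %in% c("kept", "flipped")] == "flipped"
  if (any(fl)) {
    out$beta[fl] <- -out$beta[fl]
    if (!is.null(out$eaf)) out$eaf[fl] <- 1 - out$eaf[fl]
    oo <- out$other_allele[fl]
    out$other_allele[fl] <- out$effect_allele[fl]
    out$effect_allele[fl] <- oo
  }
  rownames(out) <- NULL
  attr(out, "harmonization_report") <- table(factor(
    fate, levels = c("kept", "flipped", "ambiguous",
                     "allele_mismatch", "unmatched")))
  out
}
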