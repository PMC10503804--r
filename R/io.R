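# Plain-text (TSV) readers and writers for the pipeline's interchange
# formats.  All genotype matrices travel as dosage TSVs: one header row of
# variant metadata columns followed by sample rows.

#' @rdname chipmod_io
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- c("gene_id", "variant_id", "chrom", "pos", "effect_allele",
            "other_allele", "eaf", "beta", "se", "pvalue", "log_pvalue",
            "n", "tss")
  utils::write.table(sumstats[, intersect(cols, names(sumstats))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chipmod_io
#' @export
read_sumstats <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Tab-delimited interchange formats
#'
#' Readers and writers for the pipeline's on-disk formats: eQTL summary
#' statistics, genotype dosages with variant metadata, expression vectors,
#' CHIP calls, per-sample score tables and phenotype tables.  Dosage files
#' carry the variant metadata as leading columns (`variant_id`, `chrom`,
#' `pos`, `ref`, `alt`, `counted_allele`) and one column per sample.
#'
#' @param sumstats,x,expression,calls,df object to write.
#' @param path file path.
#' @name chipmod_io
#' @export
write_dosage_tsv <- function(x, path) {
  assert_that(inherits(x, "dosage_matrix"), "x must be a dosage_matrix")
  meta <- x$variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                         "counted_allele")]
  out <- cbind(meta, as.data.frame(t(x$dosages)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chipmod_io
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = c(chrom = "character"))
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "counted_allele")
  dos <- t(as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE]))
  dosage_matrix(dos, d[, meta_cols], sample_ids = rownames(dos))
}

#' @rdname chipmod_io
#' @export
write_expression <- function(expression, path) {
  utils::write.table(data.frame(sample_id = names(expression),
                                expression = as.numeric(expression)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chipmod_io
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$expression, d$sample_id)
}

#' @rdname chipmod_io
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname chipmod_io
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
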