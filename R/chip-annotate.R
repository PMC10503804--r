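#' Default CHIP driver-gene whitelist
#'
#' A versioned configuration table of putative CHIP driver genes and the
#' variant classes accepted for each, shipped with a default list of the
#' common drivers (DNMT3A, TET2, ASXL1, JAK2, SRSF2, SF3B1, TP53, PPM1D).
#' A fuller curated list (e.g. the 74-gene panels used with exome calling
#' pipelines) can be dropped in as a two-column TSV (`gene`,
#' `variant_class`) and passed wherever a whitelist is accepted.
#'
#' @param path optional path to a whitelist TSV; default is the table
#'   shipped with the package.
#' @return data.frame with columns `gene` and `variant_class`.
#' @export
chip_whitelist <- function(path = NULL) {
  path <- path %||% system.file("extdata", "chip_driver_whitelist.tsv",
                                package = "chipmod")
  wl <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene", "variant_class") %in% names(wl)),
              "whitelist needs gene and variant_class columns")
  wl
}

#' Annotate putative CHIP driver calls
#'
#' Keeps somatic calls whose gene is on the driver whitelist, whose variant
#' class satisfies the gene's rule (when the calls table carries a
#' `variant_class` column and the rule is not `"any"`), and whose variant
#' allele fraction strictly exceeds the detection threshold (default 2%).
#' Every excluded row is counted by reason in an attached report, and
#' retained plus excluded rows always account for the input.
#'
#' @param calls data.frame of somatic calls: `sample_id`, `gene`, `vaf`,
#'   optionally `protein_change` and `variant_class`.
#' @param whitelist driver whitelist (default [chip_whitelist()]).
#' @param vaf_min VAF threshold, strict `>` (default 0.02).
#' @return the retained calls, with attribute `exclusion_report` (counts by
#'   reason: `not_whitelisted`, `variant_class`, `vaf_too_low`).
#' @export
annotate_chip_variants <- function(calls, whitelist = chip_whitelist(),
                                   vaf_min = 0.02) {
  need <- c("sample_id", "gene", "vaf")
  assert_that(all(need %in% names(calls)),
              paste("calls need columns:", paste(need, collapse = ", ")))
  assert_that(is.numeric(calls$vaf) &&
                all(calls$vaf > 0 & calls$vaf <= 1, na.rm = TRUE),
              "vaf must be numeric in (0, 1]")
  reason <- rep("retained", nrow(calls))
  wl_rule <- stats::setNames(whitelist$variant_class, whitelist$gene)
  on_list <- calls$gene %in% whitelist$gene
  reason[!on_list] <- "not_whitelisted"
  if ("variant_class" %in% names(calls)) {
    rule <- wl_rule[calls$gene]
    bad_class <- on_list & !is.na(rule) & rule != "any" &
      calls$variant_class != rule
    reason[bad_class] <- "variant_class"
  }
  low <- reason == "retained" & !(calls$vaf > vaf_min)
  reason[low] <- "vaf_too_low"
  out <- calls[reason == "retained", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_report") <- table(factor(
    reason, levels = c("retained", "not_whitelisted", "variant_class",
                       "vaf_too_low")))
  out
}

#' Derive per-sample CHIP indicator variables
#'
#' Collapses annotated driver calls into the per-sample "CHIP variables"
#' used by the modifier scan: a composite carrier indicator (`has_chip`),
#' one indicator per gene of interest, a large-clone indicator
#' (`has_large_chip`, any call with VAF strictly above 10%), and the number
#' of distinct driver genes.  Samples without calls get all-FALSE
#' indicators.
#'
#' @param calls annotated calls (see [annotate_chip_variants()]).
#' @param sample_ids full cohort id list (non-carriers included).
#' @param genes genes to expose as per-gene indicators
#'   (default DNMT3A, TET2, ASXL1, JAK2).
#' @param large_vaf large-clone threshold, strict `>` (default 0.10).
#' @return data.frame: `sample_id`, `has_chip`, one logical column per
#'   gene, `has_large_chip`, `n_drivers`.
#' @export
derive_chip_variables <- function(calls, sample_ids,
                                  genes = c("DNMT3A", "TET2", "ASXL1",
                                            "JAK2"),
                                  large_vaf = 0.10) {
  assert_that(!anyDuplicated(sample_ids), "sample ids must be unique")
  unknown <- setdiff(calls$sample_id, sample_ids)
  if (length(unknown) > 0)
    stop("call(s) reference unknown sample id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  n <- length(sample_ids)
  out <- data.frame(sample_id = sample_ids, has_chip = FALSE,
                    stringsAsFactors = FALSE)
  for (g in genes) out[[g]] <- FALSE
  out$has_large_chip <- FALSE
  out$n_drivers <- 0L
  if (nrow(calls) > 0) {
    i <- match(calls$sample_id, sample_ids)
    out$has_chip[unique(i)] <- TRUE
    for (g in genes) {
      hit <- unique(i[calls$gene == g])
      if (length(hit) > 0) out[[g]][hit] <- TRUE
    }
    big <- unique(i[calls$vaf > large_vaf])
    if (length(big) > 0) out$has_large_chip[big] <- TRUE
    nd <- tapply(calls$gene, i, function(g) length(unique(g)))
    out$n_drivers[as.integer(names(nd))] <- as.integer(nd)
  }
  out
}
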