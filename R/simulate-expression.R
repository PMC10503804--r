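#' Sparse cis-eQTL architecture for one gene
#'
#' Records which variants causally drive a gene's expression and how much of
#' the expression variance the genetic component explains (the cis
#' heritability h2).  Causal variants must lie within the cis window around
#' the transcription start site.
#'
#' @param gene_id gene symbol.
#' @param causal_variant_ids character vector of variant ids.
#' @param causal_effects numeric true effects on standardized expression,
#'   one per causal variant.
#' @param h2 cis heritability in [0, 1).
#' @param tss transcription start coordinate (1-based bp).
#' @param cis_window_bp half-width of the cis window (default 500 kb).
#' @return an object of class `eqtl_architecture`.
#' @export
eqtl_architecture <- function(gene_id, causal_variant_ids, causal_effects,
                              h2, tss, cis_window_bp = 5e5) {
  assert_that(length(causal_variant_ids) == length(causal_effects),
              "one effect per causal variant required")
  assert_that(h2 >= 0 && h2 < 1, "h2 must lie in [0, 1)")
  structure(list(gene_id = gene_id,
                 causal_variant_ids = causal_variant_ids,
                 causal_effects = causal_effects,
                 h2 = h2, tss = tss, cis_window_bp = cis_window_bp),
            class = "eqtl_architecture")
}

# standardized genetic value for an architecture over a genotype panel;
# all-causal-effects-zero (or h2 = 0) yields exact zeros
genetic_value <- function(genotypes, arch) {
  miss <- setdiff(arch$causal_variant_ids, genotypes$variants$variant_id)
  if (length(miss) > 0)
    stop("causal variant(s) absent from genotypes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- as.numeric(dosage_col(genotypes, arch$causal_variant_ids) %*%
                    arch$causal_effects)
  standardize(g)
}

#' Simulate expression from genotypes under a cis-eQTL architecture
#'
#' Expression is `sqrt(h2) * g + sqrt(1 - h2) * e`, where `g` is the
#' standardized genetic value (dosages of the causal variants weighted by
#' their true effects) and `e` is standard-normal noise, so the population
#' variance is approximately 1 and the genetic component explains h2 of it.
#'
#' @param genotypes a [dosage_matrix()] containing all causal variants.
#' @param arch an [eqtl_architecture()].
#' @param seed integer seed.
#' @return named numeric vector of expression values (names = sample ids).
#' @export
simulate_expression <- function(genotypes, arch, seed) {
  assert_that(inherits(arch, "eqtl_architecture"),
              "arch must be an eqtl_architecture")
  g <- genetic_value(genotypes, arch)
  set.seed(fan_seed(seed, 23L))
  n <- length(g)
  e <- stats::rnorm(n)
  stats::setNames(sqrt(arch$h2) * g + sqrt(1 - arch$h2) * e,
                  genotypes$sample_ids)
}

#' Simulate external cis-eQTL summary statistics
#'
#' Emulates the role of a large external eQTL consortium: an independent
#' panel of `n_external` individuals is simulated under the same LD
#' structure and architecture, expression is generated, and each cis variant
#' is tested by simple marginal regression of expression on dosage.  One
#' record per variant is returned with the estimated effect, its standard
#' error, P value, effect-allele frequency and the effect allele stated
#' explicitly.  Monomorphic variants yield a record with missing effect
#' fields so downstream stages can drop them.
#'
#' @param spec the [ld_block_spec()] describing the region.
#' @param arch the [eqtl_architecture()] for the gene.
#' @param n_external external panel size (>= 100).
#' @param seed integer seed.
#' @return data.frame of summary-statistic records with columns `gene_id`,
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`, `tss`.
#' @export
simulate_external_sumstats <- function(spec, arch, n_external, seed) {
  assert_that(n_external >= 100, "n_external must be >= 100")
  panel <- simulate_ld_panel(spec, 2L * n_external, seed = fan_seed(seed, 31L))
  expr <- simulate_expression(panel, arch, seed = fan_seed(seed, 37L))
  G <- panel$dosages
  n <- nrow(G)
  gm <- colMeans(G)
  sxx <- colSums(G^2) - n * gm^2
  mono <- sxx <= 0
  em <- mean(expr)
  sxy <- as.numeric(crossprod(G, expr)) - n * gm * em
  syy <- sum(expr^2) - n * em^2
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  sse <- syy - beta^2 * sxx
  se <- ifelse(mono, NA_real_, sqrt(pmax(sse, 0) / (n - 2) / sxx))
  tstat <- beta / se
  # natural-log P retains ranking information far below double underflow;
  # the linear P is floored to the smallest positive double so it stays
  # inside its contractual (0, 1] range
  log_pvalue <- ifelse(mono, NA_real_,
                       log(2) + stats::pt(abs(tstat), df = n - 2,
                                          lower.tail = FALSE, log.p = TRUE))
  pvalue <- pmax(exp(log_pvalue), .Machine$double.xmin)
  pvalue[mono] <- NA_real_
  v <- panel$variants
  data.frame(gene_id = arch$gene_id,
             variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
             effect_allele = v$counted_allele,
             other_allele = ifelse(v$counted_allele == v$alt, v$ref, v$alt),
             eaf = gm / 2,
             beta = beta, se = se, pvalue = pvalue,
             log_pvalue = log_pvalue,
             n = n, tss = unname(arch$tss),
             stringsAsFactors = FALSE)
}
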