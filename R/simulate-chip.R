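#' Default per-gene CHIP carrier probabilities
#'
#' Marginal probabilities that a random cohort member carries a driver
#' mutation in each gene.  Defaults reproduce a composite carrier prevalence
#' of 6.2% with the driver-gene mix of a large biobank (DNMT3A 55.4%, TET2
#' 19.9%, ASXL1 9.1%, JAK2 1.0% of carriers, remainder split across the
#' less frequent whitelisted drivers SRSF2, SF3B1, TP53 and PPM1D); the
#' shares sum to 1.074 because 7.4% of carriers hold a second driver.
#'
#' @param composite_prevalence overall carrier fraction.
#' @return named numeric vector of per-gene carrier probabilities.
#' @export
chip_default_prevalences <- function(composite_prevalence = 0.062) {
  share <- c(DNMT3A = 0.554, TET2 = 0.199, ASXL1 = 0.091, JAK2 = 0.010,
             SRSF2 = 0.055, SF3B1 = 0.055, TP53 = 0.055, PPM1D = 0.055)
  composite_prevalence * share
}

#' Default gene-specific VAF distributions
#'
#' Variant allele fractions are drawn as `0.02 + 0.98 * Beta(a, b)`, i.e. a
#' Beta distribution truncated to (0.02, 1], so every emitted call clears
#' the 2% detection threshold by construction.  Most drivers use a
#' right-skewed Beta(1, 6) (about 60% of clones exceed the 10% large-clone
#' threshold); JAK2 uses Beta(3, 6.65), concentrated above 10% so that about
#' 97% of JAK2 carriers harbor large clones, matching the near-universal
#' clonal dominance of JAK2-mutant hematopoiesis.
#'
#' @return named list of `c(shape1, shape2)` pairs with a `.default` entry.
#' @export
chip_default_vaf_shapes <- function() {
  list(.default = c(1, 6), JAK2 = c(3, 6.65))
}

#' Simulate CHIP carrier status and driver calls
#'
#' Assigns carrier status, driver gene(s) and clone size (VAF) per
#' individual.  An individual is a carrier with probability
#' `sum(prevalences) / (1 + multi_driver_prob)`; carriers hold a second
#' driver with probability `multi_driver_prob` (default 7.4%, i.e. 92.6%
#' single-driver), genes drawn without replacement proportional to
#' `prevalences`.  VAFs come from gene-specific truncated Beta
#' distributions; JAK2 calls are labelled p.V617F with probability 89.5%.
#'
#' @param n_individuals cohort size.
#' @param prevalences named per-gene carrier probabilities
#'   (default [chip_default_prevalences()]).
#' @param vaf_shapes named list of Beta shape pairs
#'   (default [chip_default_vaf_shapes()]).
#' @param multi_driver_prob probability a carrier holds two drivers.
#' @param vaf_min detection floor for emitted VAFs (strictly exceeded).
#' @param seed integer seed.
#' @param sample_ids optional explicit ids (default S1..Sn).
#' @return data.frame of calls: `sample_id`, `gene`, `protein_change`,
#'   `vaf`; zero rows when all prevalences are zero.
#' @export
simulate_chip_status <- function(n_individuals,
                                 prevalences = chip_default_prevalences(),
                                 vaf_shapes = chip_default_vaf_shapes(),
                                 multi_driver_prob = 0.074,
                                 vaf_min = 0.02,
                                 seed = 1,
                                 sample_ids = NULL) {
  assert_that(all(prevalences >= 0 & prevalences <= 1),
              "prevalences must lie in [0, 1]")
  assert_that(multi_driver_prob >= 0 && multi_driver_prob < 1,
              "multi_driver_prob must lie in [0, 1)")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_individuals))
  set.seed(fan_seed(seed, 41L))
  empty <- data.frame(sample_id = character(), gene = character(),
                      protein_change = character(), vaf = numeric(),
                      stringsAsFactors = FALSE)
  p_comp <- sum(prevalences) / (1 + multi_driver_prob)
  if (p_comp <= 0) return(empty)
  carrier <- stats::runif(n_individuals) < p_comp
  idx <- which(carrier)
  if (length(idx) == 0) return(empty)
  n_drivers <- 1L + stats::rbinom(length(idx), 1L, multi_driver_prob)
  genes <- names(prevalences)
  w <- prevalences / sum(prevalences)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    g <- sample(genes, n_drivers[k], replace = FALSE, prob = w)
    rows[[k]] <- data.frame(sample_id = sample_ids[idx[k]], gene = g,
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  shape_for <- function(g) vaf_shapes[[g]] %||% vaf_shapes[[".default"]]
  sh <- t(vapply(calls$gene, shape_for, numeric(2)))
  u <- stats::rbeta(nrow(calls), sh[, 1], sh[, 2])
  calls$vaf <- pmin(vaf_min + (1 - vaf_min) * pmax(u, 1e-6), 1)
  calls$protein_change <- ifelse(
    calls$gene == "JAK2" & stats::runif(nrow(calls)) < 0.895,
    "p.V617F", "p.?")
  calls[, c("sample_id", "gene", "protein_change", "vaf")]
}
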