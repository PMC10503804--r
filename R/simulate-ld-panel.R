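#' Specification of an LD-block genotype region
#'
#' Describes a simulated cis region as a sequence of haplotype blocks.
#' Variants inside a block share a target pairwise haplotype correlation;
#' variants in different blocks are independent.  One minor-allele frequency
#' is drawn per block (tightly linked variants carry near-identical allele
#' frequencies, and a shared frequency is what makes a high target
#' correlation attainable for thresholded alleles).
#'
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param within_block_corr target pairwise haplotype (allele) correlation in
#'   [0, 1) for variants in the same block.
#' @param maf_range minor-allele-frequency interval; one MAF per block is
#'   drawn uniformly from it.
#' @param chrom chromosome label for all variants.
#' @param start_pos 1-based physical coordinate of the first variant.
#' @param spacing_bp inter-variant spacing in base pairs.
#' @param tss named numeric vector of transcription start coordinates, one
#'   per simulated gene; defaults to a single gene at the region midpoint.
#' @return an object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(n_blocks = 5, block_size = 10,
                          within_block_corr = 0.9,
                          maf_range = c(0.05, 0.5),
                          chrom = "1", start_pos = 1e6, spacing_bp = 5000,
                          tss = NULL) {
  assert_that(n_blocks >= 1 && block_size >= 1, "need >= 1 block and variant")
  assert_that(within_block_corr >= 0 && within_block_corr < 1,
              "within_block_corr must lie in [0, 1)")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 &&
                maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "maf_range must be an interval inside (0, 0.5]")
  assert_that(spacing_bp >= 1, "spacing must be positive")
  m <- n_blocks * block_size
  positions <- start_pos + spacing_bp * (seq_len(m) - 1L)
  if (is.null(tss)) {
    tss <- stats::setNames(positions[ceiling(m / 2)], "GENE1")
  }
  # ref/alt labels are part of the region's identity, shared by every panel
  # simulated from this spec; drawn deterministically from the spec shape.
  # Alt never complements ref: strand-ambiguous (A/T, C/G) sites are absent,
  # as in a QC'd imputation panel, so harmonization is orientation-exact.
  set.seed(fan_seed(1701L + sum(utf8ToInt(as.character(chrom))), m + n_blocks))
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, c(r, comp[[r]])), 1L),
                "", USE.NAMES = FALSE)
  block_maf <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  structure(list(n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 within_block_corr = within_block_corr,
                 maf_range = maf_range, chrom = as.character(chrom),
                 positions = positions, spacing_bp = spacing_bp,
                 ref = ref, alt = alt, block_maf = block_maf, tss = tss),
            class = "ld_block_spec")
}

# Latent Gaussian correlation that yields a given Pearson (phi) correlation
# between two alleles thresholded at frequency f.  Solved numerically from
# the bivariate-normal orthant probability (1-D quadrature, then uniroot).
latent_corr_for_phi <- function(phi_target, f) {
  if (phi_target <= 0) return(0)
  t <- stats::qnorm(1 - f)
  phi_of <- function(rho) {
    if (rho >= 1) return(1)
    p11 <- stats::integrate(function(z) {
      stats::dnorm(z) * stats::pnorm((rho * z - t) / sqrt(1 - rho^2))
    }, t, Inf, rel.tol = 1e-9)$value
    (p11 - f^2) / (f * (1 - f))
  }
  if (phi_of(0.999999) <= phi_target) return(0.999999)
  stats::uniroot(function(r) phi_of(r) - phi_target,
                 c(0, 0.999999), tol = 1e-7)$root
}

#' Simulate an LD-structured diploid genotype panel
#'
#' Draws haplotypes from a Gaussian-copula block model: within a block,
#' latent normals share an exchangeable correlation calibrated so that the
#' thresholded alleles attain the target pairwise correlation of the spec;
#' blocks are mutually independent.  Two haplotypes are paired per
#' individual, so dosages count copies of the alternate (minor) allele.
#' Reference and alternate alleles are assigned per variant so that
#' downstream allele harmonization (including strand-ambiguous A/T and C/G
#' pairs) is exercised on realistic metadata.
#'
#' @param spec an [ld_block_spec()].
#' @param n_haplotypes even number of haplotypes (2 per individual).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return a [dosage_matrix()] with `n_haplotypes / 2` samples.
#' @export
simulate_ld_panel <- function(spec, n_haplotypes, seed) {
  assert_that(inherits(spec, "ld_block_spec"), "spec must be an ld_block_spec")
  assert_that(n_haplotypes >= 2 && n_haplotypes %% 2 == 0,
              "n_haplotypes must be even and >= 2")
  set.seed(fan_seed(seed, 11L))
  m <- spec$n_blocks * spec$block_size
  block_maf <- spec$block_maf
  haps <- matrix(0L, nrow = n_haplotypes, ncol = m)
  for (b in seq_len(spec$n_blocks)) {
    f <- block_maf[b]
    rho <- latent_corr_for_phi(spec$within_block_corr, f)
    cols <- (b - 1L) * spec$block_size + seq_len(spec$block_size)
    shared <- stats::rnorm(n_haplotypes)
    z <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(n_haplotypes * spec$block_size),
                             n_haplotypes, spec$block_size)
    haps[, cols] <- (z > stats::qnorm(1 - f)) + 0L
  }
  dos <- haps[seq(1, n_haplotypes, by = 2), , drop = FALSE] +
    haps[seq(2, n_haplotypes, by = 2), , drop = FALSE]

  variants <- data.frame(
    variant_id = paste(spec$chrom, spec$positions, spec$ref, spec$alt,
                       sep = ":"),
    chrom = spec$chrom, pos = spec$positions, ref = spec$ref, alt = spec$alt,
    counted_allele = spec$alt,
    block = rep(seq_len(spec$n_blocks), each = spec$block_size),
    maf = rep(block_maf, each = spec$block_size),
    stringsAsFactors = FALSE)
  dosage_matrix(dos, variants)
}
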