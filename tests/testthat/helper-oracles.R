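# Independent oracles and tiny fixture builders used across the suite.
# Each oracle is a literal transcription of the rule it checks and never
# calls the implementation it is compared against.

`%||%` <- function(a, b) if (is.null(a)) b else a

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# --- fixtures -----------------------------------------------------------

# hand-built dosage matrix from an explicit matrix and positions
toy_dosage <- function(dos, pos, chrom = "1", ref = NULL, alt = NULL) {
  m <- ncol(dos)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("C", m)
  dosage_matrix(dos, data.frame(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = pos, ref = ref, alt = alt, counted_allele = alt,
    stringsAsFactors = FALSE))
}

# sumstats rows aligned to a toy dosage matrix
toy_sumstats <- function(geno, beta, pvalue, gene_id = "G1",
                         eaf = NULL, tss = NULL) {
  v <- geno$variants
  data.frame(gene_id = gene_id, variant_id = v$variant_id, chrom = v$chrom,
             pos = v$pos, effect_allele = v$counted_allele,
             other_allele = ifelse(v$counted_allele == v$alt, v$ref, v$alt),
             eaf = eaf %||% colMeans(geno$dosages) / 2,
             beta = beta, se = abs(beta) / 2 + 0.05, pvalue = pvalue,
             n = nrow(geno$dosages), tss = tss %||% round(mean(v$pos)),
             stringsAsFactors = FALSE)
}

# random clumping instance: <= max_m variants on one chromosome with some
# correlated columns, random pvalues (occasionally tied) and positions
random_clump_instance <- function(max_m = 12, n_ref = 60) {
  m <- sample(1:max_m, 1)
  pos <- sort(sample(1:2e6, m))
  base <- matrix(rbinom(n_ref * m, 2, runif(m, 0.2, 0.5)), n_ref, m,
                 byrow = TRUE)
  # make some columns near-copies of earlier ones to create high r2
  for (j in seq_len(m)[-1]) {
    if (runif(1) < 0.4) {
      src <- sample(j - 1, 1)
      flip <- rbinom(n_ref, 1, 0.1)
      base[, j] <- pmax(pmin(base[, src] + flip - rbinom(n_ref, 1, 0.1), 2), 0)
    }
  }
  geno <- toy_dosage(base, pos)
  p <- signif(runif(m), 2)            # 2 significant digits => ties happen
  if (m > 1 && runif(1) < 0.3) p[2] <- p[1]
  ss <- toy_sumstats(geno, beta = rnorm(m), pvalue = p)
  list(geno = geno, ss = ss,
       r2 = sample(c(0.1, 0.01, 0.5), 1),
       window = sample(c(5e4, 5e5, 5e6), 1))
}

# --- oracles ------------------------------------------------------------

# pairwise r2 computed straight from cor(); monomorphic treated as 0
oracle_r2 <- function(geno, a, b) {
  x <- geno$dosages[, a]; y <- geno$dosages[, b]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
  cor(x, y)^2
}

# literal greedy clumping definition: sort by (p, chrom, pos); take head as
# index; delete everything within the window with r2 >= threshold; repeat
oracle_clump <- function(ss, geno, r2_clump, window_bp) {
  o <- order(ss$pvalue, ss$chrom, ss$pos)
  rem <- ss[o, , drop = FALSE]
  kept <- character(0)
  while (nrow(rem) > 0) {
    idx <- rem[1, ]
    kept <- c(kept, idx$variant_id)
    drop <- logical(nrow(rem))
    drop[1] <- TRUE
    for (k in seq_len(nrow(rem))[-1]) {
      if (rem$chrom[k] == idx$chrom &&
          abs(rem$pos[k] - idx$pos) <= window_bp &&
          oracle_r2(geno, idx$variant_id, rem$variant_id[k]) >= r2_clump)
        drop[k] <- TRUE
    }
    rem <- rem[!drop, , drop = FALSE]
  }
  kept
}

# literal weighted-allele-count sum with the strict p indicator
oracle_pt_score <- function(geno, ss, kept_ids, p_thresh) {
  out <- rep(0, nrow(geno$dosages))
  for (vid in kept_ids) {
    r <- ss[ss$variant_id == vid, ]
    if (is.finite(r$beta) && is.finite(r$pvalue) && r$pvalue < p_thresh) {
      g <- geno$dosages[, vid]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      out <- out + r$beta * g
    }
  }
  unname(out)
}

# step-up BH transcription: q_(i) = min_{j >= i} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-clause carry-forward transcription
oracle_carry <- function(pp, pa, alpha = 0.05) {
  !is.na(pp) & pp < alpha & !is.na(pa) & pa >= alpha
}

# fast exponential survival generator for calibration loops (no package
# code; used to test the scan against data it did not generate)
oracle_survival <- function(lp, rate, horizon) {
  t0 <- rexp(length(lp), rate * exp(lp))
  data.frame(follow_time = pmax(pmin(t0, horizon), 1e-6),
             event = as.integer(t0 <= horizon))
}
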