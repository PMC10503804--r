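test_that("the candidate grid has the 30 stated members in fixed order", {
  g <- pt_grid()
  expect_equal(nrow(g), 30)
  expect_equal(nrow(unique(g[, c("r2_clump", "p_thresh", "window_bp")])), 30)
  expect_setequal(unique(g$r2_clump), c(0.1, 0.01, 0.001))
  expect_setequal(unique(g$p_thresh), c(5e-8, 1e-5, 1e-3, 1e-2, 0.1))
  expect_setequal(unique(g$window_bp), c(250000, 5e6))
  # first element under (r2, p, window) lexicographic order
  expect_equal(g$r2_clump[1], 0.1)
  expect_equal(g$p_thresh[1], 5e-8)
  expect_equal(g$window_bp[1], 250000)
})

test_that("hand-worked 3-variant score evaluates to 0.8", {
  geno <- toy_dosage(rbind(c(2, 1, 2), c(0, 2, 1)),
                     pos = c(100, 200, 300))
  ss <- toy_sumstats(geno, beta = c(0.5, -0.2, 0.1),
                     pvalue = c(1e-9, 1e-6, 0.5))
  cl <- clump(ss, geno, r2_clump = 1.1, window_bp = 0)  # keep all three
  expect_length(cl$index_variant_ids, 3)
  sv <- build_pt_score(geno, ss, cl, p_thresh = 1e-3)
  expect_equal(unname(sv$values[1]), 0.5 * 2 + (-0.2) * 1)  # = 0.8
  expect_equal(sv$n_variants_used, 2)  # third variant fails the threshold
  expect_false(sv$degenerate)
})

test_that("no passing variant yields an all-zero degenerate score", {
  geno <- toy_dosage(rbind(c(2, 1), c(0, 2), c(1, 1)), pos = c(100, 200))
  ss <- toy_sumstats(geno, beta = c(0.5, 0.2), pvalue = c(0.5, 0.9))
  cl <- clump(ss, geno, 1.1, 0)
  sv <- build_pt_score(geno, ss, cl, p_thresh = 1e-3)
  expect_true(sv$degenerate)
  expect_true(all(sv$values == 0))
  expect_equal(sv$n_variants_used, 0)
  # all-zero weights also give an all-zero score
  ss0 <- toy_sumstats(geno, beta = c(0, 0), pvalue = c(1e-9, 1e-9))
  sv0 <- build_pt_score(geno, ss0, clump(ss0, geno, 1.1, 0), 1e-3)
  expect_true(all(sv0$values == 0))
})

test_that("the p threshold indicator is strictly less-than", {
  geno <- toy_dosage(rbind(c(2, 2), c(0, 1), c(1, 0)), pos = c(100, 200))
  ss <- toy_sumstats(geno, beta = c(0.5, 0.3), pvalue = c(0.01, 0.005))
  cl <- clump(ss, geno, 1.1, 0)
  sv <- build_pt_score(geno, ss, cl, p_thresh = 0.01)
  expect_equal(sv$n_variants_used, 1)      # p = 0.01 excluded at p_r = 0.01
  expect_equal(sv$variant_ids, geno$variants$variant_id[2])
})

test_that("scores are linear in the effect sizes", {
  set.seed(10)
  geno <- toy_dosage(matrix(rbinom(40, 2, 0.4), 8, 5),
                     pos = seq(100, 500, by = 100))
  b1 <- rnorm(5); b2 <- rnorm(5)
  p <- runif(5, 0, 1e-4)
  cl <- clump(toy_sumstats(geno, b1, p), geno, 1.1, 0)
  s1 <- build_pt_score(geno, toy_sumstats(geno, b1, p), cl, 0.1)
  s2 <- build_pt_score(geno, toy_sumstats(geno, b2, p), cl, 0.1)
  s12 <- build_pt_score(geno, toy_sumstats(geno, b1 + b2, p), cl, 0.1)
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-12)
})

test_that("raising the p threshold never drops variants", {
  set.seed(11)
  for (i in 1:25) {
    inst <- random_clump_instance()
    cl <- clump(inst$ss, inst$geno, inst$r2, inst$window)
    used <- vapply(c(5e-8, 1e-5, 1e-3, 1e-2, 0.1, 1), function(pt)
      build_pt_score(inst$geno, inst$ss, cl, pt)$n_variants_used, 0L)
    expect_true(all(diff(used) >= 0))
  }
})

test_that("missing dosages are mean-imputed per variant", {
  dos <- rbind(c(2, 1), c(NA, 1), c(0, 1))
  geno <- toy_dosage(dos, pos = c(100, 200))
  ss <- toy_sumstats(geno, beta = c(1, 0), pvalue = c(1e-9, 1e-9))
  sv <- build_pt_score(geno, ss, clump(ss, geno, 1.1, 0), 0.1)
  expect_equal(unname(sv$values[2]), 1)    # imputed to mean(2, 0) = 1
})

test_that("standardization uses population SD on the stated population", {
  geno <- toy_dosage(matrix(c(1, 2, 3) / 3 * 2, 3, 1), pos = 100)
  ss <- toy_sumstats(geno, beta = 1.5, pvalue = 1e-9)
  sv <- build_pt_score(geno, ss, clump(ss, geno, 1.1, 0), 0.1)
  sv$values <- setNames(c(1, 2, 3), names(sv$values))  # worked example
  z <- standardize_score(sv)
  expect_equal(unname(z$values), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_true(z$standardized)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  # per-stratum standardization uses only the stated population
  sv2 <- sv
  z2 <- standardize_score(sv2, population = names(sv$values)[1:2])
  expect_equal(unname(z2$values), c(-1, 1))
  # constant score degenerates to zeros
  svc <- sv; svc$values[] <- 5
  zc <- standardize_score(svc)
  expect_true(zc$degenerate)
  expect_true(all(zc$values == 0))
  expect_error(standardize_score(sv, population = character(0)), "nonempty")
})

test_that("build_score_grid returns 30 standardized candidates", {
  spec <- ld_block_spec(n_blocks = 2, block_size = 4,
                        within_block_corr = 0.7, maf_range = c(0.2, 0.5))
  ref <- simulate_ld_panel(spec, 300, seed = 12)
  arch <- eqtl_architecture("G1", ref$variants$variant_id[3], 1, 0.3,
                            tss = spec$tss)
  ss <- simulate_external_sumstats(spec, arch, 2000, seed = 13)
  geno <- simulate_ld_panel(spec, 400, seed = 14)
  cand <- build_score_grid(geno, ss, ref)
  expect_length(cand, 30)
  expect_identical(names(cand), pt_grid()$config_id)
  ok <- !vapply(cand, `[[`, TRUE, "degenerate")
  expect_true(any(ok))
  for (sv in cand[ok]) {
    expect_equal(mean(sv$values), 0, tolerance = 1e-10)
    expect_equal(pop_sd_oracle(sv$values), 1, tolerance = 1e-10)
  }
})
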