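# small but non-trivial cohort for fit checks
mk_scan_cohort <- function(n = 6000, seed = 40, carrier_p = 0.2,
                           beta_carrier = 0, beta_noncarrier = 0,
                           beta_inter = NULL, rate = 0.012, horizon = 10) {
  set.seed(seed)
  cov <- simulate_covariates(n, seed = seed)
  chip <- data.frame(sample_id = cov$sample_id,
                     has_chip = runif(n) < carrier_p)
  scores <- data.frame(sample_id = cov$sample_id, G1 = rnorm(n))
  b <- ifelse(chip$has_chip, beta_carrier, beta_noncarrier)
  if (!is.null(beta_inter))
    b <- beta_noncarrier + beta_inter * chip$has_chip
  out <- oracle_survival(b * scores$G1, rate, horizon)
  pheno <- cbind(cov, out)
  list(pheno = pheno, chip = chip, scores = scores)
}

test_that("fit_cox recovers a two-group exponential rate ratio of 2", {
  set.seed(41)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  d <- data.frame(x = x, oracle_survival(log(2) * x, 0.05, 8))
  fit <- fit_cox(d, terms = "x", covariates = character(0))
  expect_equal(nrow(fit), 1)
  expect_true(fit$converged)
  expect_gt(2, fit$ci_lo)
  expect_lt(2, fit$ci_hi)
  expect_equal(fit$hr, 2, tolerance = 0.15)
})

test_that("fit_cox null z statistics are standard normal across replicates", {
  set.seed(42)
  z <- vapply(1:300, function(i) {
    n <- 600
    x <- rnorm(n)
    d <- data.frame(x = x, oracle_survival(rep(0, n), 0.03, 10))
    fit_cox(d, "x", covariates = character(0))$z
  }, 0)
  rej <- mean(abs(z) > 1.96)
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
  expect_equal(mean(z), 0, tolerance = 0.12)
  expect_lt(abs(sd(z) - 1), 0.12)
})

test_that("fit_cox reports complete-case removal and validates inputs", {
  set.seed(43)
  cc <- mk_scan_cohort(n = 1000)
  d <- merge(cc$pheno, cc$scores, by = "sample_id")
  d$bmi[1:30] <- NA
  fit <- fit_cox(d, "G1")
  expect_equal(attr(fit, "removed_fraction"), 0.03, tolerance = 1e-12)
  expect_equal(fit[fit$term == "G1", "n"], 970)
  d$G1 <- 1
  expect_error(fit_cox(d, "G1"), "constant exposure")
  expect_error(fit_cox(d[d$event == 2, ], "bmi"), "at least one event")
})

test_that("stratified scan estimates per-stratum per-SD hazard ratios", {
  cc <- mk_scan_cohort(n = 12000, seed = 44, beta_carrier = log(1.6),
                       beta_noncarrier = 0)
  res <- stratified_scan(cc$scores, cc$chip, cc$pheno)
  expect_s3_class(res, "scan_result")
  expect_equal(nrow(res), 1)
  expect_equal(res$hr_present, 1.6, tolerance = 0.12)
  expect_equal(res$hr_absent, 1.0, tolerance = 0.08)
  expect_lt(res$p_present, 0.05)
  expect_true(res$ci_lo_present < res$hr_present &
                res$hr_present < res$ci_hi_present)
  # permuting sample order leaves estimates unchanged
  perm <- sample(nrow(cc$pheno))
  res2 <- stratified_scan(cc$scores[perm, ], cc$chip, cc$pheno[perm, ])
  expect_equal(res2$hr_present, res$hr_present, tolerance = 1e-10)
})

test_that("empty or event-free strata are skipped with a reason", {
  cc <- mk_scan_cohort(n = 500, seed = 45, carrier_p = 0)
  res <- stratified_scan(cc$scores, cc$chip, cc$pheno)
  expect_true(is.na(res$p_present))
  expect_match(res$note, "present stratum")
})

test_that("carry-forward applies the two-clause rule exactly", {
  # printed-value case: p 0.02 among carriers, 0.16 among non-carriers
  res <- data.frame(chip_variable = "JAK2", gene = "AIM2",
                    p_present = 0.02, p_absent = 0.16)
  expect_true(carry_forward(res)$carried_forward)
  # significant in both strata: not carried under two-clause
  res2 <- data.frame(chip_variable = "a", gene = "b",
                     p_present = 0.04, p_absent = 0.01)
  expect_false(carry_forward(res2)$carried_forward)
  expect_true(carry_forward(res2, rule = "one_clause")$carried_forward)
  # random 50-pair table matches the rule oracle
  set.seed(46)
  tab <- data.frame(chip_variable = "c", gene = paste0("g", 1:50),
                    p_present = runif(50), p_absent = runif(50))
  tab$p_present[sample(50, 5)] <- NA
  got <- carry_forward(tab)$carried_forward
  expect_equal(got, oracle_carry(tab$p_present, tab$p_absent))
})

test_that("interaction scan uses the hierarchical product-term model", {
  cc <- mk_scan_cohort(n = 12000, seed = 47, beta_noncarrier = 0,
                       beta_inter = log(1.85))
  res <- stratified_scan(cc$scores, cc$chip, cc$pheno)
  res <- carry_forward(res)
  res <- interaction_scan(res, cc$scores, cc$chip, cc$pheno)
  expect_true(res$carried_forward)
  expect_gt(res$interaction_z, 0)
  expect_lt(res$interaction_p, 0.05)
  expect_equal(res$interaction_loghr, log(1.85),
               tolerance = 2.5 * res$interaction_se / log(1.85))
  # the fitted model keeps both main effects alongside the product
  d <- merge(merge(cc$pheno, cc$chip, by = "sample_id"), cc$scores,
             by = "sample_id")
  d$has_chip <- as.numeric(d$has_chip)
  full <- fit_cox(d, c("G1", "has_chip", "G1:has_chip"))
  expect_setequal(setdiff(full$term, scan_covariates()),
                  c("G1", "has_chip", "G1:has_chip"))
  expect_equal(full[full$term == "G1:has_chip", "loghr"],
               res$interaction_loghr, tolerance = 1e-10)
})

test_that("bh_fdr reproduces the hand-worked step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.2)), c(0.04, 0.04, 0.04, 0.2))
  expect_equal(bh_fdr(0.037), 0.037)            # single p: q = p
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))  # all equal
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("bh_fdr equals the step-up oracle on random short vectors", {
  set.seed(48)
  for (i in 1:2000) {
    p <- runif(sample(1:8, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("modifier_scan assembles carry-forward flags and q-values", {
  cc <- mk_scan_cohort(n = 10000, seed = 50, beta_noncarrier = 0,
                       beta_inter = log(1.8))
  cc$scores$G2 <- rnorm(nrow(cc$scores))   # null gene
  res <- modifier_scan(cc$scores, cc$chip, cc$pheno)
  expect_equal(nrow(res), 2)
  r1 <- res[res$gene == "G1", ]
  expect_true(r1$carried_forward)
  expect_false(is.na(r1$interaction_q))
  expect_gte(r1$interaction_q, r1$interaction_p)
  expect_true(is.na(res[res$gene == "G2", "interaction_p"]) ||
                !res[res$gene == "G2", "carried_forward"])
})
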