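mk_score <- function(values, gene = "G1", degenerate = FALSE,
                     config_id = "cfg") {
  structure(list(gene_id = gene,
                 config = data.frame(config_id = config_id),
                 values = values, n_variants_used = 1L,
                 variant_ids = "1:1:A:C", standardized = TRUE,
                 degenerate = degenerate),
            class = "score_vector")
}

test_that("residualization removes covariate effects and restandardizes", {
  set.seed(20)
  n <- 3000
  ids <- paste0("S", 1:n)
  age <- rnorm(n, 60, 8)
  expr <- setNames(0.05 * age + rnorm(n), ids)
  cov <- data.frame(sample_id = ids, age = age)
  adj <- residualize_expression(expr, cov)
  expect_equal(unname(coef(lm(adj ~ age))["age"]), 0, tolerance = 1e-10)
  expect_equal(pop_sd_oracle(adj), 1, tolerance = 1e-10)
  expect_false(attr(adj, "degenerate"))
  # empty covariate set: standardized expression unchanged in order
  adj0 <- residualize_expression(expr, NULL)
  expect_equal(cor(adj0, expr), 1, tolerance = 1e-12)
  # expression exactly equal to a covariate: degenerate residuals
  adj1 <- residualize_expression(setNames(age, ids), cov)
  expect_true(attr(adj1, "degenerate"))
  expect_true(all(adj1 == 0))
})

test_that("collinear covariates are dropped with a warning", {
  set.seed(21)
  ids <- paste0("S", 1:100)
  cov <- data.frame(sample_id = ids, a = rnorm(100))
  cov$b <- 2 * cov$a
  expr <- setNames(rnorm(100), ids)
  expect_warning(residualize_expression(expr, cov), "collinear")
})

test_that("evaluate_r2 handles identity, independence and degeneracy", {
  set.seed(22)
  n <- 5000
  ids <- paste0("S", 1:n)
  y <- setNames(rnorm(n), ids)
  expect_equal(as.numeric(evaluate_r2(mk_score(y), y)), 1.0)
  x <- setNames(rnorm(n), ids)
  expect_lt(as.numeric(evaluate_r2(mk_score(x), y)), 0.005)
  dg <- evaluate_r2(mk_score(setNames(rep(0, n), ids), degenerate = TRUE), y)
  expect_equal(as.numeric(dg), 0)
  expect_equal(attr(dg, "flag"), "degenerate")
  small <- evaluate_r2(mk_score(x[1:10]), y[1:10])
  expect_equal(attr(small, "flag"), "insufficient_overlap")
  expect_equal(as.numeric(small), 0)
})

test_that("a near-oracle score for an h2 = 0.347 gene evaluates near 0.347", {
  spec <- ld_block_spec(n_blocks = 3, block_size = 5,
                        within_block_corr = 0.8, maf_range = c(0.2, 0.5))
  panel <- simulate_ld_panel(spec, 12000, seed = 23)
  cid <- panel$variants$variant_id[8]
  arch <- eqtl_architecture("G1", cid, 1, 0.347, tss = spec$tss)
  expr <- simulate_expression(panel, arch, seed = 24)
  g <- setNames(as.numeric(panel$dosages[, cid]), panel$sample_ids)
  r2 <- evaluate_r2(mk_score(g), residualize_expression(expr, NULL))
  expect_equal(as.numeric(r2), 0.347, tolerance = 0.03)
})

test_that("selection is the argmax over candidates and cohorts", {
  set.seed(25)
  n <- 400
  ids <- paste0("S", 1:n)
  y <- setNames(rnorm(n), ids)
  cands <- list(
    c1 = mk_score(setNames(y + rnorm(n, sd = 2.0), ids), config_id = "c1"),
    c2 = mk_score(setNames(y + rnorm(n, sd = 0.8), ids), config_id = "c2"),
    c3 = mk_score(setNames(rnorm(n), ids), config_id = "c3"))
  vsets <- list(whole_blood = list(expression = y))
  got <- select_best_score(cands, vsets)
  # exhaustive re-evaluation oracle
  r2s <- vapply(cands, function(sv) cor(sv$values, y)^2, 0)
  expect_equal(got$best_config, names(which.max(r2s)))
  expect_equal(got$best_r2, unname(max(r2s)), tolerance = 1e-12)
  expect_true(got$retained)
  tab <- attr(got, "r2_table")
  expect_equal(nrow(tab), 3)
  # single candidate is always best
  one <- select_best_score(cands["c3"], vsets)
  expect_equal(one$best_config, "c3")
})

test_that("retention is a strict > 1% rule on best r2", {
  set.seed(26)
  n <- 4000
  ids <- paste0("S", 1:n)
  y <- setNames(rnorm(n), ids)
  null_sc <- mk_score(setNames(rnorm(n), ids))
  got <- select_best_score(list(c1 = null_sc),
                           list(v = list(expression = y)))
  expect_false(got$retained)           # null score r2 ~ 0 < 0.01
  # all-degenerate candidates: retained FALSE with a reason
  dg <- mk_score(setNames(rep(1, n), ids), degenerate = TRUE)
  got2 <- select_best_score(list(c1 = dg), list(v = list(expression = y)))
  expect_false(got2$retained)
  expect_match(got2$reason, "degenerate")
  # best_r2 never decreases when candidates are added
  better <- mk_score(setNames(y + rnorm(n, sd = 1), ids), config_id = "c2")
  got3 <- select_best_score(list(c1 = null_sc, c2 = better),
                            list(v = list(expression = y)))
  expect_gte(got3$best_r2, got$best_r2)
})
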