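test_that("ld_r2 matches hand computation and is symmetric", {
  # 6-sample worked panel: v2 duplicates v1 exactly, v3 independent-ish
  dos <- cbind(c(0, 1, 2, 1, 0, 2), c(0, 1, 2, 1, 0, 2), c(2, 0, 1, 1, 2, 0))
  geno <- toy_dosage(dos, pos = c(10, 20, 30))
  ids <- geno$variants$variant_id
  expect_equal(ld_r2(geno, ids[1], ids[2]), 1.0)
  expect_equal(ld_r2(geno, ids[1], ids[1]), 1.0)
  expect_equal(ld_r2(geno, ids[1], ids[3]),
               ld_r2(geno, ids[3], ids[1]))
  expect_equal(ld_r2(geno, ids[1], ids[3]),
               cor(dos[, 1], dos[, 3])^2)
  mono <- toy_dosage(cbind(rep(1, 6), dos[, 1]), pos = c(10, 20))
  expect_error(ld_r2(mono, mono$variants$variant_id[1],
                     mono$variants$variant_id[2]), "monomorphic")
})

test_that("independently simulated variants have near-zero r2", {
  spec <- ld_block_spec(n_blocks = 2, block_size = 1,
                        within_block_corr = 0, maf_range = c(0.3, 0.5))
  panel <- simulate_ld_panel(spec, 20000, seed = 3)
  ids <- panel$variants$variant_id
  expect_lt(ld_r2(panel, ids[1], ids[2]), 0.01)
})

test_that("a single variant is retained as the sole index", {
  set.seed(4)
  geno <- toy_dosage(matrix(rbinom(30, 2, 0.4), 30, 1), pos = 100)
  ss <- toy_sumstats(geno, beta = 0.2, pvalue = 0.3)
  cl <- clump(ss, geno, r2_clump = 0.1, window_bp = 1e6)
  expect_equal(cl$index_variant_ids, geno$variants$variant_id)
  expect_length(cl$removed, 0)
})

test_that("5-variant toy clumps to exactly the hand-enumerated indices", {
  # v1 top hit; v2, v3 perfect proxies inside the window; v4 a perfect
  # proxy outside the window; v5 independent inside the window
  set.seed(5)
  x <- rbinom(200, 2, 0.4)
  y <- rbinom(200, 2, 0.4)
  geno <- toy_dosage(cbind(x, x, x, x, y),
                     pos = c(1000, 2000, 3000, 99000, 4000))
  ss <- toy_sumstats(geno, beta = rep(0.1, 5),
                     pvalue = c(1e-8, 1e-4, 1e-3, 1e-2, 5e-2))
  cl <- clump(ss, geno, r2_clump = 0.5, window_bp = 10000)
  ids <- geno$variants$variant_id
  expect_setequal(cl$index_variant_ids, ids[c(1, 4, 5)])
  expect_equal(sort(names(cl$removed)), sort(ids[2:3]))
  expect_true(all(cl$removed == ids[1]))
  # retained-plus-removed partitions the input
  expect_setequal(c(cl$index_variant_ids, names(cl$removed)), ids)
  # matches the literal greedy oracle
  expect_equal(sort(cl$index_variant_ids),
               sort(oracle_clump(ss, geno, 0.5, 10000)))
})

test_that("clump equals the greedy-definition oracle on random instances", {
  set.seed(6)
  for (i in 1:150) {
    inst <- random_clump_instance()
    got <- clump(inst$ss, inst$geno, inst$r2, inst$window)
    want <- oracle_clump(inst$ss, inst$geno, inst$r2, inst$window)
    expect_equal(sort(got$index_variant_ids), sort(want))
    expect_setequal(c(got$index_variant_ids, names(got$removed)),
                    inst$ss$variant_id)
  }
})

test_that("clump output is invariant to input record order", {
  set.seed(7)
  for (i in 1:20) {
    inst <- random_clump_instance()
    perm <- sample(nrow(inst$ss))
    a <- clump(inst$ss, inst$geno, inst$r2, inst$window)
    b <- clump(inst$ss[perm, ], inst$geno, inst$r2, inst$window)
    expect_identical(a$index_variant_ids, b$index_variant_ids)
  }
})

test_that("variants absent from the reference are dropped or kept by option", {
  set.seed(8)
  geno <- toy_dosage(matrix(rbinom(60, 2, 0.4), 30, 2), pos = c(100, 200))
  ss <- toy_sumstats(geno, beta = c(0.1, 0.2), pvalue = c(0.01, 0.02))
  extra <- ss[2, ]
  extra$variant_id <- "1:300:A:C"; extra$pos <- 300
  ss2 <- rbind(ss, extra)
  cl_drop <- clump(ss2, geno, 0.1, 1e6)
  expect_false("1:300:A:C" %in% cl_drop$index_variant_ids)
  expect_warning(cl_keep <- clump(ss2, geno, 0.1, 1e6,
                                  missing_reference = "keep"), "unclumped")
  expect_true("1:300:A:C" %in% cl_keep$index_variant_ids)
})
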