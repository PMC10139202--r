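test_that("size factors reproduce the median-of-ratios hand computation", {
  counts <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  same <- matrix(rep(c(5, 9, 2), 3), nrow = 3)
  expect_true(all(abs(size_factors(same) - size_factors(same)[1]) < 1e-12))

  single <- matrix(c(3, 7), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(size_factors(single)), 1)

  zeros <- matrix(c(0, 1, 1, 0), 2)
  expect_error(size_factors(zeros), "pseudo-reference")
})

test_that("size factors match the DESeq2 estimator on random counts", {
  withr::local_seed(1)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1, nrow = 100)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("log normalization is scale-invariant and monotone", {
  m <- matrix(c(0, 10, 100, 7), 2)
  f <- c(1, 2)
  norm <- normalize_log(m, f)
  expect_equal(norm[1, 1], 0)  # zero count with pseudocount 1
  # doubling a sample's counts and its factor leaves values unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  expect_equal(normalize_log(m2, c(1, 4)), norm)
  # monotone per cell
  expect_true(all(normalize_log(m + 5, f) > norm))
})

test_that("family distribution arithmetic and filters", {
  de <- tibble::tibble(feature_id = paste0("t", 1:4),
                       family = c("Alu", "Alu", "Alu", "L1"),
                       log2fc = c(2, 1.5, -1.2, 3))
  fd <- family_distribution(de, c(Alu = 10, L1 = 100))
  expect_equal(fd$share_of_de[fd$family == "Alu"], 0.75)
  expect_equal(fd$rate_in_family, c(0.30, 0.01))

  up <- family_distribution(de, c(Alu = 10, L1 = 100), direction = "up")
  expect_equal(up$n_de[up$family == "Alu"], 2L)

  one <- family_distribution(de[4, ], c(L1 = 100))
  expect_equal(one$share_of_de, 1)
  expect_error(family_distribution(de, c(Alu = 10)), "L1")
})

test_that("pearson test reproduces the hand computation and symmetries", {
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$r, 1)
  ht <- pearson_test(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(ht$r, 6.5 / sqrt(5 * 8.75), tolerance = 1e-6)
  expect_equal(ht$r, 0.9827, tolerance = 1e-4)

  withr::local_seed(5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson_test(x, y), pearson_test(y, x))
  expect_equal(pearson_test(3 * x - 2, y)$r, pearson_test(x, y)$r)
  expect_true(is.na(pearson_test(rep(1, 5), rnorm(5))$r))
})

test_that("pearson p agrees with a permutation p on small vectors", {
  withr::local_seed(99)
  x <- rnorm(8)
  y <- x + rnorm(8, sd = 1.5)
  analytic <- pearson_test(x, y)$p
  r_obs <- abs(cor(x, y))
  perm <- mean(replicate(1e4, abs(cor(x, sample(y))) >= r_obs - 1e-12))
  expect_equal(analytic, perm,
               tolerance = 5 * sqrt(perm * (1 - perm) / 1e4) / max(analytic, 0.01))
})

test_that("BH adjustment matches examples and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  withr::local_seed(123)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(enrichment_hypergeom(3, 5, 4, 10), 66 / 252,
               tolerance = 1e-12)
  expect_equal(enrichment_hypergeom(3, 5, 4, 10),
               hypergeom_oracle(3, 5, 4, 10), tolerance = 1e-12)
  expect_equal(enrichment_hypergeom(0, 5, 4, 10), 1)
  expect_equal(enrichment_hypergeom(4, 4, 4, 4), 1)
  expect_error(enrichment_hypergeom(5, 4, 4, 10), "inconsistent")
})

test_that("cis screen recovers planted pairs in both coupling modes", {
  cfg <- synth_config(seed = 2, n_te = 300, n_gene = 300,
                      frac_linked = 0.1)
  cc <- gen_counts(cfg)
  te <- normalize_log(cc$te_counts)
  ge <- normalize_log(cc$gene_counts)
  cis <- cis_correlate(te, ge, cc$truth, cc$samples)
  rec <- tidy(cis)
  expect_gte(mean(rec$sig_all[cc$truth$linked]), 0.8)

  cfg2 <- synth_config(seed = 2, n_te = 300, n_gene = 300,
                       frac_linked = 0.1, coupling_mode = "case_only")
  cc2 <- gen_counts(cfg2)
  rec2 <- tidy(cis_correlate(normalize_log(cc2$te_counts),
                             normalize_log(cc2$gene_counts),
                             cc2$truth, cc2$samples))
  linked2 <- cc2$truth$linked
  expect_gt(mean(rec2$sig_case[linked2]), mean(rec2$sig_ctrl[linked2]))
  expect_gt(mean(rec2$r_case[linked2] - rec2$r_ctrl[linked2]), 0.4)
})

test_that("permuting sample labels destroys planted cis significance", {
  cfg <- synth_config(seed = 8, n_te = 200, n_gene = 200,
                      frac_linked = 0.25)
  cc <- gen_counts(cfg)
  te <- normalize_log(cc$te_counts)
  ge <- normalize_log(cc$gene_counts)
  withr::local_seed(1)
  perm <- sample(ncol(ge))
  rec <- tidy(cis_correlate(te, ge[, perm], cc$truth, cc$samples))
  # after permutation the discovery rate drops to about the FDR level
  expect_lt(mean(rec$sig_all[cc$truth$linked]), 0.1)
})

test_that("pairs referencing unknown features are skipped with a warning", {
  cfg <- synth_config(seed = 3, n_te = 20, n_gene = 20)
  cc <- gen_counts(cfg)
  pairs <- rbind(cc$truth[1:5, ],
                 tibble::tibble(te_id = "nope", gene_id = "gene0001",
                                linked = FALSE, mode = "both_groups"))
  expect_warning(
    cis <- cis_correlate(normalize_log(cc$te_counts),
                         normalize_log(cc$gene_counts), pairs, cc$samples),
    "missing")
  expect_equal(nrow(tidy(cis)), 5L)
})

test_that("trans overlap satisfies the conservation identities", {
  ov <- trans_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(ov$shared, c("b", "c"))
  expect_equal(length(ov$only_case), 1L)
  expect_equal(length(ov$only_ctrl), 1L)
  g <- glance(ov)
  expect_equal(g$n_shared + g$n_only_case, g$n_case)
  expect_equal(g$n_shared + g$n_only_ctrl, g$n_ctrl)

  disjoint <- trans_overlap(c("a", "b"), c("x", "y"))
  expect_equal(length(disjoint$shared), 0L)
})

test_that("trans screen output is consistent with its own record table", {
  cfg <- synth_config(seed = 4, n_te = 40, n_gene = 40, frac_linked = 0.3)
  cc <- gen_counts(cfg)
  tr <- trans_correlate(normalize_log(cc$te_counts),
                        normalize_log(cc$gene_counts), cc$samples)
  rec <- tidy(tr)
  expect_equal(nrow(rec), 1600L)
  g <- glance(tr$overlap)
  expect_equal(g$n_case, dplyr::n_distinct(rec$te_id[rec$sig_case]))
  expect_equal(g$n_shared + g$n_only_case, g$n_case)
  # planted diagonal pairs dominate the significant set
  diag_pairs <- rec$te_id == sub("gene", "te", rec$gene_id)
  expect_gt(mean(rec$sig_all[diag_pairs & cc$truth$linked[
    match(rec$te_id[diag_pairs], cc$truth$te_id)]]), 0.8)
})

test_that("DE filtering applies both thresholds", {
  de <- tibble::tibble(feature_id = paste0("f", 1:4),
                       log2fc = c(2, 0.5, -3, 1.5),
                       pvalue = c(1e-5, 1e-5, 1e-4, 0.2),
                       padj = c(1e-3, 1e-3, 5e-3, 0.5))
  expect_equal(filter_de(de)$feature_id, c("f1", "f3"))
  expect_error(filter_de(dplyr::mutate(de, padj = padj * 10)), "\\[0, 1\\]")
})
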