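test_that("genotype generation follows Hardy-Weinberg proportions at the drawn MAF", {
  g <- gen_genotypes(100000, 3, seed = 30)
  maf <- attr(g, "drawn_maf")
  for (m in 1:3) {
    q <- maf[m]
    emp <- tabulate(g$counts[, m] + 1, 3) / 100000
    hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    expect_lt(max(abs(emp - hwe)), 0.01)
    se <- sqrt(q * (1 - q) / (2 * 100000))
    expect_lt(abs(mean(g$counts[, m]) / 2 - q), 4 * se)
  }
  g2 <- gen_genotypes(50, 4, seed = 77)
  g3 <- gen_genotypes(50, 4, seed = 77)
  expect_identical(g2$counts, g3$counts)
})

test_that("closed-form factor-model correlations match their defining constants", {
  expect_equal(factor_model_correlation(lag = 1), 0.65)
  expect_equal(factor_model_correlation(lag = NULL), 0.30)
  expect_equal(factor_model_correlation(lag = 3, c0_sq = 0.5, rho = 0.3),
               0.5 + 0.5 * 0.3^3)
})

test_that("null factor-model phenotypes reproduce the implied correlation structure", {
  cfg <- factor_model_config(N = 8000, K = 20, C = 4, M = 10, beta = 0)
  sim <- simulate_dataset(cfg, mode = "quantitative", seed = 31)
  cm <- cor(sim$pheno$values)
  cat_idx <- sim$truth$category
  k <- cfg$k
  adj <- unlist(lapply(1:4, function(c) {
    idx <- which(cat_idx == c)
    cm[cbind(idx[-k], idx[-1])]
  }))
  expect_equal(mean(adj), 0.65, tolerance = 0.03)
  between <- cm[outer(cat_idx, cat_idx, "!=") & upper.tri(cm)]
  expect_equal(mean(between), 0.30, tolerance = 0.03)
  # near-independence limit: tiny shared factor, no error autocorrelation
  cfg0 <- factor_model_config(N = 4000, K = 8, C = 2, M = 10, c0_sq = 1e-4,
                              rho = 0, rho_f = 0, beta = 0)
  sim0 <- simulate_dataset(cfg0, mode = "quantitative", seed = 32)
  cm0 <- cor(sim0$pheno$values)
  expect_lt(max(abs(cm0[upper.tri(cm0)])), 0.06)
})

test_that("effect patterns follow the constant and graded templates", {
  cfg <- factor_model_config(N = 10, K = 8, C = 2, M = 50, model_id = 1,
                             beta = 0.1, n_causal = 5)
  eff <- effect_matrix(cfg, seed = 33)
  expect_length(eff$causal_idx, 5)
  row <- eff$B[[1]][eff$causal_idx[1], ]
  expect_equal(row, rep(0.1, 4))
  expect_true(all(eff$B[[2]] == 0))
  cfg2 <- factor_model_config(N = 10, K = 8, C = 2, M = 50, model_id = 2,
                              beta = 0.1, n_causal = 5)
  eff2 <- effect_matrix(cfg2, seed = 33)
  expect_equal(eff2$B[[1]][eff2$causal_idx[1], ], c(0.04, 0.08, 0.12, 0.16),
               tolerance = 1e-12)
})

test_that("two-category models share or oppose directions; split models partition the causal set", {
  cfg4 <- factor_model_config(N = 10, K = 8, C = 2, M = 50, model_id = 4,
                              beta = 0.2, n_causal = 6)
  eff4 <- effect_matrix(cfg4, seed = 34)
  expect_equal(eff4$B[[2]][eff4$causal_idx, ], -eff4$B[[1]][eff4$causal_idx, ])
  cfg5 <- factor_model_config(N = 10, K = 8, C = 2, M = 400, model_id = 5,
                              beta = 0.2)
  expect_equal(cfg5$n_causal, 200)
  cfg5$n_causal <- 10; cfg5$M <- 50
  eff5 <- effect_matrix(cfg5, seed = 35)
  aff1 <- which(rowSums(eff5$B[[1]] != 0) > 0)
  aff2 <- which(rowSums(eff5$B[[2]] != 0) > 0)
  expect_length(intersect(aff1, aff2), 0)
  expect_equal(sort(c(aff1, aff2)), eff5$causal_idx)
  expect_error(effect_matrix(factor_model_config(N = 10, K = 8, C = 2, M = 5,
                                                 n_causal = 10)),
               "causal")
})

test_that("a zero effect size leaves all effect matrices empty", {
  cfg <- factor_model_config(N = 10, K = 8, C = 2, M = 50, model_id = 3,
                             beta = 0, n_causal = 5)
  eff <- effect_matrix(cfg, seed = 36)
  expect_true(all(vapply(eff$B, function(b) all(b == 0), logical(1))))
})

test_that("liability thresholding yields the exact case count with rank invariance", {
  set.seed(37)
  y <- rnorm(322607)
  d <- dichotomize(y, 0.000658)
  expect_equal(sum(d == 1), 212)
  expect_equal(sum(d == 0), 322395)
  expect_equal(sum(dichotomize(rnorm(10), 1)), 5)
  y2 <- rnorm(100)
  expect_identical(dichotomize(y2, 0.25), dichotomize(exp(y2), 0.25))
  expect_error(dichotomize(rnorm(100), 0.0001), "zero cases")
})

test_that("ratio sampling stays in the configured pool and is uniform over it", {
  pool <- default_ratio_pool()
  expect_true(all(pool >= 0.000658 & pool <= 0.03937))
  expect_identical(sample_ratio(pool, seed = 38), sample_ratio(pool, seed = 38))
  set.seed(39)
  draws <- replicate(10000, sample_ratio(pool))
  expect_true(all(draws %in% pool))
  gof <- stats::chisq.test(table(factor(draws, levels = pool)))
  expect_gt(gof$p.value, 0.001)
  expect_true(all(default_ratio_pool(N = 1000, min_cases = 5) >= 0.005))
})

test_that("dataset composition matches the requested phenotype mode", {
  cfg <- factor_model_config(N = 400, K = 12, C = 3, M = 50, beta = 0)
  mix <- simulate_dataset(cfg, mode = "mixture", seed = 40)
  expect_equal(sum(mix$pheno$trait_kind == "binary"), 6)
  expect_equal(unique(mix$truth$ratios[mix$pheno$trait_kind == "binary"]), 1)
  bin <- simulate_dataset(cfg, mode = "binary", seed = 41,
                          ratio_pool = c(0.03, 0.05))
  expect_true(all(bin$pheno$trait_kind == "binary"))
  expect_true(all(bin$truth$ratios %in% c(0.03, 0.05)))
  q1 <- simulate_dataset(cfg, mode = "quantitative", seed = 42)
  q2 <- simulate_dataset(cfg, mode = "quantitative", seed = 42)
  expect_identical(q1$pheno$values, q2$pheno$values)
  expect_identical(q1$geno$counts, q2$geno$counts)
  expect_equal(dim(q1$pheno$values), c(400L, 12L))
})

test_that("hierarchical planted effects give every category its own causal block", {
  cfg <- factor_model_config(N = 10, K = 16, C = 4, M = 100, beta = 0.5,
                             n_causal = 20)
  eff <- planted_category_effects(cfg, seed = 43)
  own <- vapply(1:4, function(c) {
    any(abs(eff$B[[c]]) > 0)
  }, logical(1))
  expect_true(all(own))
  expect_length(eff$causal_idx, 20)
  expect_equal(eff$affected_categories, 1:4)
})
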