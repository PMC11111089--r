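test_that("univariate z-scores reuse the score machinery and the SPA calibration", {
  expect_equal(univariate_z(c(1, 2, 3), c(0, 1, 2)), sqrt(3), tolerance = 1e-10)
  # binary: magnitude from the SPA p-value, sign from the score
  set.seed(14)
  n <- 500
  g <- rbinom(n, 2, 0.3); gc <- g - mean(g)
  y <- rbinom(n, 1, 0.04)
  z <- univariate_z(y, gc, "binary")
  ref <- spa_pvalue(y, gc, mu = mean(y))
  expect_equal(abs(z), qnorm(ref$p / 2, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(sign(z), sign(ref$S))
  expect_equal(univariate_z(c(0, 1, 0, 1, 0), rep(0, 5), "binary",
                            mu = rep(0.5, 5)), 0)
})

test_that("normal-quantile magnitude: p = 0.05 with a negative score gives z = -1.96", {
  expect_equal(sign(-3) * qnorm(0.05 / 2, lower.tail = FALSE), -1.959964,
               tolerance = 1e-6)
})

test_that("residual correlation estimation floors eigenvalues for duplicated traits", {
  set.seed(15)
  Y <- matrix(rnorm(2000 * 2), 2000, 2)
  R <- estimate_R(Y)
  expect_lt(abs(R[1, 2]), 3 / sqrt(2000))
  Yd <- cbind(Y, Y[, 1])
  Rd <- estimate_R(Yd)
  expect_no_error(solve(Rd))
  expect_gt(min(eigen(Rd, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(estimate_R(cbind(Y, 5)), "constant")
})

test_that("O'Brien reduces to a z-test for one trait and sums under independence", {
  z1 <- 1.7
  out <- obrien(z1, matrix(1, 1, 1))
  expect_equal(out$statistic, z1)
  expect_equal(out$p, 2 * pnorm(-z1))
  out2 <- obrien(rep(0.8, 4), diag(4))
  expect_equal(out2$statistic, sqrt(4) * 0.8, tolerance = 1e-12)
})

test_that("O'Brien equals a generalized-least-squares oracle on a random fixture", {
  R <- random_corr(4, seed = 16)
  z <- c(1.2, -0.4, 2.1, 0.3)
  # GLS route: whiten by the Cholesky factor, regress on the whitened 1-vector
  L <- chol(R)
  zs <- backsolve(L, z, transpose = TRUE)
  os <- backsolve(L, rep(1, 4), transpose = TRUE)
  gls_t <- sum(os * zs) / sqrt(sum(os^2))
  expect_equal(obrien(z, R)$statistic, gls_t, tolerance = 1e-12)
})

test_that("Omnibus is the chi-square quadratic form with K' degrees of freedom", {
  z <- c(1, -2, 0.5)
  out <- omnibus(z, diag(3))
  expect_equal(out$statistic, sum(z^2), tolerance = 1e-12)
  expect_equal(out$df, 3)
  out1 <- omnibus(1.3, matrix(1, 1, 1))
  expect_equal(out1$statistic, 1.69, tolerance = 1e-12)
  expect_equal(out1$p, pchisq(1.69, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("CLC collapses: identity clusters give Omnibus, one cluster gives O'Brien squared", {
  R <- random_corr(5, seed = 17)
  z <- rnorm(5)
  expect_equal(clc(z, R, diag(5))$statistic, omnibus(z, R)$statistic,
               tolerance = 1e-12)
  expect_equal(clc(z, R, matrix(1, 5, 1))$statistic, obrien(z, R)$statistic^2,
               tolerance = 1e-12)
})

test_that("CLC matches a direct quadratic-form oracle at L = 2", {
  R <- random_corr(5, seed = 18)
  z <- c(0.5, 1.5, -1, 2, 0.1)
  U <- cluster_indicator(c(1, 1, 2, 2, 2))
  Ri <- solve(R)
  q <- t(U) %*% Ri %*% z
  oracle <- drop(t(q) %*% solve(t(U) %*% Ri %*% U) %*% q)
  out <- clc(z, R, U)
  expect_equal(out$statistic, oracle, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_error(clc(z, R, matrix(0, 5, 2)), "exactly one")
})

test_that("Cauchy combination: fixed point, single input, and CDF oracle", {
  expect_equal(acat(rep(0.37, 6)), 0.37, tolerance = 1e-12)
  expect_equal(acat(0.2), 0.2, tolerance = 1e-12)
  stat <- mean(tan((0.5 - c(0.01, 0.04)) * pi))
  expect_equal(acat(c(0.01, 0.04)), pcauchy(stat, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(acat(c(0.01, 0.04)), 0.016, tolerance = 1e-3)
  expect_warning(pc <- acat(c(1, 0.5)), "clipped")
  expect_true(pc > 0 && pc <= 1)
  # monotone in each argument
  expect_lt(acat(c(0.001, 0.3)), acat(c(0.01, 0.3)))
})

test_that("ceCLC and HCLC reduce to the single-trait chi-square", {
  for (f in list(ceclc, hclc)) {
    out <- f(1.5, matrix(1, 1, 1))
    expect_equal(out$statistic, 2.25, tolerance = 1e-12)
    expect_equal(out$p, pchisq(2.25, 1, lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("HCLC with a two-trait tree equals CLC at its only merge level", {
  R <- random_corr(2, seed = 19)
  z <- c(1.1, -0.7)
  expect_equal(hclc(z, R)$p, clc(z, R, diag(2))$p, tolerance = 1e-12)
})

test_that("joint z-based tests hold their nominal level under the correlated null", {
  set.seed(20)
  K <- 6
  R <- 0.4 * diag(K) + 0.6
  L <- chol(R)
  n_draw <- 1e5
  Z <- t(L) %*% matrix(rnorm(K * n_draw), K, n_draw)
  p_omni <- batch_test_pvals(Z, R, "omnibus")
  expect_gt(mean(p_omni <= 0.05), 0.045)
  expect_lt(mean(p_omni <= 0.05), 0.055)
  for (tn in c("ceclc", "hclc")) {
    p <- batch_test_pvals(Z[, 1:10000], R, tn)
    expect_gt(mean(p <= 0.05), 0.040)
    expect_lt(mean(p <= 0.05), 0.060)
  }
})

test_that("batch p-values equal the per-SNP test functions", {
  set.seed(22)
  K <- 7; M <- 25
  R <- random_corr(K)
  Z <- matrix(rnorm(K * M), K, M)
  for (tn in c("obrien", "omnibus", "clc", "ceclc", "hclc")) {
    pb <- batch_test_pvals(Z, R, tn)
    ps <- vapply(seq_len(M), function(m) test_snp_no(Z[, m], R, tn)$p,
                 numeric(1))
    expect_equal(pb, ps, tolerance = 1e-10)
  }
})

test_that("MultiPhen detects a strong monotone effect and is uniform under permutation", {
  set.seed(23)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  Y <- cbind(g * 0.8 + rnorm(n), rnorm(n))
  expect_lt(multiphen(g, Y)$p, 1e-4)
  ps <- vapply(1:200, function(i)
    suppressWarnings(multiphen(sample(g), Y)$p), numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps[!is.na(ps)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MultiPhen handles two-level and degenerate genotypes", {
  set.seed(24)
  Y <- cbind(rnorm(60))
  g2 <- rbinom(60, 1, 0.5)
  out <- multiphen(g2, Y)
  expect_true(out$p > 0 && out$p <= 1)
  expect_warning(out0 <- multiphen(rep(1, 60), Y), "single observed")
  expect_true(is.na(out0$p))
})

test_that("module-wise testing Bonferroni-combines across modules", {
  set.seed(25)
  K <- 6
  R <- random_corr(K)
  z <- rnorm(K)
  part1 <- list(labels = rep(1, K))
  net1 <- test_snp_net(z, R, part1, "omnibus")
  expect_equal(net1$combined_p, test_snp_no(z, R, "omnibus")$p,
               tolerance = 1e-12)
  expect_equal(min(1, 3 * min(c(0.001, 0.5, 0.2))), 0.003)
  part3 <- list(labels = c(1, 1, 2, 2, 3, 3))
  net3 <- test_snp_net(z, R, part3, "ceclc")
  expect_equal(net3$combined_p, min(1, 3 * min(net3$module_p)),
               tolerance = 1e-12)
  Zb <- matrix(rnorm(K * 10), K, 10)
  pb <- batch_test_pvals_net(Zb, R, part3, "ceclc")
  ps <- vapply(1:10, function(m)
    test_snp_net(Zb[, m], R, part3, "ceclc")$combined_p, numeric(1))
  expect_equal(pb, ps, tolerance = 1e-10)
})

test_that("the Bonferroni-combined p-value is valid (stochastically >= uniform) under the null", {
  set.seed(26)
  K <- 6
  R <- 0.5 * diag(K) + 0.5
  L <- chol(R)
  Z <- t(L) %*% matrix(rnorm(K * 20000), K, 20000)
  part <- list(labels = c(1, 1, 2, 2, 3, 3))
  p <- batch_test_pvals_net(Z, R, part, "omnibus")
  for (a in c(0.01, 0.05, 0.1))
    expect_lte(mean(p <= a), a + 3 * sqrt(a * (1 - a) / 20000))
})
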