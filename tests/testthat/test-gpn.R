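test_that("residualization centers, fits, and matches a least-squares oracle", {
  expect_equal(drop(residualize(cbind(c(1, 2, 3)))), c(-1, 0, 1))
  x <- c(0.3, 1.2, -0.5, 2.2)
  cov1 <- covariate_dataset(cbind(x = x))
  expect_equal(drop(residualize(cbind(x), cov1)), rep(0, 4), tolerance = 1e-12)
  # covariate orthogonal to a centered column leaves it unchanged
  y <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)           # orthogonal to y and to the intercept
  expect_equal(drop(residualize(cbind(y), covariate_dataset(cbind(z = z)))),
               y, tolerance = 1e-12)
  # generic oracle: lm residuals on a random fixture
  set.seed(1)
  V <- matrix(rnorm(40), 20, 2)
  Cv <- covariate_dataset(matrix(rnorm(60), 20, 3))
  r1 <- residualize(V, Cv)
  r2 <- apply(V, 2, function(v) stats::lm(v ~ Cv$values)$residuals)
  expect_equal(unname(r1), unname(r2), tolerance = 1e-10)
  # residuals orthogonal to covariates and intercept
  expect_lt(max(abs(crossprod(cbind(1, Cv$values), r1))), 1e-8 * 20)
  expect_error(
    residualize(V, covariate_dataset(cbind(a = rnorm(20), b = 0:19,
                                           c = 2 * (0:19)))),
    "collinear")
})

test_that("score test matches the printed-formula hand evaluation", {
  st <- score_test(c(1, 2, 3), c(0, 1, 2))
  expect_equal(st$S, 2)
  expect_equal(st$sigma2, 4 / 3)
  expect_equal(st$z, sqrt(3), tolerance = 1e-12)
  expect_equal(st$p, 2 * pnorm(-sqrt(3)), tolerance = 1e-12)
})

test_that("degenerate score input returns the S=0, p=1 contract, not an error", {
  st <- score_test(rep(2, 5), c(0, 1, 2, 1, 0))
  expect_equal(st$S, 0)
  expect_equal(st$p, 1)
  expect_equal(score_test(c(1, 2, 3, 4), rep(1, 4))$p, 1)
})

test_that("score z equals sqrt(n) * Pearson correlation on random fixtures", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    y <- rnorm(n); g <- rbinom(n, 2, 0.3)
    if (sd(g) == 0) next
    expect_equal(score_test(y, g)$z, sqrt(n) * cor(y, g), tolerance = 1e-10)
  }
})

test_that("saddlepoint p-values agree with exhaustive enumeration (n = 10)", {
  set.seed(7)
  g <- round(rnorm(10), 2)
  gc <- g - mean(g)
  mu <- rep(0.3, 10)
  checked <- 0
  for (i in 1:8) {
    y <- rbinom(10, 1, mu)
    res <- spa_pvalue(y, gc, mu = mu, fastspa = FALSE)
    if (res$S == 0) next
    p_exact <- enum_score_pvalue(res$S, gc, mu)
    expect_lt(abs(res$p - p_exact) / p_exact, 0.10)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("saddlepoint and normal p-values agree in the balanced small-z regime", {
  set.seed(1)
  n <- 2000
  g <- rbinom(n, 2, 0.3); gc <- g - mean(g)
  mu <- rep(0.5, n)
  found <- FALSE
  for (i in 1:20) {
    y <- rbinom(n, 1, 0.5)
    res <- spa_pvalue(y, gc, mu = mu, fastspa = FALSE)
    if (abs(res$z) >= 1 || res$S == 0) next
    expect_lt(abs(res$p - 2 * pnorm(-abs(res$z))), 0.01)
    found <- TRUE
  }
  expect_true(found)
})

test_that("zero score gives p = 1 under the symmetric null", {
  res <- spa_pvalue(c(0, 0, 1, 1), c(-1, 1, -1, 1), mu = rep(0.5, 4))
  expect_equal(res$p, 1)
})

test_that("vectorized saddlepoint tails equal the scalar solver", {
  set.seed(9)
  n <- 300
  G <- matrix(rbinom(n * 25, 2, 0.25), n, 25)
  G <- scale(G, scale = FALSE)
  mu <- rep(0.03, n)
  sds <- sqrt(colSums(G^2 * (mu * (1 - mu))))
  s <- rnorm(25, sd = sds) * 2.5
  bt <- gpnet:::.spa_tail_batch(s, G, mu)
  st <- vapply(1:25, function(j) gpnet:::.spa_tail(s[j], G[, j], mu), numeric(1))
  expect_equal(bt, st, tolerance = 1e-7)
})

test_that("chi-square(1) strength transform hits the reference quantiles", {
  s <- build_gpn_from_summary(data.frame(
    trait_id = "t1", snp_id = c("s1", "s2", "s3"),
    direction = c(1, -1, 1), p_value = c(0.5, 0.05, 1)))
  expect_equal(s$T[1, 1], 0.4549364, tolerance = 1e-6)
  expect_equal(s$T[1, 2], -3.841459, tolerance = 1e-6)
  expect_equal(s$T[1, 3], 0)
})

test_that("null network: mean |T| is E[chi-square(1)] = 1 and p-values are uniform", {
  cfg <- factor_model_config(N = 500, K = 50, C = 5, M = 2000, beta = 0)
  sim <- simulate_dataset(cfg, mode = "quantitative", seed = 11)
  gpn <- build_gpn(sim$geno, sim$pheno)
  expect_equal(mean(abs(gpn$T)), 1, tolerance = 0.02)
  ks <- suppressWarnings(stats::ks.test(as.vector(gpn$pvals), "punif"))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("individual-level and summary-level builds give identical networks", {
  cfg <- factor_model_config(N = 300, K = 6, C = 2, M = 40, beta = 0)
  sim <- simulate_dataset(cfg, mode = "quantitative", seed = 3)
  gpn <- build_gpn(sim$geno, sim$pheno)
  stats_df <- data.frame(
    trait_id = rep(gpn$trait_ids, times = length(gpn$snp_ids)),
    snp_id = rep(gpn$snp_ids, each = length(gpn$trait_ids)),
    direction = ifelse(as.vector(gpn$signs) >= 0, 1, -1),
    p_value = as.vector(gpn$pvals))
  gpn2 <- build_gpn_from_summary(stats_df, trait_ids = gpn$trait_ids,
                                 snp_ids = gpn$snp_ids)
  expect_equal(gpn2$T, gpn$T, tolerance = 1e-10)
})

test_that("negating a quantitative trait negates its network row", {
  cfg <- factor_model_config(N = 200, K = 4, C = 2, M = 30, beta = 0)
  sim <- simulate_dataset(cfg, mode = "quantitative", seed = 5)
  gpn1 <- build_gpn(sim$geno, sim$pheno)
  ph2 <- sim$pheno
  ph2$values[, 2] <- -ph2$values[, 2]
  gpn2 <- build_gpn(sim$geno, ph2)
  expect_equal(gpn2$T[2, ], -gpn1$T[2, ], tolerance = 1e-10)
  expect_equal(gpn2$T[-2, ], gpn1$T[-2, ], tolerance = 1e-10)
})

test_that("zero-variance SNP columns are zeroed with a warning", {
  g <- genotype_dataset(cbind(s1 = c(1, 1, 1, 1), s2 = c(0, 1, 2, 1)),
                        orient = FALSE)
  p <- phenotype_dataset(cbind(y = rnorm(4)))
  expect_warning(gpn <- build_gpn(g, p), "zero-variance")
  expect_equal(unname(gpn$T[, 1]), 0)
})

test_that("binary traits route through the saddlepoint engine under auto", {
  set.seed(21)
  n <- 800
  g <- genotype_dataset(matrix(rbinom(3 * n, 2, 0.3), n, 3), orient = FALSE)
  y <- rbinom(n, 1, 0.05)
  p <- phenotype_dataset(cbind(d = y))
  gpn_auto <- build_gpn(g, p, engine = "auto")
  gpn_norm <- build_gpn(g, p, engine = "normal")
  expect_s3_class(gpn_auto, "gpn_matrix")
  # hybrid rule: small-|z| entries identical to the normal engine
  small <- abs(zscores_from_gpn(gpn_norm)) < 2
  expect_equal(gpn_auto$pvals[small], gpn_norm$pvals[small], tolerance = 1e-12)
})
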