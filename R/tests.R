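# Per-SNP multiple-phenotype association tests: O'Brien, Omnibus, CLC,
# ceCLC, HCLC, MultiPhen. Tests run either on all K phenotypes jointly
# ("N.O.") or within each detected network module with Bonferroni
# combination across modules ("NET").

.test_outcome <- function(statistic, df, p, test_name) {
  list(statistic = statistic, df = df, p = min(max(p, 1e-320), 1),
       test_name = test_name)
}

#' Signed univariate z-score for one trait / SNP pair
#'
#' Quantitative traits use the normal score test (`z = S / sigma`); binary
#' traits take their magnitude from the saddlepoint-approximated p-value with
#' the score sign, `z = sign(S) * qnorm(1 - p/2)`, so extreme case-control
#' imbalance does not inflate the joint tests.
#'
#' @param y trait vector (residualized for quantitative; raw 0/1 for binary).
#' @param g genotype vector (residualized).
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param mu null case probabilities for binary traits (default trait mean).
#' @return signed z-score (0 for degenerate input).
#' @export
univariate_z <- function(y, g, trait_kind = c("quantitative", "binary"),
                         mu = NULL) {
  trait_kind <- match.arg(trait_kind)
  if (trait_kind == "quantitative") {
    return(score_test(y, g)$z)
  }
  if (is.null(mu)) mu <- mean(y)
  res <- spa_pvalue(y, g, mu = mu)
  if (res$S == 0 || res$p >= 1) return(0)
  sign(res$S) * stats::qnorm(res$p / 2, lower.tail = FALSE)
}

#' Convert a GPN matrix to signed per-entry z-scores
#'
#' `z_km = sign(T_km) * qnorm(1 - p_km / 2)`; inherits the saddlepoint
#' calibration of the network's p-values.
#'
#' @param gpn a `gpn_matrix` from [build_gpn()].
#' @return K x M matrix of signed z-scores.
#' @export
zscores_from_gpn <- function(gpn) {
  Z <- gpn$signs * stats::qnorm(pmin(gpn$pvals, 1) / 2, lower.tail = FALSE)
  Z[gpn$pvals >= 1] <- 0
  dimnames(Z) <- dimnames(gpn$T)
  Z
}

#' Null correlation matrix of trait residuals
#'
#' Pearson correlation of the phenotype residual columns; under the
#' no-association null this is the correlation of the univariate test
#' statistics. Eigenvalues are floored at `floor_eig` so the matrix is
#' always invertible (engages e.g. for duplicated traits).
#'
#' @param Y_block n x K' matrix of trait residuals.
#' @param floor_eig eigenvalue floor (default 1e-6).
#' @return K' x K' correlation matrix.
#' @export
estimate_R <- function(Y_block, floor_eig = 1e-6) {
  Y_block <- as.matrix(Y_block)
  sds <- apply(Y_block, 2, stats::sd)
  if (any(sds == 0)) stop("constant trait column(s); cannot estimate correlation")
  R <- stats::cor(Y_block)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < floor_eig) {
    vals <- pmax(ev$values, floor_eig)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  (R + t(R)) / 2
}

#' O'Brien (linear combination) test
#'
#' `statistic = 1' R^-1 z / sqrt(1' R^-1 1)`, standard normal under the
#' null; two-sided p-value. Powerful when all traits move in the same
#' direction, weak under opposite-direction effects.
#'
#' @param z vector of per-trait signed z-scores.
#' @param R trait correlation matrix from [estimate_R()].
#' @return test outcome list (`statistic`, `df`, `p`, `test_name`).
#' @export
obrien <- function(z, R) {
  w <- solve(R, rep(1, length(z)))
  stat <- sum(w * z) / sqrt(sum(w))
  .test_outcome(stat, NA_integer_, 2 * stats::pnorm(-abs(stat)), "obrien")
}

#' Omnibus (chi-square) test
#'
#' `statistic = z' R^-1 z`, chi-square with K' degrees of freedom under the
#' null.
#'
#' @inheritParams obrien
#' @return test outcome list.
#' @export
omnibus <- function(z, R) {
  stat <- sum(z * solve(R, z))
  K <- length(z)
  .test_outcome(stat, K, stats::pchisq(stat, df = K, lower.tail = FALSE),
                "omnibus")
}

#' Binary cluster-indicator matrix from labels
#' @param labels length-K' cluster labels (values `1..L`).
#' @return K' x L binary matrix with unit row sums.
#' @export
cluster_indicator <- function(labels) {
  labels <- as.integer(factor(labels))
  L <- max(labels)
  U <- matrix(0, length(labels), L)
  U[cbind(seq_along(labels), labels)] <- 1
  U
}

# Number of clusters by the largest relative gap between consecutive Ward
# merge heights; cutting between merges j and j+1 yields K - j clusters.
.gap_cluster_count <- function(hc) {
  K <- length(hc$order)
  h <- hc$height
  if (K <= 2L) return(K)
  j <- seq_len(K - 2L)
  gaps <- (h[j + 1L] - h[j]) / pmax(h[j], .Machine$double.eps)
  K - which.max(gaps)
}

#' Clustering linear combination (CLC) test
#'
#' Collapses the z-scores within each of L clusters and tests the collapsed
#' vector: `statistic = (U'R^-1 z)' (U'R^-1 U)^-1 (U'R^-1 z)`, chi-square
#' with L degrees of freedom. `U = I` recovers the Omnibus test; a single
#' cluster recovers the squared O'Brien statistic. When `U` is not supplied,
#' phenotypes are Ward-clustered on `1 - R` and the cluster count chosen by
#' the largest relative gap in merge heights.
#'
#' @inheritParams obrien
#' @param U K' x L binary cluster-indicator matrix (rows sum to 1, no empty
#'   cluster), or `NULL` to derive one from `R`.
#' @return test outcome list.
#' @export
clc <- function(z, R, U = NULL) {
  K <- length(z)
  if (is.null(U)) {
    if (K == 1L) {
      U <- matrix(1, 1, 1)
    } else {
      hc <- stats::hclust(stats::as.dist(1 - R), method = "ward.D2")
      U <- cluster_indicator(stats::cutree(hc, k = .gap_cluster_count(hc)))
    }
  }
  U <- as.matrix(U)
  if (any(rowSums(U) != 1)) stop("each phenotype must belong to exactly one cluster")
  if (any(colSums(U) == 0)) stop("empty cluster in indicator matrix")
  L <- ncol(U)
  RiZ <- solve(R, z)
  q <- drop(crossprod(U, RiZ))
  Mq <- crossprod(U, solve(R, U))
  stat <- sum(q * solve(Mq, q))
  .test_outcome(stat, L, stats::pchisq(stat, df = L, lower.tail = FALSE), "clc")
}

#' Cauchy combination (ACAT) of p-values
#'
#' `statistic = sum(w * tan((0.5 - p) * pi)) / sum(w)`; the combined p-value
#' is `0.5 - atan(statistic) / pi`, valid under arbitrary dependence of the
#' inputs. Identical inputs are a fixed point. p-values of exactly 0 or 1
#' are clipped to `[1e-15, 1 - 1e-15]` with a warning.
#'
#' @param p_values vector of p-values in (0, 1).
#' @param weights optional nonnegative weights (default equal).
#' @return combined p-value.
#' @export
acat <- function(p_values, weights = NULL) {
  if (!length(p_values)) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values >= 1)) {
    warning("p-values at 0 or 1 clipped to [1e-15, 1 - 1e-15]")
    p_values <- pmin(pmax(p_values, 1e-15), 1 - 1e-15)
  }
  if (is.null(weights)) weights <- rep(1, length(p_values))
  stat <- sum(weights * tan((0.5 - p_values) * pi)) / sum(weights)
  min(max(0.5 - atan(stat) / pi, 1e-320), 1)
}

# Ward dendrogram of traits on 1 - R (used by the CLC family).
.trait_dendrogram <- function(R) {
  stats::hclust(stats::as.dist(1 - R), method = "ward.D2")
}

# CLC p-values at a set of dendrogram levels (cluster counts).
.clc_level_pvals <- function(z, R, hc, levels) {
  vapply(levels, function(L) {
    U <- if (L == length(z)) diag(length(z)) else
      cluster_indicator(stats::cutree(hc, k = L))
    clc(z, R, U)$p
  }, numeric(1))
}

#' Cauchy-enhanced CLC (ceCLC) test
#'
#' Evaluates the CLC statistic at every cluster level `L = 1..K'` of a Ward
#' dendrogram built on the trait correlation matrix and combines the level
#' p-values with the Cauchy combination ([acat()]), so no single cluster
#' level has to be chosen.
#'
#' @inheritParams obrien
#' @param dendrogram optional precomputed `hclust` of the K' traits; by
#'   default Ward on `1 - R`.
#' @return test outcome list (statistic is the Cauchy combination statistic).
#' @export
ceclc <- function(z, R, dendrogram = NULL) {
  K <- length(z)
  if (K == 1L) {
    stat <- z[1]^2
    return(.test_outcome(stat, 1L,
                         stats::pchisq(stat, 1, lower.tail = FALSE), "ceclc"))
  }
  if (is.null(dendrogram)) dendrogram <- .trait_dendrogram(R)
  ps <- .clc_level_pvals(z, R, dendrogram, seq_len(K))
  p <- acat(pmin(pmax(ps, 1e-15), 1 - 1e-15))
  .test_outcome(tan((0.5 - p) * pi), NA_integer_, p, "ceclc")
}

#' Hierarchical CLC (HCLC) test
#'
#' Evaluates the CLC statistic along the dendrogram's merge levels
#' (`L = 2..K'`, each internal node of the Ward tree) and combines the level
#' p-values with the Cauchy combination. Differs from [ceclc()] by omitting
#' the single-cluster (O'Brien) level, so it tracks the hierarchy's actual
#' merge structure.
#'
#' @inheritParams ceclc
#' @return test outcome list.
#' @export
hclc <- function(z, R, dendrogram = NULL) {
  K <- length(z)
  if (K == 1L) {
    stat <- z[1]^2
    return(.test_outcome(stat, 1L,
                         stats::pchisq(stat, 1, lower.tail = FALSE), "hclc"))
  }
  if (is.null(dendrogram)) dendrogram <- .trait_dendrogram(R)
  ps <- .clc_level_pvals(z, R, dendrogram, 2:K)
  p <- acat(pmin(pmax(ps, 1e-15), 1 - 1e-15))
  .test_outcome(tan((0.5 - p) * pi), NA_integer_, p, "hclc")
}

#' MultiPhen reverse ordinal regression test
#'
#' Proportional-odds ordinal regression of the genotype categories
#' `{0, 1, 2}` on the K' phenotypes jointly, tested by likelihood ratio
#' against the intercept-only null (df = K'). Included for comparison only:
#' its type-I error is inflated for binary phenotypes with extremely
#' unbalanced case-control ratios.
#'
#' @param g length-n genotype vector (counts; rounded to `{0,1,2}`).
#' @param Y_block n x K' phenotype matrix.
#' @return test outcome list; `p = NA` with a warning on non-convergence or
#'   separation.
#' @export
multiphen <- function(g, Y_block) {
  Y_block <- as.matrix(Y_block)
  gf <- factor(round(g), levels = 0:2)
  gf <- droplevels(gf)
  K <- ncol(Y_block)
  if (nlevels(gf) < 2L) {
    warning("genotype has a single observed category; MultiPhen undefined")
    return(.test_outcome(NA_real_, K, NA_real_, "multiphen"))
  }
  res <- tryCatch({
    if (nlevels(gf) == 2L) {
      yb <- as.integer(gf) - 1L
      fit1 <- stats::glm(yb ~ Y_block, family = stats::binomial())
      fit0 <- stats::glm(yb ~ 1, family = stats::binomial())
      stat <- fit0$deviance - fit1$deviance
    } else {
      df_dat <- data.frame(gf = gf, Y_block)
      fit1 <- MASS::polr(gf ~ ., data = df_dat, Hess = FALSE)
      fit0 <- MASS::polr(gf ~ 1, data = df_dat, Hess = FALSE)
      stat <- fit0$deviance - fit1$deviance
    }
    .test_outcome(stat, K, stats::pchisq(stat, df = K, lower.tail = FALSE),
                  "multiphen")
  }, error = function(e) {
    warning(sprintf("MultiPhen did not converge: %s", conditionMessage(e)))
    .test_outcome(NA_real_, K, NA_real_, "multiphen")
  })
  res
}

.TEST_FUNS <- c("obrien", "omnibus", "clc", "ceclc", "hclc")

# Dispatch a z-based test by name on one z vector.
.run_test <- function(test_name, z, R, dendrogram = NULL) {
  switch(test_name,
         obrien = obrien(z, R),
         omnibus = omnibus(z, R),
         clc = clc(z, R),
         ceclc = ceclc(z, R, dendrogram),
         hclc = hclc(z, R, dendrogram),
         stop(sprintf("unknown test '%s'", test_name)))
}

#' Joint test of all phenotypes for one SNP (N.O. mode)
#'
#' @param z_full length-K vector of signed univariate z-scores.
#' @param R_full K x K trait correlation matrix.
#' @param test_name one of `"obrien"`, `"omnibus"`, `"clc"`, `"ceclc"`,
#'   `"hclc"`.
#' @return test outcome list.
#' @export
test_snp_no <- function(z_full, R_full, test_name) {
  .run_test(test_name, z_full, R_full)
}

#' Module-wise test of one SNP with Bonferroni combination (NET mode)
#'
#' Runs the named test within each detected module and combines across the
#' C modules by Bonferroni: `combined_p = min(1, C * min(module p))`.
#'
#' @inheritParams test_snp_no
#' @param partition a `module_partition` from [detect_modules()] (or any
#'   list with a `labels` vector aligned to `z_full`).
#' @return list with `module_outcomes` (per-module test outcome lists),
#'   `module_p` (named vector), `combined_p`.
#' @export
test_snp_net <- function(z_full, R_full, partition, test_name) {
  labels <- partition$labels
  stopifnot(length(labels) == length(z_full))
  mods <- sort(unique(labels))
  outcomes <- lapply(mods, function(m) {
    idx <- which(labels == m)
    .run_test(test_name, z_full[idx], R_full[idx, idx, drop = FALSE])
  })
  names(outcomes) <- paste0("module", mods)
  module_p <- vapply(outcomes, `[[`, numeric(1), "p")
  list(module_outcomes = outcomes, module_p = module_p,
       combined_p = min(1, length(mods) * min(module_p)))
}
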