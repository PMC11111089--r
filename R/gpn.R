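# Signed bipartite genotype-phenotype network (GPN).
#
# Edge (k, m) carries T_km = sign(S_km) * Qchi1(1 - p_km), where S_km is the
# score statistic between trait k and SNP m (after covariate residualization)
# and p_km its p-value from the normal approximation or, for binary traits
# with unbalanced case-control ratios, from a saddlepoint approximation of
# the score statistic's null distribution.

.P_MIN <- 1e-320

#' Residualize a matrix on covariates
#'
#' Each column is replaced by its residual from an ordinary least-squares fit
#' on an intercept plus the covariates. With no covariates this reduces to
#' mean-centering.
#'
#' @param values numeric matrix (n x q), columns are traits or SNPs.
#' @param covariates a [covariate_dataset()] or `NULL`.
#' @return matrix of residuals, same dimensions as `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(covariates) || length(covariates) == 0L)
    return(scale(values, center = TRUE, scale = FALSE)[, , drop = FALSE])
  X <- cbind(`(Intercept)` = 1, covariates$values)
  if (n <= ncol(X)) stop("need more samples than covariates + intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(drop_cols, collapse = ", ")))
  }
  qr.resid(qrX, values)
}

#' Score test for association between a centered trait and a genotype
#'
#' Computes `S = sum((y - mean(y)) * g)` with null variance
#' `sigma2 = sum((y - mean(y))^2) * sum((g - mean(g))^2) / n` and a two-sided
#' normal p-value for `z = S / sqrt(sigma2)`. For a quantitative trait `z`
#' equals `sqrt(n) * cor(y, g)` exactly. Degenerate input (constant `y` or
#' `g`) yields `S = 0, z = 0, p = 1` rather than an error.
#'
#' @param y numeric trait vector (length n >= 3).
#' @param g numeric genotype vector (same length).
#' @return list with `S`, `sigma2`, `z`, `p`, `method = "normal"`.
#' @export
score_test <- function(y, g) {
  stopifnot(length(y) == length(g), length(y) >= 3L)
  n <- length(y)
  yc <- y - mean(y)
  gc <- g - mean(g)
  S <- sum(yc * g)
  sigma2 <- sum(yc^2) * sum(gc^2) / n
  if (sigma2 <= 0) {
    return(list(S = 0, sigma2 = 0, z = 0, p = 1, method = "normal"))
  }
  z <- S / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(S = S, sigma2 = sigma2, z = z, p = max(p, .P_MIN), method = "normal")
}

# Cumulant generating function of S = sum(g * (y - mu)) for independent
# Bernoulli(mu) outcomes, and its first two derivatives.
.spa_cgf <- function(t, g, mu) {
  e <- exp(g * t)
  sum(log1p(mu * (e - 1))) - t * sum(g * mu)
}
.spa_cgf_d1 <- function(t, g, mu) {
  e <- exp(g * t)
  denom <- 1 - mu + mu * e
  sum(g * mu * e / denom) - sum(g * mu)
}
.spa_cgf_d2 <- function(t, g, mu) {
  e <- exp(g * t)
  denom <- 1 - mu + mu * e
  sum(g^2 * mu * (1 - mu) * e / denom^2)
}

# One-sided saddlepoint tail P(S >= s) (s > 0) or P(S <= s) (s < 0) using the
# Barndorff-Nielsen formula. Returns NA on root-finding failure.
.spa_tail <- function(s, g, mu) {
  rng <- range(g)
  if (rng[1] == rng[2]) return(NA_real_)
  kp <- function(t) .spa_cgf_d1(t, g, mu) - s
  # K'(t) is increasing; bracket the root by doubling, staying inside the
  # range where exp(g * t) cannot overflow.
  tmax <- 700 / max(abs(g))
  lo <- -min(1, tmax); hi <- min(1, tmax)
  while (kp(lo) >= 0 && lo > -tmax) lo <- max(lo * 2, -tmax)
  while (kp(hi) <= 0 && hi < tmax) hi <- min(hi * 2, tmax)
  if (kp(lo) > 0 || kp(hi) < 0) return(NA_real_)
  root <- tryCatch(
    stats::uniroot(kp, lower = lo, upper = hi, tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  t_hat <- root
  K <- .spa_cgf(t_hat, g, mu)
  K2 <- .spa_cgf_d2(t_hat, g, mu)
  if (!is.finite(K) || !is.finite(K2) || K2 <= 0) return(NA_real_)
  arg <- 2 * (t_hat * s - K)
  if (arg < 0) arg <- 0
  w <- sign(t_hat) * sqrt(arg)
  v <- t_hat * sqrt(K2)
  if (abs(w) < 1e-6 || abs(v) < 1e-12) {
    # saddlepoint at the mean: fall back to normal tail
    sd0 <- sqrt(.spa_cgf_d2(0, g, mu))
    return(stats::pnorm(-abs(s) / sd0))
  }
  z_bn <- w + log(v / w) / w
  if (s >= 0) stats::pnorm(z_bn, lower.tail = FALSE) else stats::pnorm(z_bn)
}

#' Saddlepoint-approximated p-value for a binary-trait score statistic
#'
#' For a 0/1 trait `y` with null case probabilities `mu` (from a null
#' logistic regression on covariates, or the trait mean with none) and a
#' residualized genotype `g`, the score statistic is
#' `S = sum(g * (y - mu))`. Its null cumulant generating function
#' `K(t) = sum(log(1 - mu + mu * exp(g t))) - t * sum(g * mu)` gives
#' two-sided tail probabilities via the Barndorff-Nielsen saddlepoint
#' formula, summing the upper tail at `|S|` and the lower tail at `-|S|`.
#' A hybrid speedup (`fastspa = TRUE`) returns the normal p-value when the
#' normal z-score is below `spa_cutoff` in absolute value, where the normal
#' approximation is accurate even under extreme case-control imbalance.
#'
#' @param y binary 0/1 vector.
#' @param g numeric genotype vector (residualized; not all equal).
#' @param mu null case probabilities in (0, 1); scalar or length-n vector.
#' @param fastspa use the normal p when `|z| < spa_cutoff`.
#' @param spa_cutoff hybrid threshold on `|z|` (default 2).
#' @return list with `S`, `sigma2` (null variance `K''(0)`), `z`, `p`,
#'   `method` (`"spa"` or `"normal"` when the hybrid or a fallback applied).
#' @export
spa_pvalue <- function(y, g, mu = mean(y), fastspa = TRUE, spa_cutoff = 2) {
  stopifnot(length(y) == length(g))
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly in (0, 1)")
  mu <- rep_len(mu, length(y))
  S <- sum(g * (y - mu))
  sigma2 <- sum(g^2 * mu * (1 - mu))
  if (sigma2 <= 0 || S == 0) {
    return(list(S = S, sigma2 = sigma2, z = 0, p = 1, method = "spa"))
  }
  z <- S / sqrt(sigma2)
  if (fastspa && abs(z) < spa_cutoff) {
    return(list(S = S, sigma2 = sigma2, z = z,
                p = max(2 * stats::pnorm(-abs(z)), .P_MIN), method = "normal"))
  }
  upper <- .spa_tail(abs(S), g, mu)
  lower <- .spa_tail(-abs(S), g, mu)
  if (is.na(upper) || is.na(lower)) {
    warning("saddlepoint root-finding failed; falling back to normal p-value")
    return(list(S = S, sigma2 = sigma2, z = z,
                p = max(2 * stats::pnorm(-abs(z)), .P_MIN), method = "normal"))
  }
  p <- min(1, upper + lower)
  list(S = S, sigma2 = sigma2, z = z, p = max(p, .P_MIN), method = "spa")
}

# Vectorized saddlepoint tails for one trait and many SNPs: column j of G
# gets the tail at s[j] (P(S >= s_j) for s_j > 0, P(S <= s_j) otherwise).
# Newton iteration on K'(t) = s with a uniroot fallback per column.
.spa_tail_batch <- function(s, G, mu) {
  P <- ncol(G)
  n <- nrow(G)
  gmax <- pmax(apply(abs(G), 2, max), .Machine$double.eps)
  tmax <- 700 / gmax
  k2_0 <- colSums(G^2 * (mu * (1 - mu)))
  sum_gmu <- colSums(G * mu)
  tv <- pmin(pmax(s / k2_0, -tmax), tmax)
  ok <- rep(FALSE, P)
  K1 <- K2 <- rep(NA_real_, P)
  for (iter in 1:50) {
    E <- exp(G * rep(tv, each = n))
    denom <- 1 - mu + mu * E
    W1 <- mu * E / denom
    K1 <- colSums(G * W1) - sum_gmu
    K2 <- colSums(G^2 * W1 * ((1 - mu) / denom))
    ok <- is.finite(K1) & is.finite(K2) & abs(K1 - s) < 1e-9 * (1 + abs(s))
    if (all(ok)) break
    step <- (K1 - s) / pmax(K2, 1e-300)
    step[!is.finite(step)] <- 0
    tv_new <- tv - ifelse(ok, 0, step)
    tv <- pmin(pmax(tv_new, -tmax), tmax)
  }
  out <- rep(NA_real_, P)
  E <- exp(G * rep(tv, each = n))
  Kval <- colSums(log1p(mu * (E - 1))) - tv * sum_gmu
  denom <- 1 - mu + mu * E
  W1 <- mu * E / denom
  K2 <- colSums(G^2 * W1 * ((1 - mu) / denom))
  arg <- pmax(2 * (tv * s - Kval), 0)
  w <- sign(tv) * sqrt(arg)
  v <- tv * sqrt(K2)
  good <- ok & is.finite(w) & is.finite(v) & abs(w) >= 1e-6 & abs(v) >= 1e-12
  zb <- w + log(v / w) / w
  up <- s >= 0
  out[good & up] <- stats::pnorm(zb[good & up], lower.tail = FALSE)
  out[good & !up] <- stats::pnorm(zb[good & !up])
  for (j in which(!good)) out[j] <- .spa_tail(s[j], G[, j], mu)
  out
}

# chi-square(1) transform of a p-value, computed on the upper tail directly
# so p down to 1e-320 maps to a finite strength without forming 1 - p.
.chi1_strength <- function(p) {
  stats::qchisq(pmin(pmax(p, .P_MIN), 1), df = 1, lower.tail = FALSE)
}

#' Build the signed bipartite genotype-phenotype network
#'
#' Computes the K x M association-strength matrix
#' `T_km = sign(S_km) * Qchi1(1 - p_km)` between every phenotype and every
#' SNP, where `Qchi1` is the chi-square(1) quantile function. Genotypes and
#' phenotypes are residualized on the covariates first (mean-centered when
#' none); missing genotypes are mean-imputed per SNP. p-values come from the
#' normal approximation of the score statistic, except for binary traits
#' under `engine = "auto"` or `"spa"`, which use the hybrid saddlepoint
#' approximation (accurate for extremely unbalanced case-control ratios).
#'
#' @param geno a [genotype_dataset()].
#' @param pheno a [phenotype_dataset()] (samples aligned with `geno`; use
#'   [align_samples()] first if needed).
#' @param covar a [covariate_dataset()] or `NULL`.
#' @param engine `"auto"` (SPA for binary traits, normal otherwise),
#'   `"normal"`, or `"spa"` (SPA for all binary traits; quantitative traits
#'   always use the normal score test).
#' @param spa_cutoff hybrid |z| threshold passed to [spa_pvalue()].
#' @return Object of class `gpn_matrix`: list with `T` (K x M), `signs`,
#'   `pvals`, `trait_ids`, `snp_ids`.
#' @export
build_gpn <- function(geno, pheno, covar = NULL,
                      engine = c("auto", "normal", "spa"), spa_cutoff = 2) {
  engine <- match.arg(engine)
  if (!identical(geno$sample_ids, pheno$sample_ids))
    stop("datasets are not sample-aligned; call align_samples() first")
  geno <- impute_genotypes(geno)
  n <- nrow(geno$counts)
  K <- length(pheno$trait_ids)
  M <- length(geno$snp_ids)

  G_res <- residualize(geno$counts, covar)
  Y_res <- residualize(pheno$values, covar)

  css_g <- colSums(G_res^2)
  css_y <- colSums(Y_res^2)
  zero_snp <- css_g <= 0
  if (any(zero_snp))
    warning(sprintf("%d zero-variance SNP column(s); their T entries set to 0",
                    sum(zero_snp)))

  S <- crossprod(Y_res, G_res)                     # K x M score statistics
  sigma2 <- outer(css_y, css_g) / n
  Z <- matrix(0, K, M)
  ok <- sigma2 > 0
  Z[ok] <- S[ok] / sqrt(sigma2[ok])
  P <- matrix(1, K, M)
  P[ok] <- 2 * stats::pnorm(-abs(Z[ok]))

  use_spa <- engine %in% c("auto", "spa") & pheno$trait_kind == "binary"
  if (any(use_spa)) {
    mu_list <- .null_case_probs(pheno, covar)
    for (k in which(use_spa)) {
      y <- pheno$values[, k]
      mu <- mu_list[[k]]
      Sk <- as.numeric(crossprod(G_res, y - mu))    # SPA score per SNP
      v <- as.numeric(crossprod(G_res^2, mu * (1 - mu)))
      zk <- ifelse(v > 0, Sk / sqrt(v), 0)
      need <- which(abs(zk) >= spa_cutoff & v > 0 & !zero_snp)
      pk <- ifelse(v > 0, 2 * stats::pnorm(-abs(zk)), 1)
      if (length(need)) {
        Gs <- G_res[, need, drop = FALSE]
        up <- .spa_tail_batch(abs(Sk[need]), Gs, mu)
        lo <- .spa_tail_batch(-abs(Sk[need]), Gs, mu)
        both <- !is.na(up) & !is.na(lo)
        pk[need[both]] <- pmin(1, up[both] + lo[both])
      }
      P[k, ] <- pmax(pk, .P_MIN)
      S[k, ] <- Sk
    }
  }
  P[, zero_snp] <- 1
  P <- pmin(pmax(P, .P_MIN), 1)

  signs <- sign(S)
  signs[P >= 1] <- 0
  Tm <- signs * .chi1_strength(P)
  Tm[, zero_snp] <- 0
  dimnames(Tm) <- list(pheno$trait_ids, geno$snp_ids)
  structure(list(T = Tm, signs = signs, pvals = P,
                 trait_ids = pheno$trait_ids, snp_ids = geno$snp_ids),
            class = "gpn_matrix")
}

# Null case probabilities per binary trait: logistic regression of y on the
# covariates (intercept-only reduces to the trait mean).
.null_case_probs <- function(pheno, covar) {
  K <- length(pheno$trait_ids)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    if (pheno$trait_kind[k] != "binary") next
    y <- pheno$values[, k]
    if (is.null(covar)) {
      out[[k]] <- rep(mean(y), length(y))
    } else {
      fit <- stats::glm.fit(cbind(1, covar$values), y,
                            family = stats::binomial())
      out[[k]] <- fit$fitted.values
    }
  }
  out
}

#' @export
print.gpn_matrix <- function(x, ...) {
  cat(sprintf("gpn_matrix: %d phenotypes x %d SNPs, mean |T| = %.3f\n",
              nrow(x$T), ncol(x$T), mean(abs(x$T))))
  invisible(x)
}

#' Build the network from GWAS summary statistics
#'
#' Individual-level genotypes are not required: each edge needs only the
#' effect direction and the association p-value,
#' `T_km = direction * Qchi1(1 - p)`. Pairs absent from the table get weight
#' 0 (their count is reported in a message).
#'
#' @param stats data.frame with columns `trait_id`, `snp_id`, `direction`
#'   (-1/+1), `p_value` in (0, 1] (see [read_summary_stats()]).
#' @param trait_ids,snp_ids row/column order of the output; defaults to the
#'   order of first appearance in `stats`.
#' @return Object of class `gpn_matrix`.
#' @export
build_gpn_from_summary <- function(stats, trait_ids = unique(stats$trait_id),
                                   snp_ids = unique(stats$snp_id)) {
  if (any(stats$p_value <= 0)) stop("p_value must be > 0")
  if (any(stats$p_value > 1)) stop("p_value must be <= 1")
  K <- length(trait_ids); M <- length(snp_ids)
  Tm <- matrix(0, K, M, dimnames = list(trait_ids, snp_ids))
  P <- matrix(1, K, M, dimnames = list(trait_ids, snp_ids))
  ki <- match(stats$trait_id, trait_ids)
  mi <- match(stats$snp_id, snp_ids)
  keep <- !is.na(ki) & !is.na(mi)
  idx <- cbind(ki[keep], mi[keep])
  P[idx] <- stats$p_value[keep]
  Tm[idx] <- stats$direction[keep] * .chi1_strength(stats$p_value[keep])
  n_missing <- K * M - sum(keep)
  if (n_missing > 0)
    message(sprintf("build_gpn_from_summary: %d (trait, SNP) pair(s) missing; weights set to 0",
                    n_missing))
  signs <- sign(Tm)
  structure(list(T = Tm, signs = signs, pvals = P,
                 trait_ids = trait_ids, snp_ids = snp_ids),
            class = "gpn_matrix")
}
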