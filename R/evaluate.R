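# Monte-Carlo harness: type-I-error calibration and power for the joint
# tests, with the replicate bookkeeping and binomial confidence bands used
# to judge calibration. Includes vectorized (all-SNPs-at-once) versions of
# the z-score-based tests.

#' 95% binomial confidence band for (type-I rate / nominal level)
#'
#' `1 +/- 1.959964 * sqrt((1 - alpha) / (alpha * n))`, reported to 3
#' decimals. At 10^6 replicates this gives (0.938, 1.062) for alpha = 0.001
#' and (0.804, 1.196) for alpha = 0.0001.
#'
#' @param alpha nominal significance level.
#' @param n_replicates number of null replicates.
#' @return named vector `c(lower, upper)`, rounded to 3 decimals.
#' @export
binomial_ci_ratio <- function(alpha, n_replicates) {
  if (alpha * n_replicates < 5)
    warning("alpha * n < 5: normal approximation to the binomial is unreliable")
  half <- 1.959964 * sqrt((1 - alpha) / (alpha * unname(n_replicates)))
  c(lower = round(1 - half, 3), upper = round(1 + half, 3))
}

#' Replicate bookkeeping for Monte-Carlo runs
#'
#' Each MC run contributes one replicate per SNP tested (all M null SNPs for
#' type-I error; the causal SNPs for power), so e.g. 500 runs x 2,000 null
#' SNPs = 10^6 type-I replicates and 10 runs x 100 causal SNPs = 1,000
#' power replicates.
#'
#' @param n_mc number of Monte-Carlo runs.
#' @param snps_per_run SNPs contributing per run.
#' @return total replicate count.
#' @export
mc_replicates <- function(n_mc, snps_per_run) {
  as.numeric(n_mc) * as.numeric(snps_per_run)
}

# ---- vectorized z-based tests over all SNP columns -------------------------

# Chi-square CLC statistics for all columns of Z at given cluster labels.
.batch_clc_stat <- function(Z, Ri, RiZ, labels) {
  L <- length(unique(labels))
  if (L == length(labels)) return(colSums(Z * RiZ))
  q <- rowsum(RiZ, labels)
  M2 <- rowsum(t(rowsum(Ri, labels)), labels)
  colSums(q * solve(M2, q))
}

#' Vectorized per-SNP p-values for one z-based joint test
#'
#' Same statistics as [obrien()], [omnibus()], [clc()], [ceclc()], [hclc()]
#' but computed for every column of a K' x M z-score matrix at once.
#'
#' @param Z K' x M matrix of signed z-scores (traits x SNPs).
#' @param R K' x K' trait correlation matrix.
#' @param test_name one of `"obrien"`, `"omnibus"`, `"clc"`, `"ceclc"`,
#'   `"hclc"`.
#' @return length-M vector of p-values.
#' @export
batch_test_pvals <- function(Z, R, test_name) {
  Z <- as.matrix(Z)
  K <- nrow(Z)
  if (K == 1L) {
    stat <- Z[1, ]^2
    return(switch(test_name,
                  obrien = 2 * stats::pnorm(-abs(Z[1, ])),
                  stats::pchisq(stat, 1, lower.tail = FALSE)))
  }
  Ri <- solve(R)
  if (test_name == "obrien") {
    w <- Ri %*% rep(1, K)
    stat <- drop(crossprod(w, Z)) / sqrt(sum(w))
    return(2 * stats::pnorm(-abs(stat)))
  }
  RiZ <- Ri %*% Z
  if (test_name == "omnibus") {
    stat <- colSums(Z * RiZ)
    return(stats::pchisq(stat, df = K, lower.tail = FALSE))
  }
  hc <- .trait_dendrogram(R)
  labelmat <- stats::cutree(hc, k = seq_len(K))
  if (test_name == "clc") {
    L <- .gap_cluster_count(hc)
    stat <- .batch_clc_stat(Z, Ri, RiZ, labelmat[, L])
    return(stats::pchisq(stat, df = L, lower.tail = FALSE))
  }
  levels <- if (test_name == "ceclc") seq_len(K) else 2:K
  if (!test_name %in% c("ceclc", "hclc"))
    stop(sprintf("unknown test '%s'", test_name))
  P <- matrix(NA_real_, length(levels), ncol(Z))
  for (i in seq_along(levels)) {
    L <- levels[i]
    nlab <- length(unique(labelmat[, L]))
    stat <- .batch_clc_stat(Z, Ri, RiZ, labelmat[, L])
    P[i, ] <- stats::pchisq(stat, df = nlab, lower.tail = FALSE)
  }
  P <- pmin(pmax(P, 1e-15), 1 - 1e-15)
  S <- colMeans(tan((0.5 - P) * pi))
  pmin(pmax(0.5 - atan(S) / pi, 1e-320), 1)
}

#' Vectorized NET-mode p-values (module-wise tests, Bonferroni combined)
#'
#' @inheritParams batch_test_pvals
#' @param partition `module_partition` (labels aligned to rows of `Z`).
#' @return length-M vector of Bonferroni-combined p-values.
#' @export
batch_test_pvals_net <- function(Z, R, partition, test_name) {
  labels <- partition$labels
  mods <- sort(unique(labels))
  C <- length(mods)
  pmat <- vapply(mods, function(m) {
    idx <- which(labels == m)
    batch_test_pvals(Z[idx, , drop = FALSE], R[idx, idx, drop = FALSE],
                     test_name)
  }, numeric(ncol(Z)))
  if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = 1)
  pmin(1, C * apply(pmat, 1, min))
}

# Residual trait correlation for a simulated dataset (no covariates:
# residual = centered observed trait values).
.sim_trait_R <- function(pheno) {
  estimate_R(residualize(pheno$values, NULL))
}

# One Monte-Carlo realization: p-values for the requested tests/modes.
.mc_run_pvals <- function(config, mode, tests, modes, B, cluster_on,
                          ratio_pool = NULL, partition_override = NULL) {
  sim <- simulate_dataset(config, mode = mode, ratio_pool = ratio_pool)
  gpn <- build_gpn(sim$geno, sim$pheno)
  Z <- zscores_from_gpn(gpn)
  R <- .sim_trait_R(sim$pheno)
  out <- list(sim = sim, pvals = list())
  partition <- NULL
  if ("NET" %in% modes) {
    partition <- if (is.null(partition_override))
      detect_modules(gpn, B = B, cluster_on = cluster_on)
    else partition_override
    out$partition <- partition
  }
  for (test in tests) {
    if (test == "multiphen") {
      geno_imp <- impute_genotypes(sim$geno)
      p_no <- vapply(seq_len(config$M), function(m)
        suppressWarnings(multiphen(geno_imp$counts[, m], sim$pheno$values)$p),
        numeric(1))
      if ("NO" %in% modes) out$pvals[[paste(test, "NO", sep = ".")]] <- p_no
      if ("NET" %in% modes) {
        labels <- partition$labels
        mods <- sort(unique(labels))
        pm <- vapply(mods, function(mod) {
          idx <- which(labels == mod)
          vapply(seq_len(config$M), function(m)
            suppressWarnings(multiphen(geno_imp$counts[, m],
                                       sim$pheno$values[, idx, drop = FALSE])$p),
            numeric(1))
        }, numeric(config$M))
        if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1)
        out$pvals[[paste(test, "NET", sep = ".")]] <-
          pmin(1, length(mods) * apply(pm, 1, min, na.rm = TRUE))
      }
    } else {
      if ("NO" %in% modes)
        out$pvals[[paste(test, "NO", sep = ".")]] <- batch_test_pvals(Z, R, test)
      if ("NET" %in% modes)
        out$pvals[[paste(test, "NET", sep = ".")]] <-
          batch_test_pvals_net(Z, R, partition, test)
    }
  }
  out
}

#' Type-I-error calibration by Monte-Carlo simulation
#'
#' Per MC run: simulate a null dataset (`beta = 0`), build the network,
#' detect modules (NET mode), test every SNP with each requested test, and
#' count p-values at or below the nominal level. Every null SNP of every run
#' is one replicate. The report compares the estimated rate / nominal ratio
#' with the binomial 95% band from [binomial_ci_ratio()].
#'
#' @param config a [factor_model_config()] with `beta = 0`.
#' @param phenotype_mode `"mixture"`, `"binary"` or `"quantitative"`.
#' @param tests character vector of test names (may include `"multiphen"`).
#' @param modes subset of `c("NO", "NET")`.
#' @param n_mc number of Monte-Carlo runs.
#' @param nominal nominal significance level(s).
#' @param B perturbation count for module detection.
#' @param seed integer seed; run r uses `seed + r`.
#' @param cluster_on passed to [detect_modules()].
#' @param ratio_pool passed to [simulate_dataset()] for binary mode.
#' @return data.frame with one row per (test, mode, nominal): columns
#'   `test`, `mode`, `nominal`, `n_replicates`, `rate`, `ratio`,
#'   `ci_lower`, `ci_upper`.
#' @export
run_type_i <- function(config, phenotype_mode = "mixture",
                       tests = c("ceclc", "clc", "hclc", "omnibus"),
                       modes = c("NO", "NET"), n_mc = 50, nominal = 0.001,
                       B = 100, seed = 1, cluster_on = "projection",
                       ratio_pool = NULL) {
  stopifnot(config$beta == 0)
  keys <- as.vector(outer(tests, intersect(c("NO", "NET"), modes),
                          paste, sep = "."))
  counts <- stats::setNames(rep(0, length(keys) * length(nominal)),
                            as.vector(outer(keys, nominal, paste, sep = "@")))
  n_valid <- stats::setNames(rep(0, length(keys)), keys)
  for (r in seq_len(n_mc)) {
    set.seed(seed + r)
    run <- .mc_run_pvals(config, phenotype_mode, tests, modes, B, cluster_on,
                         ratio_pool)
    for (key in names(run$pvals)) {
      p <- run$pvals[[key]]
      ok <- !is.na(p)
      n_valid[key] <- n_valid[key] + sum(ok)
      for (a in nominal)
        counts[paste(key, a, sep = "@")] <-
          counts[paste(key, a, sep = "@")] + sum(p[ok] <= a)
    }
  }
  rows <- do.call(rbind, lapply(keys, function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    do.call(rbind, lapply(nominal, function(a) {
      n <- n_valid[key]
      ci <- suppressWarnings(binomial_ci_ratio(a, n))
      rate <- counts[paste(key, a, sep = "@")] / n
      data.frame(test = parts[1], mode = parts[2], nominal = a,
                 n_replicates = n, rate = rate, ratio = rate / a,
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Power by Monte-Carlo simulation
#'
#' Power is the fraction of causal SNPs with p at or below the Bonferroni
#' level `0.05 / n_causal`, averaged over MC runs; each causal SNP of each
#' run is one replicate.
#'
#' @inheritParams run_type_i
#' @param config a [factor_model_config()] with `beta > 0`.
#' @param alpha family-wise level before Bonferroni correction (0.05).
#' @return data.frame with one row per (test, mode): `test`, `mode`,
#'   `beta`, `model_id`, `n_replicates`, `alpha_used`, `power`.
#' @export
run_power <- function(config, phenotype_mode = "mixture",
                      tests = "ceclc", modes = c("NO", "NET"), n_mc = 10,
                      B = 100, seed = 1, alpha = 0.05,
                      cluster_on = "projection", ratio_pool = NULL) {
  stopifnot(config$beta > 0)
  alpha_used <- alpha / config$n_causal
  keys <- as.vector(outer(tests, intersect(c("NO", "NET"), modes),
                          paste, sep = "."))
  hits <- stats::setNames(rep(0, length(keys)), keys)
  n_valid <- stats::setNames(rep(0, length(keys)), keys)
  for (r in seq_len(n_mc)) {
    set.seed(seed + r)
    run <- .mc_run_pvals(config, phenotype_mode, tests, modes, B, cluster_on,
                         ratio_pool)
    causal <- run$sim$truth$causal_idx
    for (key in names(run$pvals)) {
      p <- run$pvals[[key]][causal]
      ok <- !is.na(p)
      n_valid[key] <- n_valid[key] + sum(ok)
      hits[key] <- hits[key] + sum(p[ok] <= alpha_used)
    }
  }
  rows <- do.call(rbind, lapply(keys, function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(test = parts[1], mode = parts[2], beta = config$beta,
               model_id = config$model_id, n_replicates = n_valid[key],
               alpha_used = alpha_used, power = hits[key] / n_valid[key])
  }))
  rownames(rows) <- NULL
  rows
}
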