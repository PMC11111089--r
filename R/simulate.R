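# Factor-model phenotype simulator with planted category structure, six
# causal-effect models, and liability-threshold binary traits with extreme
# case-control imbalance.
#
# Quantitative phenotypes in category c follow
#   Y_c = G B_c + c0 * f_c 1_k' + sqrt(1 - c0^2) * E_c
# with AR(1) errors (Sigma_ij = rho^|i-j|) within category and an
# exchangeable factor correlation rho_f between categories, so with beta = 0
# the within-category correlation is c0^2 + (1 - c0^2) rho^|i-j| and the
# between-category correlation is c0^2 * rho_f.

#' Factor-model simulation configuration
#'
#' Defaults are the study conditions used throughout: `c0^2 = 0.5`,
#' `rho = 0.3`, `rho_f = 0.3 / c0^2` (so the between-category correlation is
#' 0.3 and the maximum within-category correlation is 0.65), `M = 2000` SNPs
#' with MAF ~ U(0.05, 0.5), and 100 causal SNPs for models 1-4 / 200 for
#' models 5-6.
#'
#' @param N sample count.
#' @param K phenotype count (must equal `C * k`).
#' @param C number of phenotype categories.
#' @param M SNP count.
#' @param c0_sq squared shared-factor loading, in (0, 1).
#' @param rho AR(1) error correlation within a category.
#' @param rho_f factor correlation between categories.
#' @param maf_low,maf_high bounds of the uniform MAF distribution.
#' @param model_id effect model, 1-6.
#' @param beta effect size (0 = global null).
#' @param n_causal number of causal SNPs; default 100 for models 1-4 and
#'   200 for models 5-6.
#' @return list of validated settings (class `factor_model_config`).
#' @export
factor_model_config <- function(N, K, C, M = 2000, c0_sq = 0.5, rho = 0.3,
                                rho_f = 0.3 / c0_sq, maf_low = 0.05,
                                maf_high = 0.5, model_id = 1, beta = 0,
                                n_causal = if (model_id <= 4) 100 else 200) {
  if (K %% C != 0) stop("K must be a multiple of C (equal phenotypes per category)")
  if (c0_sq <= 0 || c0_sq >= 1) stop("c0_sq must lie in (0, 1)")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (rho_f < 0 || rho_f > 1) stop("rho_f must lie in [0, 1]")
  if (!model_id %in% 1:6) stop("model_id must be 1..6")
  if (beta != 0 && n_causal > M) stop("more causal SNPs than SNPs")
  structure(list(N = N, K = K, C = C, k = K %/% C, M = M, c0_sq = c0_sq,
                 rho = rho, rho_f = rho_f, maf_low = maf_low,
                 maf_high = maf_high, model_id = model_id, beta = beta,
                 n_causal = n_causal),
            class = "factor_model_config")
}

#' Closed-form phenotype correlation implied by the factor model at beta = 0
#'
#' Within one category, traits i and j correlate at
#' `c0^2 + (1 - c0^2) * rho^|i - j|`; across categories the correlation is
#' `c0^2 * rho_f`.
#'
#' @param lag `|i - j|` between two traits of the same category, or `NULL`
#'   for the between-category value.
#' @param c0_sq squared shared-factor loading.
#' @param rho AR(1) error correlation.
#' @param rho_f factor correlation (needed when `lag` is `NULL`).
#' @return correlation value.
#' @export
factor_model_correlation <- function(lag = 1, c0_sq = 0.5, rho = 0.3,
                                     rho_f = 0.3 / c0_sq) {
  if (is.null(lag)) return(c0_sq * rho_f)
  c0_sq + (1 - c0_sq) * rho^abs(lag)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per-SNP MAF drawn from U(maf_low, maf_high); counts i.i.d.
#' Binomial(2, MAF).
#'
#' @param N,M sample and SNP counts.
#' @param maf_low,maf_high MAF bounds.
#' @param seed optional integer seed.
#' @return a [genotype_dataset()] (orientation not re-applied; the drawn MAF
#'   is recorded in attribute `"drawn_maf"`).
#' @export
gen_genotypes <- function(N, M, maf_low = 0.05, maf_high = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- stats::runif(M, maf_low, maf_high)
  counts <- matrix(stats::rbinom(N * M, 2L, rep(maf, each = N)), N, M)
  out <- genotype_dataset(counts, sample_ids = paste0("sample", seq_len(N)),
                          snp_ids = paste0("snp", seq_len(M)), orient = FALSE)
  attr(out, "drawn_maf") <- maf
  out
}

#' Per-category effect matrices for the six simulation models
#'
#' Causal SNP rows carry one of two patterns across the k phenotypes of an
#' affected category: `lambda1 = beta * (1, ..., 1)` or
#' `lambda2 = (2 * beta / (k + 1)) * (1, ..., k)`. The six models:
#' \describe{
#'   \item{1 / 2}{all causal SNPs affect category 1 with lambda1 / lambda2.}
#'   \item{3 / 4}{causal SNPs affect categories 1 and 2 with lambda1, in the
#'     same / opposite directions.}
#'   \item{5 / 6}{causal SNPs split in halves, the first half affecting
#'     category 1 and the second category 2, with lambda1 / lambda2.}
#' }
#'
#' @param config a [factor_model_config()].
#' @param seed optional integer seed (causal SNPs are sampled without
#'   replacement).
#' @return list with `B` (list of C M x k matrices), `causal_idx` (integer
#'   SNP indices), `affected_categories`.
#' @export
effect_matrix <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- config$M; k <- config$k; C <- config$C
  beta <- config$beta; id <- config$model_id
  if (config$n_causal > M) stop("more causal SNPs than SNPs")
  causal <- sort(sample.int(M, config$n_causal))
  lambda1 <- rep(beta, k)
  lambda2 <- (2 * beta / (k + 1)) * seq_len(k)
  B <- lapply(seq_len(C), function(c) matrix(0, M, k))
  set_rows <- function(cat, rows, pattern) {
    B[[cat]][rows, ] <<- matrix(pattern, length(rows), k, byrow = TRUE)
  }
  if (id == 1L) {
    set_rows(1L, causal, lambda1)
    affected <- 1L
  } else if (id == 2L) {
    set_rows(1L, causal, lambda2)
    affected <- 1L
  } else if (id == 3L) {
    set_rows(1L, causal, lambda1)
    set_rows(2L, causal, lambda1)
    affected <- 1:2
  } else if (id == 4L) {
    set_rows(1L, causal, lambda1)
    set_rows(2L, causal, -lambda1)
    affected <- 1:2
  } else {
    pattern <- if (id == 5L) lambda1 else lambda2
    half <- length(causal) %/% 2
    set_rows(1L, causal[seq_len(half)], pattern)
    set_rows(2L, causal[seq(half + 1L, length(causal))], pattern)
    affected <- 1:2
  }
  if (config$C < max(affected))
    stop("model needs at least 2 categories")
  list(B = B, causal_idx = causal, affected_categories = affected)
}

#' Planted-category effects with a hierarchical sharing structure
#'
#' Splits the causal SNPs into C equal blocks and gives every category a
#' genetic signature built from those blocks, with cross-category sharing
#' following a random ultrametric (binary-tree) similarity matrix whose
#' pairwise values lie in about [0.1, 0.6]. Each category is therefore
#' genetically distinct, but categories are hierarchically related with
#' distinct separation levels, the regime in which hierarchical clustering
#' has a well-defined stable partition at every cut up to C. Used for
#' module-recovery experiments.
#'
#' @inheritParams effect_matrix
#' @return same structure as [effect_matrix()].
#' @export
planted_category_effects <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- config$M; k <- config$k; C <- config$C
  if (config$n_causal > M) stop("more causal SNPs than SNPs")
  causal <- sort(sample.int(M, config$n_causal))
  blocks <- split(causal, rep(seq_len(C), length.out = length(causal)))
  if (C > 1L) {
    pts <- stats::rnorm(C)
    h <- as.matrix(stats::cophenetic(stats::hclust(stats::dist(pts),
                                                   method = "complete")))
    h <- 0.51 + (h / max(h)) * 1.8     # similarity exp(-h) in ~[0.10, 0.60]
    A <- exp(-h)
    diag(A) <- 1
    L <- chol(A)                        # A = t(L) %*% L; column c = profile
  } else {
    L <- matrix(1, 1, 1)
  }
  B <- lapply(seq_len(C), function(cc) {
    Bc <- matrix(0, M, k)
    for (b in seq_len(C))
      if (abs(L[b, cc]) > 1e-12) Bc[blocks[[b]], ] <- config$beta * L[b, cc]
    Bc
  })
  list(B = B, causal_idx = causal, affected_categories = seq_len(C))
}

# Cholesky factor of the AR(1) correlation matrix rho^|i-j| (k x k).
.ar1_chol <- function(k, rho) {
  chol(rho^abs(outer(seq_len(k), seq_len(k), "-")))
}

#' Simulate quantitative phenotypes from the factor model
#'
#' @param config a [factor_model_config()].
#' @param G N x M genotype count matrix (from [gen_genotypes()]).
#' @param effects effect structure from [effect_matrix()]; `NULL` means the
#'   global null (beta = 0).
#' @param seed optional integer seed.
#' @return a [phenotype_dataset()] with K quantitative traits named
#'   `cat<c>_t<j>`, plus attribute `"category"` (per-trait category index).
#' @export
gen_quantitative <- function(config, G, effects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(G); C <- config$C; k <- config$k
  c0 <- sqrt(config$c0_sq)
  Sigma_f <- (1 - config$rho_f) * diag(C) + config$rho_f
  ev <- min(eigen(Sigma_f, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-12) stop("factor covariance is not positive semidefinite")
  f <- matrix(stats::rnorm(N * C), N, C) %*% chol(Sigma_f)   # N x C factors
  cholS <- .ar1_chol(k, config$rho)
  Y <- matrix(0, N, C * k)
  for (c in seq_len(C)) {
    E <- matrix(stats::rnorm(N * k), N, k) %*% cholS
    Yc <- c0 * f[, c] %*% t(rep(1, k)) + sqrt(1 - config$c0_sq) * E
    if (!is.null(effects)) {
      Bc <- effects$B[[c]]
      nz <- which(rowSums(Bc != 0) > 0)
      if (length(nz))
        Yc <- Yc + G[, nz, drop = FALSE] %*% Bc[nz, , drop = FALSE]
    }
    Y[, (c - 1) * k + seq_len(k)] <- Yc
  }
  ids <- paste0("cat", rep(seq_len(C), each = k), "_t", rep(seq_len(k), C))
  out <- phenotype_dataset(Y, sample_ids = paste0("sample", seq_len(N)),
                           trait_ids = ids,
                           trait_kind = rep("quantitative", C * k))
  attr(out, "category") <- rep(seq_len(C), each = k)
  out
}

#' Liability-threshold dichotomization
#'
#' For case-control ratio `r` and sample size `N`, the `n_a = rN / (r + 1)`
#' individuals with the highest liability are cases (1) and the remaining
#' `n_c = N / (r + 1)` are controls (0). The case count is rounded
#' half-to-even; ranking ties are broken by stable sample order.
#'
#' @param y numeric liability vector.
#' @param r case-control ratio (> 0).
#' @return integer 0/1 vector with exactly `round(r * N / (r + 1))` ones.
#' @export
dichotomize <- function(y, r) {
  N <- length(y)
  n_a <- round(r * N / (r + 1))
  if (n_a < 1) stop(sprintf("ratio %g yields zero cases at N = %d", r, N))
  if (n_a >= N) stop("ratio yields zero controls")
  out <- integer(N)
  out[order(y, decreasing = TRUE)[seq_len(n_a)]] <- 1L
  out
}

#' Default pool of extremely unbalanced case-control ratios
#'
#' Five ratios spanning the range observed for EHR-derived diseases of the
#' musculoskeletal system in a large biobank (0.000658 to 0.03937, i.e.
#' roughly 1 case per 1,500 down to 1 per 25 individuals). `min_cases`
#' restricts the pool to ratios yielding at least that many cases at sample
#' size `N`, so desk-scale runs keep a usable case count.
#'
#' @param N sample size used to enforce `min_cases` (`NULL` = no restriction).
#' @param min_cases minimum acceptable case count.
#' @return numeric vector of admissible ratios.
#' @export
default_ratio_pool <- function(N = NULL, min_cases = 10) {
  pool <- c(0.000658, 0.002, 0.005, 0.015, 0.03937)
  if (!is.null(N)) {
    keep <- round(pool * N / (pool + 1)) >= min_cases
    if (!any(keep)) stop("no ratio in the pool yields enough cases at this N")
    pool <- pool[keep]
  }
  pool
}

#' Sample a case-control ratio from a pool
#' @param pool numeric vector of admissible ratios.
#' @param seed optional integer seed.
#' @return one ratio, drawn uniformly.
#' @export
sample_ratio <- function(pool = default_ratio_pool(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool[sample.int(length(pool), 1L)]
}

#' Simulate a full dataset (genotypes, phenotypes, truth)
#'
#' Two compositions mirror the evaluation settings:
#' \describe{
#'   \item{`mixture`}{half the traits of each category stay quantitative,
#'     the other half are dichotomized at the balanced ratio r = 1.}
#'   \item{`binary`}{every trait is dichotomized at a ratio drawn from
#'     `ratio_pool` (extremely unbalanced).}
#'   \item{`quantitative`}{no dichotomization.}
#' }
#'
#' @param config a [factor_model_config()].
#' @param mode `"mixture"`, `"binary"` or `"quantitative"`.
#' @param seed integer seed driving every random draw.
#' @param ratio_pool pool for the binary mode (default
#'   `default_ratio_pool(N)`).
#' @return list of class `simulated_dataset` with `geno`
#'   ([genotype_dataset()]), `pheno` ([phenotype_dataset()]), `liability`
#'   (the underlying quantitative traits), `truth` (causal indices, affected
#'   categories, per-trait category, ratios used) and `config`.
#' @export
simulate_dataset <- function(config, mode = c("mixture", "binary", "quantitative"),
                             seed = NULL, ratio_pool = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  geno <- gen_genotypes(config$N, config$M, config$maf_low, config$maf_high)
  effects <- if (config$beta != 0) effect_matrix(config) else NULL
  liab <- gen_quantitative(config, geno$counts, effects)
  category <- attr(liab, "category")

  values <- liab$values
  kind <- rep("quantitative", config$K)
  ratios <- rep(NA_real_, config$K)
  if (mode == "mixture") {
    within <- rep(seq_len(config$k), config$C)
    make_binary <- within > config$k / 2
    for (j in which(make_binary)) {
      values[, j] <- dichotomize(values[, j], 1)
      kind[j] <- "binary"; ratios[j] <- 1
    }
  } else if (mode == "binary") {
    if (is.null(ratio_pool)) ratio_pool <- default_ratio_pool(config$N)
    for (j in seq_len(config$K)) {
      r <- ratio_pool[sample.int(length(ratio_pool), 1L)]
      values[, j] <- dichotomize(values[, j], r)
      kind[j] <- "binary"; ratios[j] <- r
    }
  }
  pheno <- phenotype_dataset(values, sample_ids = liab$sample_ids,
                             trait_ids = liab$trait_ids, trait_kind = kind)
  structure(list(
    geno = geno, pheno = pheno, liability = liab,
    truth = list(causal_idx = if (is.null(effects)) integer(0) else effects$causal_idx,
                 affected_categories = if (is.null(effects)) integer(0) else
                   effects$affected_categories,
                 category = category, ratios = ratios),
    config = config), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: N = %d, M = %d SNPs, K = %d traits (%d binary), %d causal SNPs\n",
              x$config$N, x$config$M, x$config$K,
              sum(x$pheno$trait_kind == "binary"),
              length(x$truth$causal_idx)))
  invisible(x)
}
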