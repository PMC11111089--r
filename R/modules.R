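# Community detection: Ward clustering of the phenotype network, with the
# number of modules chosen by a perturbation-stability procedure on the
# association-strength matrix.

#' Ward dendrogram of phenotypes from the genetic-correlation network
#'
#' Agglomerative Ward linkage (`hclust` method `"ward.D2"`) on the
#' dissimilarity `d_kl = 1 - W_kl`, so perfectly anti-correlated phenotypes
#' are maximally distant (d = 2). Tie-breaks are `hclust`'s deterministic
#' leaf-index order.
#'
#' @param ppn a `ppn_matrix` from [project_ppn()], or a bare symmetric
#'   correlation-like matrix.
#' @return an `hclust` object.
#' @export
ward_dendrogram <- function(ppn) {
  W <- if (is.matrix(ppn)) ppn else ppn$W
  if (nrow(W) < 2L) stop("need at least 2 phenotypes to cluster")
  d <- stats::as.dist(1 - W)
  stats::hclust(d, method = "ward.D2")
}

#' Connectivity matrix of a cluster assignment
#'
#' `C(k, l) = 1` iff phenotypes k and l carry the same cluster label.
#'
#' @param labels vector of cluster labels.
#' @return K x K binary matrix.
#' @export
connectivity <- function(labels) {
  if (!length(labels)) stop("labels must be nonempty")
  outer(labels, labels, "==") * 1
}

#' Perturb an association-strength matrix
#'
#' Adds i.i.d. Gaussian noise `N(0, sigma2)` to every entry, where `sigma2`
#' is the median of the per-SNP-column sample variances of `T` (each column
#' variance taken over its K phenotype entries). If all columns are constant
#' (`sigma2 = 0`) the matrix is returned unchanged with a warning.
#'
#' @param Tm K x M matrix (or `gpn_matrix`).
#' @param seed optional integer seed for reproducibility.
#' @return list with `T` (perturbed matrix) and `sigma2`.
#' @export
perturb <- function(Tm, seed = NULL) {
  if (!is.matrix(Tm)) Tm <- Tm$T
  if (nrow(Tm) < 2L) stop("need K >= 2 phenotype rows")
  sigma2 <- perturb_sigma2(Tm)
  if (sigma2 <= 0) {
    warning("all SNP columns of T are constant; perturbation is degenerate")
    return(list(T = Tm, sigma2 = 0))
  }
  if (!is.null(seed)) set.seed(seed)
  list(T = Tm + matrix(stats::rnorm(length(Tm), sd = sqrt(sigma2)),
                       nrow(Tm), ncol(Tm)),
       sigma2 = sigma2)
}

#' Perturbation noise variance: median of per-SNP-column variances of T
#' @param Tm K x M matrix.
#' @return scalar variance.
#' @export
perturb_sigma2 <- function(Tm) {
  if (!is.matrix(Tm)) Tm <- Tm$T
  K <- nrow(Tm)
  mu <- colMeans(Tm)
  stats::median(colSums((Tm - rep(mu, each = K))^2) / (K - 1))
}

# Cluster a T matrix: Ward on Euclidean row distances, or project to the
# phenotype network first and Ward-cluster 1 - W.
.cluster_T <- function(Tm, on = c("rows", "projection")) {
  on <- match.arg(on)
  if (on == "projection") {
    ward_dendrogram(suppressWarnings(project_ppn(Tm)))
  } else {
    stats::hclust(stats::dist(Tm), method = "ward.D2")
  }
}

#' Stability (AF) curve over candidate module counts
#'
#' For each candidate count `k0 = 1..K`: cut the unperturbed dendrogram at
#' `k0` to get connectivity matrix `C_k0`; cut each of `B` perturbed
#' datasets' dendrograms at `k0` and average their connectivity matrices to
#' get `A_k0`; form `D_k0 = |A_k0 - C_k0|`; `F_k0` is the empirical CDF of
#' the K^2 entries of `D_k0` and `AF_k0` its area under the curve on
#' `[0, 1]`, computed by the exact identity `AF = 1 - mean(D)`.
#'
#' @param Tm K x M association-strength matrix (or `gpn_matrix`).
#' @param B number of perturbed datasets (>= 2).
#' @param seed integer seed for the perturbations.
#' @param cluster_on `"rows"` (cluster perturbed T rows directly on
#'   Euclidean distance; default) or `"projection"` (perturb T, re-project,
#'   Ward-cluster the perturbed network). Entrywise noise shrinks all
#'   projected correlations nearly uniformly, so the projection mode leaves
#'   Ward's decisions almost unchanged and its stability curve saturates
#'   near 1; the rows mode is the discriminating variant.
#' @return list with `af` (length-K vector), `sigma2`, `B`,
#'   `dendrogram` (unperturbed `hclust`).
#' @export
af_curve <- function(Tm, B = 1000, seed = NULL,
                     cluster_on = c("rows", "projection")) {
  cluster_on <- match.arg(cluster_on)
  if (!is.matrix(Tm)) Tm <- Tm$T
  if (B < 2) stop("B must be >= 2")
  K <- nrow(Tm)
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- perturb_sigma2(Tm)

  h0 <- .cluster_T(Tm, cluster_on)
  labels0 <- stats::cutree(h0, k = seq_len(K))        # K x K label matrix

  # Accumulate sum over b of the perturbed connectivity, per k0.
  Asum <- array(0, dim = c(K, K, K))
  degenerate <- sigma2 <= 0
  if (degenerate)
    warning("all SNP columns of T are constant; perturbation is degenerate")
  for (b in seq_len(B)) {
    Tb <- if (degenerate) Tm else
      Tm + matrix(stats::rnorm(length(Tm), sd = sqrt(sigma2)), K, ncol(Tm))
    hb <- .cluster_T(Tb, cluster_on)
    lb <- stats::cutree(hb, k = seq_len(K))
    for (k0 in seq_len(K))
      Asum[, , k0] <- Asum[, , k0] + connectivity(lb[, k0])
  }
  af <- numeric(K)
  for (k0 in seq_len(K)) {
    D <- abs(Asum[, , k0] / B - connectivity(labels0[, k0]))
    af[k0] <- 1 - mean(D)
  }
  list(af = af, sigma2 = sigma2, B = B, dendrogram = h0)
}

#' Choose the number of modules from the AF curve
#'
#' Returns the smallest `k` in `1..K-1` maximizing `|AF_{k+1} - AF_k|`. On a
#' dataset with a planted cluster count `C` the stability curve stays near 1
#' up to `k = C` and drops at `k = C + 1`, so the largest jump sits at
#' `k = C`.
#'
#' @param af numeric stability vector of length K >= 2.
#' @return integer module count in `1..K-1`.
#' @export
select_modules <- function(af) {
  K <- length(af)
  if (K < 2) stop("af must have at least 2 entries")
  jumps <- abs(diff(af))
  which.max(jumps)   # first index attaining the maximum
}

#' Detect phenotype modules
#'
#' Full pipeline: stability curve by perturbation ([af_curve()]), module
#' count by the largest stability jump ([select_modules()]), labels by
#' cutting the unperturbed Ward dendrogram at that count.
#'
#' @inheritParams af_curve
#' @return Object of class `module_partition`: list with `labels` (named
#'   integer vector), `C` (module count), `af`, `sigma2`, `B`, `dendrogram`,
#'   `trait_ids`.
#' @export
detect_modules <- function(Tm, B = 1000, seed = NULL,
                           cluster_on = c("rows", "projection")) {
  cluster_on <- match.arg(cluster_on)
  trait_ids <- if (is.matrix(Tm)) rownames(Tm) else Tm$trait_ids
  if (!is.matrix(Tm)) Tm <- Tm$T
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(nrow(Tm)))
  ac <- af_curve(Tm, B = B, seed = seed, cluster_on = cluster_on)
  C <- select_modules(ac$af)
  labels <- stats::cutree(ac$dendrogram, k = C)
  names(labels) <- trait_ids
  structure(list(labels = labels, C = C, af = ac$af, sigma2 = ac$sigma2,
                 B = ac$B, dendrogram = ac$dendrogram, trait_ids = trait_ids),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d phenotypes in %d module(s) (B = %d)\n",
              length(x$labels), x$C, x$B))
  print(table(module = x$labels))
  invisible(x)
}
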