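# One-mode projection of the bipartite network onto phenotypes.

#' Project the genotype-phenotype network onto phenotypes
#'
#' The phenotype-phenotype network (PPN) adjacency is the K x K matrix of
#' Pearson correlations between rows of the association-strength matrix `T`,
#' taken over the M SNPs:
#' `W_kl = sum_m (T_km - Tbar_k)(T_lm - Tbar_l) / sqrt(sum_m (T_km - Tbar_k)^2 sum_m (T_lm - Tbar_l)^2)`.
#' `W_kl` is interpreted as the genetic correlation between phenotypes k and
#' l, a signed quantity in `[-1, 1]`. Rows of `T` with zero variance get 0
#' off-diagonal entries (with a warning) and 1 on the diagonal.
#'
#' @param gpn a `gpn_matrix` from [build_gpn()], or a bare K x M matrix.
#' @return Object of class `ppn_matrix`: list with `W` (K x K) and
#'   `trait_ids`.
#' @export
project_ppn <- function(gpn) {
  Tm <- if (is.matrix(gpn)) gpn else gpn$T
  trait_ids <- if (is.matrix(gpn)) {
    if (is.null(rownames(gpn))) paste0("trait", seq_len(nrow(gpn))) else rownames(gpn)
  } else gpn$trait_ids
  if (ncol(Tm) < 2L) stop("projection needs at least 2 SNP columns")
  Tc <- Tm - rowMeans(Tm)
  ss <- rowSums(Tc^2)
  zero <- ss <= 0
  if (any(zero))
    warning(sprintf("%d constant row(s) of T; their correlations set to 0",
                    sum(zero)))
  denom <- sqrt(ss)
  denom[zero] <- 1
  Tn <- Tc / denom
  W <- tcrossprod(Tn)
  W[zero, ] <- 0
  W[, zero] <- 0
  diag(W) <- 1
  W[W > 1] <- 1
  W[W < -1] <- -1
  dimnames(W) <- list(trait_ids, trait_ids)
  structure(list(W = W, trait_ids = trait_ids), class = "ppn_matrix")
}

#' @export
print.ppn_matrix <- function(x, ...) {
  off <- x$W[upper.tri(x$W)]
  cat(sprintf("ppn_matrix: %d phenotypes, off-diagonal range [%.3f, %.3f]\n",
              nrow(x$W), min(off), max(off)))
  invisible(x)
}
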