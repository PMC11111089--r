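#' Construct a genotype dataset
#'
#' Container for a sample-by-SNP matrix of minor-allele counts. Counts are
#' oriented so that each column counts copies of the minor allele; columns
#' whose raw allele frequency exceeds 0.5 are flipped (`c -> 2 - c`) and the
#' per-SNP minor-allele frequency (MAF) is recomputed from the non-missing
#' entries.
#'
#' @param counts integer matrix (n samples x M SNPs) with entries in
#'   `{0, 1, 2}`; `NA` marks a missing genotype.
#' @param sample_ids,snp_ids unique identifiers for rows and columns.
#' @param orient if `TRUE` (default), enforce minor-allele orientation.
#' @return An object of class `genotype_dataset` with elements `counts`,
#'   `sample_ids`, `snp_ids` and `maf`.
#' @examples
#' g <- genotype_dataset(matrix(c(0, 1, 2, 1, 1, 0), nrow = 3),
#'                       sample_ids = c("a", "b", "c"),
#'                       snp_ids = c("s1", "s2"))
#' g$maf
#' @export
genotype_dataset <- function(counts, sample_ids = rownames(counts),
                             snp_ids = colnames(counts), orient = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(counts)))
  if (nrow(counts) < 2L) stop("genotype dataset needs at least 2 samples")
  if (ncol(counts) < 1L) stop("genotype dataset needs at least 1 SNP")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  bad <- which(!is.na(counts) & !(counts %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("genotype value not in {0,1,2,NA} at row %d (%s), column %d (%s)",
                 rc[1], sample_ids[rc[1]], rc[2], snp_ids[rc[2]]))
  }
  storage.mode(counts) <- "double"
  if (orient) {
    af <- colMeans(counts, na.rm = TRUE) / 2
    flip <- which(!is.na(af) & af > 0.5)
    if (length(flip)) counts[, flip] <- 2 - counts[, flip]
  }
  maf <- colMeans(counts, na.rm = TRUE) / 2
  dimnames(counts) <- list(sample_ids, snp_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 snp_ids = snp_ids, maf = maf),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs, MAF range [%.4g, %.4g]\n",
              nrow(x$counts), ncol(x$counts), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Construct a phenotype dataset
#'
#' Holds an n x K matrix of traits. Traits whose non-missing values are all in
#' `{0, 1}` are auto-flagged binary (unless overridden) and their case-control
#' ratio (#cases / #controls) is recorded.
#'
#' @param values numeric matrix (n samples x K traits).
#' @param sample_ids,trait_ids identifiers for rows and columns.
#' @param trait_kind optional character vector, entries in
#'   `c("quantitative", "binary")`, recycled/na-filled; `NA` means auto-detect.
#' @return Object of class `phenotype_dataset` with `values`, `sample_ids`,
#'   `trait_ids`, `trait_kind`, `case_control_ratio` (NA for quantitative).
#' @export
phenotype_dataset <- function(values, sample_ids = rownames(values),
                              trait_ids = colnames(values), trait_kind = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(ncol(values)))
  if (ncol(values) < 1L) stop("need at least one trait")
  storage.mode(values) <- "double"
  K <- ncol(values)
  auto <- vapply(seq_len(K), function(k) {
    v <- values[, k]
    v <- v[!is.na(v)]
    if (!length(v)) stop(sprintf("trait '%s' is all-missing", trait_ids[k]))
    all(v %in% c(0, 1))
  }, logical(1))
  kind <- ifelse(auto, "binary", "quantitative")
  if (!is.null(trait_kind)) {
    trait_kind <- rep_len(as.character(trait_kind), K)
    override <- !is.na(trait_kind)
    if (!all(trait_kind[override] %in% c("quantitative", "binary")))
      stop("trait_kind entries must be 'quantitative' or 'binary'")
    kind[override] <- trait_kind[override]
  }
  ccr <- rep(NA_real_, K)
  for (k in which(kind == "binary")) {
    v <- values[, k]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop(sprintf("trait '%s' flagged binary but has values outside {0,1}",
                   trait_ids[k]))
    n1 <- sum(v == 1, na.rm = TRUE)
    n0 <- sum(v == 0, na.rm = TRUE)
    ccr[k] <- n1 / n0
  }
  dimnames(values) <- list(sample_ids, trait_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 trait_ids = trait_ids, trait_kind = kind,
                 case_control_ratio = ccr),
            class = "phenotype_dataset")
}

#' @export
print.phenotype_dataset <- function(x, ...) {
  nb <- sum(x$trait_kind == "binary")
  cat(sprintf("phenotype_dataset: %d samples x %d traits (%d binary, %d quantitative)\n",
              nrow(x$values), length(x$trait_ids), nb, length(x$trait_ids) - nb))
  invisible(x)
}

#' Construct a covariate dataset
#'
#' @param values numeric matrix (n samples x p covariates); do not include an
#'   intercept column, one is always added during residualization.
#' @param sample_ids,covariate_ids identifiers.
#' @return Object of class `covariate_dataset`.
#' @export
covariate_dataset <- function(values, sample_ids = rownames(values),
                              covariate_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(covariate_ids)) covariate_ids <- paste0("cov", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  is_const <- apply(values, 2, function(v) all(v == v[1]))
  if (any(is_const))
    stop(sprintf("constant covariate column(s) duplicate the intercept: %s",
                 paste(covariate_ids[is_const], collapse = ", ")))
  dimnames(values) <- list(sample_ids, covariate_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 covariate_ids = covariate_ids),
            class = "covariate_dataset")
}

#' Align genotype, phenotype and covariate datasets on shared samples
#'
#' Samples are matched by identifier intersection and kept in genotype-file
#' order; samples absent from any supplied dataset are dropped with a message
#' stating the count.
#'
#' @param geno a [genotype_dataset()].
#' @param pheno a [phenotype_dataset()].
#' @param covar a [covariate_dataset()] or `NULL`.
#' @return list with the three datasets subset to the common samples.
#' @export
align_samples <- function(geno, pheno, covar = NULL) {
  ids <- geno$sample_ids
  ids <- ids[ids %in% pheno$sample_ids]
  if (!is.null(covar)) ids <- ids[ids %in% covar$sample_ids]
  dropped <- length(geno$sample_ids) - length(ids)
  if (dropped > 0)
    message(sprintf("align_samples: dropped %d sample(s) without a match in all datasets",
                    dropped))
  if (length(ids) < 2L) stop("fewer than 2 samples shared across datasets")
  g <- genotype_dataset(geno$counts[ids, , drop = FALSE], sample_ids = ids,
                        snp_ids = geno$snp_ids, orient = FALSE)
  p <- phenotype_dataset(pheno$values[match(ids, pheno$sample_ids), , drop = FALSE],
                         sample_ids = ids, trait_ids = pheno$trait_ids,
                         trait_kind = pheno$trait_kind)
  cv <- NULL
  if (!is.null(covar))
    cv <- covariate_dataset(covar$values[match(ids, covar$sample_ids), , drop = FALSE],
                            sample_ids = ids, covariate_ids = covar$covariate_ids)
  list(geno = g, pheno = p, covar = cv)
}

#' Mean-impute missing genotype counts per SNP
#'
#' Missing entries of each SNP column are replaced by the column mean of the
#' observed counts. Applied immediately before analysis; raw datasets keep
#' their missing values.
#'
#' @param geno a [genotype_dataset()].
#' @return a `genotype_dataset` without missing values (counts may be
#'   fractional after imputation).
#' @export
impute_genotypes <- function(geno) {
  counts <- geno$counts
  if (anyNA(counts)) {
    mu <- colMeans(counts, na.rm = TRUE)
    idx <- which(is.na(counts), arr.ind = TRUE)
    counts[idx] <- mu[idx[, 2]]
  }
  out <- geno
  out$counts <- counts
  out
}
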