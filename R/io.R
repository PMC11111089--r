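# File formats: PLINK .raw (additive recoding), tab-separated matrices with
# '.' decimal and 'NA' missing, summary-statistics TSV, edge-list / GraphML /
# dense-matrix network exports.

.PLINK_META <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read a genotype matrix
#'
#' Supports the PLINK `.raw` additive export (header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP coded as
#' allele counts) and a plain TSV dialect (first column `sample_id`, one
#' column per SNP). Counts are minor-allele oriented on read.
#'
#' @param path file path.
#' @param dialect `"plink_raw"` or `"tsv"`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("plink_raw", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (dialect == "plink_raw") {
    dt <- data.table::fread(path, header = TRUE, na.strings = "NA",
                            data.table = FALSE)
    if (ncol(dt) < 7L || !identical(colnames(dt)[1:6], .PLINK_META))
      stop("malformed .raw header: expected FID IID PAT MAT SEX PHENOTYPE then SNP columns")
    sample_ids <- as.character(dt[["IID"]])
    counts <- as.matrix(dt[, -(1:6), drop = FALSE])
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                            data.table = FALSE)
    if (ncol(dt) < 2L) stop("malformed genotype TSV: need sample_id plus SNP columns")
    sample_ids <- as.character(dt[[1]])
    counts <- as.matrix(dt[, -1, drop = FALSE])
  }
  if (!is.numeric(counts)) {
    suppressWarnings(storage.mode(counts) <- "double")
  }
  genotype_dataset(counts, sample_ids = sample_ids, snp_ids = colnames(counts))
}

#' Write a genotype dataset as TSV
#'
#' @param geno a [genotype_dataset()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(sample_id = geno$sample_ids, geno$counts,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with a `sample_id` column followed by one numeric column per trait.
#' Traits with all values in `{0,1}` are flagged binary unless overridden.
#'
#' @param path file path.
#' @param trait_kinds optional named character vector of per-trait overrides
#'   (`"quantitative"` or `"binary"`).
#' @return a [phenotype_dataset()].
#' @export
read_phenotypes <- function(path, trait_kinds = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE)
  if (ncol(dt) < 2L) stop("malformed phenotype TSV: need sample_id plus trait columns")
  sample_ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stop(sprintf("non-numeric phenotype column(s): %s",
                 paste(colnames(vals)[nonnum], collapse = ", ")))
  values <- as.matrix(vals)
  kind <- NULL
  if (!is.null(trait_kinds)) {
    kind <- rep(NA_character_, ncol(values))
    names(kind) <- colnames(values)
    hit <- intersect(names(trait_kinds), colnames(values))
    kind[hit] <- trait_kinds[hit]
  }
  phenotype_dataset(values, sample_ids = sample_ids,
                    trait_ids = colnames(values), trait_kind = kind)
}

#' Write a phenotype dataset as TSV
#' @param pheno a [phenotype_dataset()].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- data.frame(sample_id = pheno$sample_ids, pheno$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a covariate table
#' @param path TSV with `sample_id` column then numeric covariates.
#' @return a [covariate_dataset()].
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE)
  covariate_dataset(as.matrix(dt[, -1, drop = FALSE]),
                    sample_ids = as.character(dt[[1]]),
                    covariate_ids = colnames(dt)[-1])
}

#' Read a per-(trait, SNP) summary-statistics table
#'
#' TSV with columns `trait_id`, `snp_id`, `direction` (sign of the effect,
#' -1 or +1) and `p_value` in (0, 1].
#'
#' @param path file path.
#' @return data.frame with the four validated columns.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("trait_id", "snp_id", "direction", "p_value")
  if (!all(need %in% colnames(dt)))
    stop(sprintf("summary-stats TSV must have columns: %s",
                 paste(need, collapse = ", ")))
  dt <- dt[, need]
  if (!all(dt$direction %in% c(-1, 1)))
    stop("direction must be -1 or +1")
  if (any(dt$p_value <= 0 | dt$p_value > 1))
    stop("p_value must lie in (0, 1]")
  if (anyDuplicated(dt[, c("trait_id", "snp_id")]))
    stop("duplicate (trait_id, snp_id) rows in summary statistics")
  dt
}

#' Write a network matrix
#'
#' Writes the bipartite phenotype-SNP matrix `T` or the phenotype-phenotype
#' matrix `W` in one of three formats:
#' \describe{
#'   \item{`edge_tsv`}{columns `source_id`, `target_id`, `weight`. For a
#'     square symmetric matrix only the upper off-diagonal triangle is
#'     emitted (undirected edges, self-edges suppressed); for a rectangular
#'     matrix one row per (phenotype, SNP) pair. Zero weights are kept.}
#'   \item{`matrix_tsv`}{dense labeled matrix, values rendered at 17
#'     significant digits so a read-back is bit-identical.}
#'   \item{`graphml`}{GraphML via igraph; bipartite matrices carry a node
#'     attribute `layer` in `{phenotype, snp}`.}
#' }
#'
#' @param x matrix with dimnames, or an object with `$T` or `$W` field
#'   (association-strength or genetic-correlation result).
#' @param path output path.
#' @param format one of `"edge_tsv"`, `"graphml"`, `"matrix_tsv"`.
#' @export
write_network <- function(x, path, format = c("edge_tsv", "graphml", "matrix_tsv")) {
  format <- match.arg(format)
  m <- .as_network_matrix(x)
  if (!all(is.finite(m))) stop("network matrix has non-finite entries")
  square <- nrow(m) == ncol(m) && identical(rownames(m), colnames(m))
  if (format == "matrix_tsv") {
    body <- apply(m, 1:2, function(v) sprintf("%.17g", v))
    df <- data.frame(id = rownames(m), body, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  } else if (format == "edge_tsv") {
    if (square) {
      idx <- which(upper.tri(m), arr.ind = TRUE)
    } else {
      idx <- as.matrix(expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m))))
    }
    df <- data.frame(source_id = rownames(m)[idx[, 1]],
                     target_id = colnames(m)[idx[, 2]],
                     weight = m[idx])
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  } else {
    if (square) {
      g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
    } else {
      inc <- m
      g <- igraph::graph_from_biadjacency_matrix(inc, weighted = TRUE)
      igraph::V(g)$layer <- ifelse(igraph::V(g)$type, "snp", "phenotype")
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.as_network_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.null(x$T)) {
    m <- x$T
    dimnames(m) <- list(x$trait_ids, x$snp_ids)
    return(m)
  }
  if (!is.null(x$W)) {
    m <- x$W
    dimnames(m) <- list(x$trait_ids, x$trait_ids)
    return(m)
  }
  stop("cannot interpret object as a network matrix")
}

#' Read a dense labeled matrix TSV written by [write_network()]
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write module assignments as TSV (columns `trait_id`, `module`)
#' @param partition a module partition (see [detect_modules()]).
#' @param path output path.
#' @export
write_modules <- function(partition, path) {
  df <- data.frame(trait_id = partition$trait_ids, module = partition$labels)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
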