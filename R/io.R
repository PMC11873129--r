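# Readers and writers for the pipeline's external-interface formats.
# All files are plain text: TSV matrices/tables, whitespace-delimited
# summary statistics, MatrixMarket triplets for expression counts.

#' Read a beta matrix TSV (probes as rows, header = sample ids)
#'
#' @param path file path. First column must be the probe id.
#' @param impute_missing if `TRUE`, missing values are replaced by the
#'   per-probe median; the default is to reject files with missing values.
#' @return numeric matrix probes x samples.
#' @export
read_beta_matrix <- function(path, impute_missing = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stop_if_not(!anyDuplicated(rownames(m)), "duplicate probe ids in %s", path)
  if (anyNA(m)) {
    if (!impute_missing)
      stop("missing beta values in ", path,
           " (use impute_missing = TRUE for per-probe median imputation)")
    for (i in which(rowSums(is.na(m)) > 0))
      m[i, is.na(m[i, ])] <- stats::median(m[i, ], na.rm = TRUE)
  }
  m
}

#' Write a probes-x-samples matrix as TSV
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read whitespace-delimited GWAS summary statistics
#'
#' Expects the header `SNP CHR BP A1 A2 BETA SE P INFO`.
#' @param path file path.
#' @return data.frame of summary statistics.
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "INFO")
  miss <- setdiff(need, names(ss))
  stop_if_not(length(miss) == 0, "sumstats missing columns: %s",
              paste(miss, collapse = ", "))
  ss$CHR <- as.character(ss$CHR)
  ss
}

#' Read a dosage TSV (samples as rows, header = variant ids)
#' @param path file path; first column is the sample id.
#' @return numeric matrix samples x variants.
#' @export
read_dosages <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read an expression MatrixMarket triplet with gene / cell sidecar TSVs
#' @param mtx path to the `.mtx` file.
#' @param genes_tsv one gene symbol per line (no header).
#' @param cells_tsv TSV with columns cell, class, subtype.
#' @return list with `expr` (dense genes x cells matrix) and `cells`.
#' @export
read_expression_mtx <- function(mtx, genes_tsv, cells_tsv) {
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- readLines(genes_tsv)
  cells <- utils::read.delim(cells_tsv, stringsAsFactors = FALSE)
  dimnames(m) <- list(genes, cells$cell)
  list(expr = m, cells = cells)
}
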