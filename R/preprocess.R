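#' Quantile-normalize sample columns
#'
#' Forces every sample column of a log-expression matrix onto the common
#' reference distribution given by the row-wise mean of the sorted columns.
#' Ties within a column receive the mean of the reference values at their
#' rank positions (average-rank dialect), so the operation is deterministic
#' and idempotent.
#'
#' @param x numeric matrix, genes in rows, samples in columns. All values
#'   must be finite.
#' @return matrix of the same shape and dimnames with quantile-equal columns.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("quantile normalization needs at least 2 genes and 2 samples")
  if (!all(is.finite(x)))
    stop("non-finite values in expression matrix; check data quality upstream")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Log-transform and replicate-average expression values
#'
#' Converts positive linear-scale expression `E[g, sample]` to log10 and
#' averages over the replicates of each condition. The replicate-level
#' standard deviation of the logged values (population form, divide by R)
#' is retained per gene and condition: it feeds the locally pooled error
#' curve used by the shrinkage-t score. Conditions measured with a single
#' replicate get `NA` standard deviations (the error model must then rely
#' on the pooled curve alone).
#'
#' @param raw numeric matrix, genes x sample-columns; strictly positive when
#'   `scale = "linear"`.
#' @param conditions character/factor of length `ncol(raw)` mapping each
#'   sample column to its condition.
#' @param scale `"linear"` (default; log10 is applied) or `"log10"` (values
#'   are already logged and used as-is).
#' @return list with `e` (genes x conditions log10 means), `sigma` (same
#'   shape, replicate SDs, `NA` where R = 1), `R` (replicate count per
#'   condition), `conditions` (condition levels, column order of `e`).
#' @export
log_and_average <- function(raw, conditions, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  raw <- as.matrix(raw)
  if (length(conditions) != ncol(raw))
    stop("`conditions` must have one entry per sample column")
  if (is.null(rownames(raw)))
    rownames(raw) <- paste0("g", seq_len(nrow(raw)))
  if (anyDuplicated(rownames(raw)))
    stop("gene ids must be unique")
  if (scale == "linear") {
    bad <- which(!(is.finite(raw) & raw > 0), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf(
        "non-positive expression value for gene '%s' in sample column '%s'",
        rownames(raw)[bad[1L, 1L]],
        colnames(raw)[bad[1L, 2L]] %||% as.character(bad[1L, 2L])))
    }
    lg <- log10(raw)
  } else {
    if (!all(is.finite(raw)))
      stop("non-finite log10 expression values")
    lg <- raw
  }
  conditions <- as.character(conditions)
  lev <- unique(conditions)
  e <- matrix(NA_real_, nrow(lg), length(lev),
              dimnames = list(rownames(lg), lev))
  sigma <- e
  R <- integer(length(lev))
  names(R) <- lev
  for (j in seq_along(lev)) {
    cols <- which(conditions == lev[j])
    R[j] <- length(cols)
    sub <- lg[, cols, drop = FALSE]
    e[, j] <- rowMeans(sub)
    if (R[j] >= 2L) {
      # population SD: sqrt(<(e_r - <e>)^2>_r), divide by R not R-1
      sigma[, j] <- sqrt(rowMeans((sub - e[, j])^2))
    }
  }
  list(e = e, sigma = sigma, R = R, conditions = lev)
}

#' Center each gene at its cross-sample mean
#'
#' Turns log10 expression into differential expression
#' `delta_e[g, m] = e[g, m] - mean_m(e[g, m])`, the quantity the SOM
#' trains on. Row means of the result are zero by construction.
#'
#' @param e numeric genes x samples matrix of log10 expression.
#' @return matrix of the same shape with zero row means.
#' @export
center_genes <- function(e) {
  e <- as.matrix(e)
  if (ncol(e) < 2L)
    stop("centering needs at least 2 samples")
  e - rowMeans(e)
}

#' Read a genes x samples expression matrix from TSV/CSV
#'
#' First column holds gene ids, header row holds sample ids. The delimiter
#' is inferred from the file extension (`.csv` -> comma, otherwise tab).
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read a two-column sample-to-condition annotation TSV
#'
#' @param path file with columns `sample` and `condition` (header required).
#' @return named character vector: condition keyed by sample id.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("annotation needs two columns: sample, condition")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a numeric matrix as TSV with a leading id column
#'
#' @param x matrix with rownames.
#' @param path output path.
#' @param id_name header of the id column.
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full preprocessing: normalize, log-average, center
#'
#' Runs the standard chain raw expression -> quantile normalization ->
#' log10 replicate averaging -> gene centering. Normalization is applied to
#' the logged sample columns before replicate averaging by default; set
#' `normalize = "after"` to normalize the replicate-averaged condition
#' columns instead, or `"none"` to skip.
#'
#' @param raw genes x sample-columns matrix.
#' @param conditions sample -> condition assignment (length `ncol(raw)`).
#' @param scale `"linear"` or `"log10"` input scale.
#' @param normalize `"before"`, `"after"` or `"none"`.
#' @return list with `delta` (centered matrix), plus the `e`, `sigma`, `R`
#'   components of [log_and_average()].
#' @export
preprocess_expression <- function(raw, conditions,
                                  scale = c("linear", "log10"),
                                  normalize = c("before", "after", "none")) {
  scale <- match.arg(scale)
  normalize <- match.arg(normalize)
  raw <- as.matrix(raw)
  if (normalize == "before") {
    lg <- if (scale == "linear") {
      if (any(raw <= 0)) stop("non-positive expression values")
      log10(raw)
    } else raw
    lg <- quantile_normalize(lg)
    la <- log_and_average(lg, conditions, scale = "log10")
  } else {
    la <- log_and_average(raw, conditions, scale = scale)
    if (normalize == "after")
      la$e <- quantile_normalize(la$e)
  }
  c(list(delta = center_genes(la$e)), la)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
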