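#' Quantile-normalize an FPKM matrix across samples
#'
#' Forces every sample (column) to share one reference distribution while
#' preserving within-sample ranks. The reference distribution is the mean
#' across samples of the k-th order statistics. Tied values within a sample
#' all receive the mean of the reference values spanned by their rank range,
#' so the transform is deterministic.
#'
#' @param matrix Gene-by-sample numeric matrix (validated with
#'   [validate_expression()]); at least 2 genes and 2 samples.
#' @return A list with elements:
#'   \describe{
#'     \item{matrix}{the normalized matrix, same dimnames;}
#'     \item{report}{a list with `reference_distribution` (non-decreasing,
#'       length = gene count), `per_sample_rank_method` ("average"), and
#'       `tie_policy` ("mean-of-reference-over-rank-range").}
#'   }
#' @export
quantile_normalize <- function(matrix) {
  validate_expression(matrix)
  if (ncol(matrix) < 2L) stop("quantile normalization needs at least 2 samples")
  if (nrow(matrix) < 2L) stop("quantile normalization needs at least 2 genes")
  n <- nrow(matrix)
  sorted <- apply(matrix, 2L, sort, method = "radix")
  reference <- unname(rowMeans(sorted))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    col <- matrix[, j]
    ord <- order(col)
    # rank range occupied by each tie group -> mean of reference over it
    assigned <- numeric(n)
    sorted_col <- col[ord]
    grp <- cumsum(c(TRUE, sorted_col[-1L] != sorted_col[-n]))
    ref_means <- vapply(split(reference, grp), mean, 0)
    assigned[ord] <- ref_means[grp]
    out[, j] <- assigned
  }
  report <- list(reference_distribution = reference,
                 per_sample_rank_method = "average",
                 tie_policy = "mean-of-reference-over-rank-range")
  list(matrix = out, report = report)
}

#' Write a normalization report as TSV
#' @param report Report list from [quantile_normalize()].
#' @param path Output path.
#' @export
write_normalization_report <- function(report, path) {
  df <- data.frame(rank = seq_along(report$reference_distribution),
                   reference_value = report$reference_distribution)
  attrline <- sprintf("# rank_method=%s tie_policy=%s",
                      report$per_sample_rank_method, report$tie_policy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attrline, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2 transform with pseudocount
#'
#' value <- log2(value + pseudocount); monotone in the input. Used before PCA
#' and wherever symmetric fold changes are needed.
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param pseudocount Strictly positive offset (default 1).
#' @return Transformed matrix with the same dimnames.
#' @export
log_transform <- function(matrix, pseudocount = 1.0) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  validate_expression(matrix)
  log2(matrix + pseudocount)
}

#' Invert [log_transform()]
#' @param matrix log2-scale matrix.
#' @param pseudocount The pseudocount used in the forward transform.
#' @return FPKM-scale matrix.
#' @export
unlog_transform <- function(matrix, pseudocount = 1.0) {
  if (pseudocount <= 0) stop("pseudocount must be a single positive number")
  2^matrix - pseudocount
}
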