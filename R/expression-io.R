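#' Read a gene-by-sample FPKM expression matrix from TSV
#'
#' The expected layout is the plain interchange format used throughout the
#' package: a UTF-8, tab-separated file whose first row holds sample
#' identifiers, whose first column holds gene identifiers, and whose body is
#' numeric FPKM (non-negative, no missing values, "." decimal separator).
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix (genes x samples) with unique rownames (gene ids)
#'   and colnames (sample ids), all values finite and non-negative. Row and
#'   column order follow the file.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression file needs a gene-id column plus >=1 sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite value at gene '%s' (row %d), sample '%s' (column %d)",
                 gene_ids[bad[1, 1]], bad[1, 1], sample_ids[bad[1, 2]], bad[1, 2]))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at gene '%s' (row %d), sample '%s' (column %d)",
                 gene_ids[neg[1, 1]], neg[1, 1], sample_ids[neg[1, 2]], neg[1, 2]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  validate_expression(values)
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; full-precision round trip.
#'
#' @param matrix Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @param gene_column Header for the gene-id column.
#' @export
write_expression_tsv <- function(matrix, path, gene_column = "gene_id") {
  validate_expression(matrix)
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_column
  write_tsv_precise(df, path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Enforces the container invariants: numeric matrix, dimnames present and
#' unique, all values finite and non-negative.
#'
#' @param matrix Object to validate.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]), collapse = ", "))
  if (any(!is.finite(matrix))) stop("expression matrix contains non-finite values")
  if (any(matrix < 0)) stop("expression matrix contains negative values")
  invisible(matrix)
}

#' Read a sample design table from TSV
#'
#' Two or three tab-separated columns: `sample_id`, `cohort` and optionally
#' `hiv`. Cohort labels are matched case-insensitively against
#' stunting / SAM / adult and stored in canonical case.
#'
#' @param path Path to the design file.
#' @return A data.frame with columns `sample_id`, `cohort` (factor with levels
#'   stunting, SAM, adult) and `hiv` (pos / neg / unknown).
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L) stop("design file is empty")
  if (!all(c("sample_id", "cohort") %in% colnames(df)))
    stop("design file must have columns sample_id and cohort")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("sample listed twice in design: ", paste(unique(dup), collapse = ", "))
  cohort <- normalize_cohort(df$cohort)
  hiv <- if ("hiv" %in% colnames(df)) {
    h <- tolower(df$hiv)
    bad <- setdiff(unique(h), c("pos", "neg", "unknown", "", NA))
    if (length(bad)) stop("unrecognized hiv status: ", paste(bad, collapse = ", "))
    h[h == "" | is.na(h)] <- "unknown"
    h
  } else rep("unknown", nrow(df))
  data.frame(sample_id = df$sample_id,
             cohort = factor(cohort, levels = cohort_levels()),
             hiv = hiv, stringsAsFactors = FALSE)
}

#' Write a design table as TSV
#' @param design Design data.frame as from [read_design_tsv()].
#' @param path Output path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cohort_levels <- function() c("stunting", "SAM", "adult")

normalize_cohort <- function(x) {
  lv <- cohort_levels()
  idx <- match(tolower(x), tolower(lv))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unrecognized cohort label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(lv, collapse = ", "), ")")
  }
  lv[idx]
}

#' Check a design against an expression matrix
#'
#' Every sample column of the matrix must be assigned to exactly one cohort,
#' and each cohort used must contain at least `min_per_cohort` samples.
#'
#' @param matrix Expression matrix.
#' @param design Design data.frame.
#' @param min_per_cohort Minimum samples per represented cohort (default 2).
#' @return The design rows matching the matrix columns, in matrix column
#'   order, invisibly returned as a data.frame.
#' @export
match_design <- function(matrix, design, min_per_cohort = 2L) {
  validate_expression(matrix)
  missing <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing))
    stop("sample(s) in matrix absent from design: ", paste(missing, collapse = ", "))
  d <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  counts <- table(droplevels(d$cohort))
  small <- names(counts)[counts < min_per_cohort]
  if (length(small))
    stop("cohort(s) with fewer than ", min_per_cohort, " samples: ",
         paste(small, collapse = ", "))
  rownames(d) <- NULL
  d
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a set are dropped; duplicate set names are an
#' error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (the sets), with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  names_ <- vapply(fields, `[[`, "", 1L)
  dup <- names_[duplicated(names_)]
  if (length(dup)) stop("duplicate set name(s): ", paste(unique(dup), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  descriptions <- vapply(fields, `[[`, "", 2L)
  names(descriptions) <- names_
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets Named list of character vectors, optionally with a
#'   `descriptions` attribute.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Generic writer for the package's result data.frames (ratio records, strict
#' test records, enrichment results, PCA scores...). Numeric columns are
#' written with enough significant digits (15) for a lossless practical
#' round trip; column order is the data.frame's documented order.
#'
#' @param records A data.frame (possibly zero rows: header-only output).
#' @param path Output path.
#' @export
write_result_table <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  write_tsv_precise(records, path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path Path to the TSV file.
#' @return A data.frame with types inferred per column.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE)
}

# shared precise TSV writer: numbers at 15 significant digits, no quoting
write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  invisible(ok)
}
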