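#' Per-cohort mean FPKM for every gene
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param design Design data.frame (`sample_id`, `cohort`); every matrix
#'   column must be assigned and every represented cohort must have at least
#'   2 samples.
#' @return A data.frame with one row per gene: `gene_id`, one `mean_<cohort>`
#'   column per represented cohort, and one `n_<cohort>` column with sample
#'   counts.
#' @export
group_means <- function(matrix, design) {
  d <- match_design(matrix, design)
  cohorts <- levels(droplevels(d$cohort))
  out <- data.frame(gene_id = rownames(matrix), stringsAsFactors = FALSE)
  for (co in cohorts) {
    cols <- d$cohort == co
    out[[paste0("mean_", co)]] <- rowMeans(matrix[, cols, drop = FALSE])
    out[[paste0("n_", co)]] <- sum(cols)
  }
  out
}

#' Pairwise expression ratio records
#'
#' For each gene, forms the ratio of cohort mean FPKM between a numerator
#' and denominator cohort, with a small pseudocount so genes expressed in
#' only one cohort remain rankable. Genes with both means exactly 0 are
#' flagged `excluded_zero` and never enter tail ranking.
#'
#' @param summaries Group-mean data.frame from [group_means()] (or the
#'   packaged [table2_fixture()]).
#' @param numerator,denominator Cohort names (must differ and be present as
#'   `mean_<cohort>` columns).
#' @param pseudocount Strictly positive ratio offset (default 0.01).
#' @return A data.frame of ratio records: `gene_id`, `numerator_cohort`,
#'   `denominator_cohort`, `num_mean`, `den_mean`, `ratio`, `log2_ratio`,
#'   `tail` ("upper"/"lower"/"none"), `trimmed_out`, `excluded_zero`.
#'   `tail` is "none" until [tail_select()] runs; `trimmed_out` is FALSE
#'   until [trim_deg()] runs.
#' @export
compute_ratio_records <- function(summaries, numerator, denominator,
                                  pseudocount = 0.01) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (identical(numerator, denominator))
    stop("numerator and denominator cohorts must differ")
  num_col <- paste0("mean_", numerator)
  den_col <- paste0("mean_", denominator)
  for (col in c(num_col, den_col)) {
    if (!col %in% colnames(summaries))
      stop("summaries lack column ", col)
  }
  num_mean <- summaries[[num_col]]
  den_mean <- summaries[[den_col]]
  ratio <- (num_mean + pseudocount) / (den_mean + pseudocount)
  data.frame(gene_id = summaries$gene_id,
             numerator_cohort = numerator,
             denominator_cohort = denominator,
             num_mean = num_mean,
             den_mean = den_mean,
             ratio = ratio,
             log2_ratio = log2(ratio),
             tail = "none",
             trimmed_out = FALSE,
             excluded_zero = num_mean == 0 & den_mean == 0,
             stringsAsFactors = FALSE)
}

#' Flag the empirical 95%-confidence-limit tails of the ratio distribution
#'
#' Operationalizes "outside the 95% confidence limits of the ratio" as rank
#' selection on the log2 ratio: with n non-excluded genes and
#' k = floor(n * alpha / 2), the k largest log2 ratios are flagged "upper"
#' and the k smallest "lower". Ties are broken by ascending gene id so the
#' selection is deterministic.
#'
#' @param records Ratio-record data.frame from [compute_ratio_records()].
#' @param alpha Two-sided tail mass (default 0.05, i.e. 2.5% per tail).
#' @return The records with the `tail` column filled in.
#' @export
tail_select <- function(records, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  eligible <- which(!records$excluded_zero)
  n <- length(eligible)
  if (n < 2L) stop("need at least 2 non-excluded records")
  k <- floor(n * alpha / 2)
  records$tail <- "none"
  if (k == 0L) {
    warning("alpha too small for n: no genes selected in either tail")
    return(records)
  }
  lr <- records$log2_ratio[eligible]
  gid <- records$gene_id[eligible]
  ord_up <- eligible[order(-lr, gid)]
  ord_lo <- eligible[order(lr, gid)]
  records$tail[ord_up[seq_len(k)]] <- "upper"
  records$tail[ord_lo[seq_len(k)]] <- "lower"
  records
}

#' Trim ratio records by minimum group-mean FPKM
#'
#' The post-selection trimming step: a gene is kept when its group means
#' clear `threshold` under the chosen rule. `mode = "any"` keeps a gene when
#' either mean is at or above the threshold (the convention behind the
#' trimmed supplementary gene lists); `mode = "both"` requires both (the
#' convention behind the scatter/dot-plot displays). Tail flags are not
#' altered; only `trimmed_out` is set.
#'
#' @param records Ratio-record data.frame.
#' @param threshold Positive FPKM threshold (default 1).
#' @param mode "any" or "both".
#' @return The records with `trimmed_out` set (TRUE = fails the rule).
#' @export
trim_deg <- function(records, threshold = 1.0, mode = c("any", "both")) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  mode <- match.arg(mode)
  keep <- if (mode == "any") {
    pmax(records$num_mean, records$den_mean) >= threshold
  } else {
    pmin(records$num_mean, records$den_mean) >= threshold
  }
  records$trimmed_out <- !keep
  records
}

#' Summarize a selected tail as a DEG list
#'
#' @param records Ratio records after [tail_select()] and [trim_deg()].
#' @param direction "up" (upper tail) or "down" (lower tail).
#' @return A list: `comparison` label, `direction`, `records` (the selected
#'   rows), `n_selected`, `n_after_trim`.
#' @export
deg_list <- function(records, direction = c("up", "down")) {
  direction <- match.arg(direction)
  tail_name <- if (direction == "up") "upper" else "lower"
  sel <- records[records$tail == tail_name, , drop = FALSE]
  list(comparison = paste0(records$numerator_cohort[1L], "_vs_",
                           records$denominator_cohort[1L]),
       direction = direction,
       records = sel,
       n_selected = nrow(sel),
       n_after_trim = sum(!sel$trimmed_out))
}

#' Two-sided Mann-Whitney U test
#'
#' Classical min-convention U with a two-sided p-value: exact when both
#' groups have at most 8 observations and the pooled data are tie-free,
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric vectors, each with at least 2 observations.
#' @return A list with `u_statistic` (min of the two U's) and `raw_p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u <- min(u_x, m * n - u_x)
  tie_free <- !any(duplicated(c(x, y)))
  use_exact <- m <= 8L && n <= 8L && tie_free
  p <- stats::wilcox.test(x, y, alternative = "two.sided",
                          exact = use_exact, correct = TRUE)$p.value
  list(u_statistic = u, raw_p = p)
}

#' Strict fold-change + Mann-Whitney differential-expression filter
#'
#' The deliberately stringent second selection procedure: a gene passes when
#' its absolute fold change between cohort means exceeds `fc_threshold`
#' (2.5 by default) and its two-sided Mann-Whitney p-value is below
#' `p_threshold` (1e-6 by default). A Bonferroni-adjusted p
#' (min(1, p * n_genes)) is reported alongside so either threshold
#' convention can be audited.
#'
#' @param matrix Gene-by-sample numeric matrix (normalized FPKM).
#' @param design Design data.frame.
#' @param group_a,group_b Cohort names; fold change is mean(a)/mean(b) with
#'   pseudocount 0.01.
#' @param fc_threshold Fold-change threshold, must exceed 1 (default 2.5).
#' @param p_threshold Raw p-value threshold (default 1e-6).
#' @param pseudocount Ratio pseudocount (default 0.01).
#' @return A data.frame with one row per gene: `gene_id`, `fold_change`,
#'   `log2_fold_change`, `u_statistic`, `raw_p`, `adjusted_p`, `passes`.
#' @export
strict_filter <- function(matrix, design, group_a, group_b,
                          fc_threshold = 2.5, p_threshold = 1e-6,
                          pseudocount = 0.01) {
  if (fc_threshold <= 1) stop("fc_threshold must be greater than 1")
  d <- match_design(matrix, design)
  ia <- which(d$cohort == group_a)
  ib <- which(d$cohort == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both cohorts need at least 2 samples")
  mean_a <- rowMeans(matrix[, ia, drop = FALSE])
  mean_b <- rowMeans(matrix[, ib, drop = FALSE])
  fc <- (mean_a + pseudocount) / (mean_b + pseudocount)
  m <- nrow(matrix)
  u <- numeric(m); p <- numeric(m)
  for (g in seq_len(m)) {
    res <- mann_whitney_u(matrix[g, ia], matrix[g, ib])
    u[g] <- res$u_statistic
    p[g] <- res$raw_p
  }
  adj <- pmin(1, p * m)
  data.frame(gene_id = rownames(matrix),
             fold_change = fc,
             log2_fold_change = log2(fc),
             u_statistic = u,
             raw_p = p,
             adjusted_p = adj,
             passes = abs(log2(fc)) > log2(fc_threshold) & p < p_threshold,
             stringsAsFactors = FALSE)
}
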