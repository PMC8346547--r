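# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (enumeration / full sort) and independent of
# the implementation paths they check.

make_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

make_design <- function(cohorts, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%02d", seq_along(cohorts))
  data.frame(sample_id = samples,
             cohort = factor(cohorts, levels = c("stunting", "SAM", "adult")),
             hiv = "unknown", stringsAsFactors = FALSE)
}

random_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  make_matrix(matrix(round(stats::rexp(n_genes * n_samples, rate = 0.1), 4),
                     nrow = n_genes))
}

# --- Mann-Whitney oracle: full enumeration of rank assignments -------------
# For tie-free pooled data, enumerates every C(m+n, m) way the x-ranks could
# fall and returns the two-sided p as the probability of a U at least as far
# from mn/2 as observed.
mw_enumeration_oracle <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(N, m)
  all_ranks <- seq_len(N)
  u_all <- apply(combos, 2L, function(ix) sum(all_ranks[ix]) - m * (m + 1) / 2)
  center <- m * n / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Independent large-sample Mann-Whitney p: hand-coded normal approximation
# with tie and continuity corrections (textbook formulas, no stats::wilcox.test).
mw_normal_oracle <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
  z <- u - m * n / 2
  z <- (z - sign(z) * 0.5) / sigma
  2 * stats::pnorm(-abs(z))
}

# --- hypergeometric oracle: exhaustive urn enumeration ---------------------
# Draws every C(N, n_query) query from the universe and counts how often the
# overlap with the set reaches k.
hyper_enumeration_oracle <- function(k, set_size, universe_size, query_size) {
  universe <- seq_len(universe_size)
  in_set <- universe <= set_size
  combos <- utils::combn(universe_size, query_size)
  hits <- apply(combos, 2L, function(ix) sum(in_set[ix]))
  mean(hits >= k)
}

# --- quantile normalization oracle: sort, average, reassign (tie-free) -----
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# --- tail selection oracle: full sort ---------------------------------------
tail_oracle <- function(log2_ratio, gene_id, excluded, alpha = 0.05) {
  ok <- !excluded
  n <- sum(ok)
  k <- floor(n * alpha / 2)
  ord <- order(log2_ratio, gene_id)   # ascending, gene id tiebreak
  ord <- ord[ok[ord]]
  lower <- gene_id[ord[seq_len(k)]]
  ord_desc <- order(-log2_ratio, gene_id)
  ord_desc <- ord_desc[ok[ord_desc]]
  upper <- gene_id[ord_desc[seq_len(k)]]
  list(upper = sort(upper), lower = sort(lower))
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
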