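#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more than
#' expected when drawing |query| genes at random from the universe (upper-tail
#' hypergeometric test). Sets are intersected with the universe first; sets
#' overlapping the query by fewer than `min_overlap` genes are omitted.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe Character vector of all candidate genes (no duplicates).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param min_overlap Minimum query/set overlap to report (default 2).
#' @return A data.frame sorted by p-value: `set_name`, `overlap_count`,
#'   `set_size_in_universe`, `query_size`, `universe_size`, `p_value`
#'   (upper-tail hypergeometric), `q_value` (Benjamini-Hochberg across the
#'   reported sets), `median_log2fc` (NA; filled by callers that carry ratio
#'   records, see [theme_median_matrix()]).
#' @export
hypergeom_enrich <- function(query, universe, sets, min_overlap = 2L) {
  if (anyDuplicated(universe))
    stop("universe contains duplicate gene id(s)")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) absent from universe: ", paste(outside, collapse = ", "))
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(members, query))
    if (k < min_overlap) return(NULL)
    # P(X >= k) drawing n_query genes from universe with |members| successes
    p <- stats::phyper(k - 1L, length(members), n_univ - length(members),
                       n_query, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k,
               set_size_in_universe = length(members),
               query_size = n_query, universe_size = n_univ,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set_name = character(0), overlap_count = integer(0),
                      set_size_in_universe = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      median_log2fc = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$median_log2fc <- NA_real_
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up false-discovery-rate adjustment; input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values in the input order, all in [0, 1].
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Theme-by-comparison matrix of median log2 ratios
#'
#' The summary behind the theme heatmap: each cell is the median log2 ratio
#' of a gene set's members within one pairwise comparison. A set with no
#' member present in a comparison yields NA.
#'
#' @param comparisons Named list of ratio-record data.frames (one per
#'   pairwise comparison, e.g. `SAM_vs_adult`).
#' @param sets Named list of character vectors.
#' @return A numeric matrix (set x comparison) of median log2 ratios.
#' @export
theme_median_matrix <- function(comparisons, sets) {
  if (is.null(names(comparisons)) || is.null(names(sets)))
    stop("comparisons and sets must both be named")
  out <- matrix(NA_real_, nrow = length(sets), ncol = length(comparisons),
                dimnames = list(names(sets), names(comparisons)))
  for (ci in seq_along(comparisons)) {
    rec <- comparisons[[ci]]
    lr <- setNames(rec$log2_ratio, rec$gene_id)
    for (si in seq_along(sets)) {
      vals <- lr[intersect(unique(sets[[si]]), names(lr))]
      if (length(vals)) out[si, ci] <- stats::median(vals)
    }
  }
  out
}
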