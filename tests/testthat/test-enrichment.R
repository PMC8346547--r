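test_that("hypergeometric enrichment matches exhaustive urn enumeration", {
  sets <- list(SETA = c("G1", "G2"))
  universe <- sprintf("G%d", 1:10)
  res <- hypergeom_enrich(c("G1", "G2"), universe, sets)
  expect_equal(res$p_value, 1 / 45, tolerance = 1e-12)
  expect_equal(res$p_value, hyper_enumeration_oracle(2, 2, 10, 2),
               tolerance = 1e-12)

  # random instances with N <= 12, enumerated exhaustively
  set.seed(17)
  for (rep_ in 1:20) {
    N <- sample(5:12, 1)
    universe <- sprintf("U%02d", seq_len(N))
    set_size <- sample(2:(N - 1), 1)
    query_size <- sample(2:(N - 1), 1)
    sets_r <- list(S = universe[seq_len(set_size)])
    query <- sample(universe, query_size)
    res_r <- hypergeom_enrich(query, universe, sets_r, min_overlap = 0L)
    k <- length(intersect(query, sets_r$S))
    if (nrow(res_r)) {
      expect_equal(res_r$p_value,
                   hyper_enumeration_oracle(k, set_size, N, query_size),
                   tolerance = 1e-10)
    }
  }
})

test_that("enrichment input rules: universe coverage, certain overlap, min_overlap", {
  universe <- sprintf("G%d", 1:10)
  expect_error(hypergeom_enrich(c("G1", "GX"), universe, list(S = "G1")), "GX")
  expect_error(hypergeom_enrich("G1", c(universe, "G1"), list(S = "G1")),
               "duplicate")

  res_all <- hypergeom_enrich(universe, universe, list(ALL = universe))
  expect_equal(res_all$p_value, 1)

  res_min <- hypergeom_enrich(c("G1", "G2", "G3"), universe,
                              list(S1 = c("G1", "G4"), S2 = c("G1", "G2")),
                              min_overlap = 2L)
  expect_identical(res_min$set_name, "S2")
})

test_that("Benjamini-Hochberg step-up values are exact and bounded", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # hand-computed step-up: p * m / rank with cumulative minimum from the top
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.04, 0.8)),
               c(0.02, 0.0533333333333333, 0.0533333333333333, 0.8))
  set.seed(4)
  p <- stats::runif(50)
  q <- benjamini_hochberg(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0, 1")
})

test_that("theme medians match a sort-based oracle and ignore gene order", {
  rec1 <- data.frame(gene_id = c("A", "B", "C", "D"),
                     log2_ratio = c(1, 2, 3, 10), stringsAsFactors = FALSE)
  rec2 <- data.frame(gene_id = c("A", "B", "C", "D"),
                     log2_ratio = c(1, 3, -2, 0), stringsAsFactors = FALSE)
  sets <- list(odd = c("A", "B", "C"), even = c("A", "B"), none = "ZZ")
  m <- theme_median_matrix(list(c1 = rec1, c2 = rec2), sets)
  expect_equal(m["odd", "c1"], 2)     # odd-length median
  expect_equal(m["even", "c1"], 1.5)  # even-length mean of middles
  expect_true(is.na(m["none", "c1"]))

  shuffled <- list(odd = c("C", "A", "B"), even = c("B", "A"), none = "ZZ")
  expect_equal(theme_median_matrix(list(c1 = rec1, c2 = rec2), shuffled), m)

  set.seed(9)
  ids <- sprintf("G%03d", 1:50)
  rec_r <- data.frame(gene_id = ids, log2_ratio = stats::rnorm(50),
                      stringsAsFactors = FALSE)
  sets_r <- lapply(1:5, function(i) sample(ids, sample(3:20, 1)))
  names(sets_r) <- paste0("S", 1:5)
  m_r <- theme_median_matrix(list(only = rec_r), sets_r)
  for (nm in names(sets_r)) {
    vals <- rec_r$log2_ratio[rec_r$gene_id %in% sets_r[[nm]]]
    srt <- sort(vals); n <- length(srt)
    oracle <- if (n %% 2 == 1) srt[(n + 1) / 2] else mean(srt[n / 2 + 0:1])
    expect_equal(m_r[nm, "only"], oracle)
  }
})
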