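test_that("group means match a per-group accumulation oracle", {
  m <- make_matrix(rbind(c(1, 2, 3, 10, 20), rep(0, 5)))
  d <- make_design(c("stunting", "stunting", "stunting", "adult", "adult"))
  gm <- group_means(m, d)
  expect_equal(gm$mean_stunting, c(2, 0))
  expect_equal(gm$mean_adult, c(15, 0))
  expect_identical(gm$n_stunting, c(3L, 3L))

  m2 <- random_matrix(100, 20, seed = 5)
  d2 <- make_design(rep(c("stunting", "SAM", "adult"), length.out = 20))
  gm2 <- group_means(m2, d2)
  for (co in c("stunting", "SAM", "adult")) {
    cols <- which(d2$cohort == co)
    oracle <- apply(m2[, cols, drop = FALSE], 1L, function(v) sum(v) / length(v))
    expect_equal(gm2[[paste0("mean_", co)]], unname(oracle), tolerance = 1e-12)
  }
})

test_that("ratio records use the pseudocount and flag double-zero genes", {
  sm <- data.frame(gene_id = c("LCT", "ZERO", "FLAT"),
                   mean_stunting = c(363.1, 0, 5),
                   mean_adult = c(14.0, 0, 5))
  rec <- compute_ratio_records(sm, "stunting", "adult", pseudocount = 0.01)
  expect_equal(rec$ratio[1], (363.1 + 0.01) / (14.0 + 0.01))
  expect_equal(rec$ratio[1], 25.9175, tolerance = 1e-3)
  expect_true(rec$excluded_zero[2])
  expect_identical(rec$tail[2], "none")
  expect_equal(rec$log2_ratio[3], 0)
  expect_error(compute_ratio_records(sm, "stunting", "stunting"), "differ")
  expect_error(compute_ratio_records(sm, "stunting", "adult", pseudocount = 0),
               "positive")
})

test_that("tail selection takes floor(n*alpha/2) per tail and matches the sort oracle", {
  sm <- data.frame(gene_id = sprintf("G%03d", 1:40),
                   mean_SAM = seq(1, 40), mean_adult = rep(10, 40))
  rec <- tail_select(compute_ratio_records(sm, "SAM", "adult"), alpha = 0.05)
  expect_identical(sum(rec$tail == "upper"), 1L)   # floor(40 * 0.025) = 1
  expect_identical(sum(rec$tail == "lower"), 1L)
  expect_identical(rec$gene_id[rec$tail == "upper"], "G040")
  expect_identical(rec$gene_id[rec$tail == "lower"], "G001")

  set.seed(99)
  for (rep_ in 1:25) {
    n <- sample(10:500, 1)
    sm_r <- data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                       mean_SAM = round(stats::rexp(n, 0.1), 2),
                       mean_adult = round(stats::rexp(n, 0.1), 2))
    rec_r <- suppressWarnings(
      tail_select(compute_ratio_records(sm_r, "SAM", "adult"), alpha = 0.05))
    oracle <- tail_oracle(rec_r$log2_ratio, rec_r$gene_id, rec_r$excluded_zero)
    expect_identical(sort(rec_r$gene_id[rec_r$tail == "upper"]), oracle$upper)
    expect_identical(sort(rec_r$gene_id[rec_r$tail == "lower"]), oracle$lower)
  }

  rec_small <- compute_ratio_records(sm[1:10, ], "SAM", "adult")
  expect_warning(out <- tail_select(rec_small, alpha = 0.05), "no genes")
  expect_true(all(out$tail == "none"))
})

test_that("swapping numerator and denominator negates ratios and mirrors the tails", {
  sm <- data.frame(gene_id = sprintf("G%03d", 1:200),
                   mean_SAM = round(stats::rexp(200, 0.1), 3),
                   mean_adult = round(stats::rexp(200, 0.1), 3))
  fwd <- tail_select(compute_ratio_records(sm, "SAM", "adult"))
  rev_ <- tail_select(compute_ratio_records(sm, "adult", "SAM"))
  expect_equal(rev_$log2_ratio, -fwd$log2_ratio, tolerance = 1e-12)
  expect_identical(sort(rev_$gene_id[rev_$tail == "upper"]),
                   sort(fwd$gene_id[fwd$tail == "lower"]))
  expect_identical(sort(rev_$gene_id[rev_$tail == "lower"]),
                   sort(fwd$gene_id[fwd$tail == "upper"]))
})

test_that("trimming implements the either/both FPKM >= 1 rules without touching tails", {
  rec <- data.frame(gene_id = c("A", "B", "C"),
                    numerator_cohort = "SAM", denominator_cohort = "adult",
                    num_mean = c(0.5, 2.0, 0.2), den_mean = c(2.0, 3.0, 0.4),
                    ratio = 1, log2_ratio = 0, tail = c("upper", "none", "lower"),
                    trimmed_out = FALSE, excluded_zero = FALSE,
                    stringsAsFactors = FALSE)
  any_ <- trim_deg(rec, mode = "any")
  expect_identical(any_$trimmed_out, c(FALSE, FALSE, TRUE))
  both <- trim_deg(rec, mode = "both")
  expect_identical(both$trimmed_out, c(TRUE, FALSE, TRUE))
  expect_identical(any_$tail, rec$tail)
  expect_error(trim_deg(rec, mode = "either"), "arg")

  rec_hi <- transform(rec, num_mean = num_mean + 10, den_mean = den_mean + 10)
  expect_identical(trim_deg(rec_hi, mode = "any")$trimmed_out,
                   trim_deg(rec_hi, mode = "both")$trimmed_out)
})

test_that("deg_list counts selected and trimmed records", {
  sm <- data.frame(gene_id = sprintf("G%03d", 1:100),
                   mean_SAM = c(round(stats::rexp(98, 0.1), 2), 0.2, 900),
                   mean_adult = c(round(stats::rexp(98, 0.1), 2), 40, 0.3))
  rec <- trim_deg(tail_select(compute_ratio_records(sm, "SAM", "adult")))
  up <- deg_list(rec, "up")
  expect_identical(up$comparison, "SAM_vs_adult")
  expect_identical(up$n_selected, sum(rec$tail == "upper"))
  expect_true(up$n_after_trim <= up$n_selected)
})

test_that("Mann-Whitney p-values match exact enumeration and the large-sample branch", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$raw_p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$raw_p, mw_enumeration_oracle(c(1, 2), c(3, 4)),
               tolerance = 1e-12)

  # exact branch vs enumeration oracle over assorted tie-free layouts
  set.seed(21)
  for (m in c(2, 4, 6, 8)) {
    for (n in c(3, 5, 8)) {
      x <- stats::rnorm(m); y <- stats::rnorm(n, 0.5)
      expect_equal(mann_whitney_u(x, y)$raw_p, mw_enumeration_oracle(x, y),
                   tolerance = 1e-10, label = sprintf("m=%d n=%d", m, n))
    }
  }

  # identical samples: no shift
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$raw_p, 0.99)

  # normal-approximation branch close to the exact branch at 8 vs 8
  set.seed(8)
  x8 <- stats::rnorm(8); y8 <- stats::rnorm(8, 1)
  exact_p <- mann_whitney_u(x8, y8)$raw_p
  approx_p <- stats::wilcox.test(x8, y8, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(exact_p - approx_p), 0.02)

  # large-sample cross-check against an independent implementation
  set.seed(30)
  x30 <- stats::rnorm(30); y27 <- stats::rnorm(27, 0.8)
  ours <- mann_whitney_u(x30, y27)$raw_p
  expect_equal(ours, mw_normal_oracle(x30, y27), tolerance = 1e-3)

  expect_error(mann_whitney_u(1, c(1, 2)), "at least 2")
})

test_that("strict filter enforces both the fold-change and p-value gates", {
  # group sizes comparable to the study's cohorts: with small groups the
  # rank-test p-value can never reach 1e-6
  set.seed(77)
  n_a <- 27; n_b <- 37
  flat <- stats::rnorm(n_a + n_b, 50, 5)
  shifted <- c(stats::rnorm(n_a, 400, 20), stats::rnorm(n_b, 50, 5))
  big_fc_weak_p <- c(stats::rnorm(n_a, 200, 300), stats::rnorm(n_b, 50, 100))
  m <- make_matrix(rbind(abs(flat), abs(shifted), abs(big_fc_weak_p)),
                   genes = c("FLAT", "SHIFT", "NOISY"))
  d <- make_design(rep(c("SAM", "adult"), c(n_a, n_b)))
  sf <- strict_filter(m, d, "SAM", "adult")
  expect_false(sf$passes[sf$gene_id == "FLAT"])
  expect_true(sf$passes[sf$gene_id == "SHIFT"])
  expect_true(all(sf$adjusted_p == pmin(1, sf$raw_p * 3)))
  # gates are individually necessary
  expect_true(all(abs(sf$log2_fold_change[sf$passes]) > log2(2.5)))
  expect_true(all(sf$raw_p[sf$passes] < 1e-6))
  expect_error(strict_filter(m, d, "SAM", "adult", fc_threshold = 1), "greater than 1")
})

test_that("a planted 8-fold shift passes the strict filter on synthetic cohorts", {
  p <- synth_params(n_genes = 200, seed = 101,
                    planted_fraction_stunting = 0, planted_fraction_sam = 0,
                    zero_gene_fraction = 0,
                    per_gene_noise_sd_range = c(0.2, 0.3))
  sim <- generate_dataset(p)
  m <- sim$matrix
  m["g00001", sim$design$cohort == "SAM"] <- m["g00001", sim$design$cohort == "SAM"] * 8
  sf <- strict_filter(m, sim$design, "SAM", "adult")
  expect_true(sf$passes[sf$gene_id == "g00001"])
})

test_that("the strict filter is specific under a global null", {
  p <- synth_params(n_genes = 5000, seed = 314,
                    planted_fraction_stunting = 0, planted_fraction_sam = 0)
  sim <- generate_dataset(p)
  sf <- strict_filter(sim$matrix, sim$design, "SAM", "adult")
  expect_lte(sum(sf$raw_p < 1e-6), 1)
  expect_lte(sum(sf$passes), 1)
})
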