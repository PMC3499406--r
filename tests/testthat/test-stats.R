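test_that("goodness-of-fit matches closed forms and chisq.test", {
  oe <- observed_expected(c("a", "b"), c(10, 0), c(5, 5))
  res <- chisq_goodness_of_fit(oe)
  expect_equal(res$statistic, 10)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 1.565402e-3, tolerance = 1e-6)

  perfect <- observed_expected(letters[1:3], c(4, 4, 4), c(4, 4, 4))
  expect_equal(chisq_goodness_of_fit(perfect)$statistic, 0)
  expect_equal(chisq_goodness_of_fit(perfect)$p_value, 1)

  # agreement with stats::chisq.test on a non-trivial table
  obs <- c(12, 30, 7, 51)
  p <- c(0.1, 0.3, 0.1, 0.5)
  oe2 <- observed_expected(letters[1:4], obs, sum(obs) * p)
  ref <- suppressWarnings(chisq.test(obs, p = p))
  mine <- chisq_goodness_of_fit(oe2)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)

  expect_error(observed_expected("a", 1, 0), "positive")
  expect_error(observed_expected(c("a", "b"), c(1, 1), c(3, 3)),
               "totals differ")
})

test_that("chi-squared p is permutation-invariant and monotone in X2", {
  obs <- c(9, 2, 14, 5)
  exp <- c(7.5, 7.5, 7.5, 7.5)
  p1 <- chisq_goodness_of_fit(observed_expected(letters[1:4], obs, exp))
  perm <- c(3, 1, 4, 2)
  p2 <- chisq_goodness_of_fit(observed_expected(letters[1:4], obs[perm],
                                                exp[perm]))
  expect_equal(p1$statistic, p2$statistic)
  expect_equal(p1$p_value, p2$p_value)
  x2 <- seq(0.5, 30, by = 0.5)
  p <- pchisq(x2, df = 3, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("positional bins start at 1, merge the short tail, and sum", {
  raw <- positional_bins(make_ms(c(577L, 3000L), rep("", 2), rep("A", 2),
                                 kind = rep("insertion", 2)),
                         merge_small = FALSE)
  expect_equal(nrow(raw), 9L)
  expect_equal(raw$category[1], "1-2000")
  expect_equal(raw$category[9], "16001-16569")
  # bin/region overlaps: 1424 + 7x2000 + 23 over the coding region
  expect_equal(raw$expected / sum(raw$observed) * 15447,
               c(1424, rep(2000, 7), 23))

  merged <- positional_bins(make_ms(c(577L, 3000L), rep("", 2), rep("A", 2),
                                    kind = rep("insertion", 2)))
  expect_equal(nrow(merged), 8L)
  expect_equal(merged$category[8], "14001-16569")
  expect_equal(sum(merged$expected), 2)

  eq <- positional_bins(make_ms(c(577L, 3000L), rep("", 2), rep("A", 2),
                                kind = rep("insertion", 2)),
                        expected = "equal")
  expect_true(all(abs(eq$expected - 2 / 8) < 1e-12))
  expect_error(positional_bins(make_ms(50L, "", "A", kind = "insertion")),
               "outside the analyzed region")
  expect_error(positional_bins(make_ms(600L, "", "A", kind = "insertion"),
                               bin_size = 0L), "bin_size")
})

test_that("gene-type GOF uses genome-occupancy expectations", {
  # all mutations observed exactly at expectation gives p = 1
  lens <- gene_type_lengths(rcrs_ann, c(577L, 16023L))[1:3]
  # uniform synthetic: expected proportions near 11341/1504/2513 of 15447
  ms <- generate_cohort(cohort_spec(n_cells = 300,
                                    count_probs = c(`1` = 1),
                                    transition_pairs = NULL,
                                    transversion_pairs = NULL),
                        rcrs_ann, seed = 77)
  fc <- filter_coding_region(ms)
  res <- gene_type_gof(fc, rcrs_ann)
  expect_s3_class(res, "TestResult")
  expect_equal(res$df, 2L)
  expect_equal(sum(res$observed), length(fc) - res$n_noncoding_excluded)
  expect_equal(sum(res$expected), sum(res$observed))
  expect_equal(res$expected / sum(res$observed),
               unname(lens / sum(lens)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("contingency comparison matches closed forms and Bonferroni", {
  tab <- cbind(g1 = c(10, 0), g2 = c(0, 10))
  rownames(tab) <- c("a", "b")
  res <- contingency_compare(tab)
  expect_equal(res$overall$statistic, 20)
  expect_equal(res$overall$df, 1L)
  expect_equal(res$overall$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(res$overall$p_value, 7.744216e-6, tolerance = 1e-6)

  same <- cbind(g1 = c(5, 5), g2 = c(5, 5))
  expect_equal(contingency_compare(same)$overall$statistic, 0)
  expect_equal(contingency_compare(same)$overall$p_value, 1)

  three <- cbind(a = c(30, 10), b = c(28, 12), c = c(5, 40))
  res3 <- contingency_compare(three)
  expect_equal(nrow(res3$pairwise), 3L)
  expect_equal(unname(res3$thresholds),
               c(0.05 / 3, 0.01 / 3, 0.001 / 3))
  expect_equal(round(unname(res3$thresholds["*"]), 3), 0.017)
  expect_equal(res3$pairwise$p_bonferroni,
               pmin(1, res3$pairwise$p_value * 3))
  # Yates flag available for sensitivity checks
  yates <- contingency_compare(tab, correct = TRUE)
  expect_lt(yates$overall$statistic, 20)

  expect_error(contingency_compare(cbind(a = c(0, 0), b = c(1, 1))),
               "zero total")
})

test_that("contingency accepts MutationSets with a categorizer", {
  ms1 <- make_ms(c(3243L, 1555L, 5000L), rep("", 3), rep("A", 3),
                 kind = rep("insertion", 3))
  ms2 <- make_ms(c(3243L, 3243L), rep("", 2), rep("A", 2),
                 kind = rep("insertion", 2), cell_id = c("x1", "x2"))
  res <- contingency_compare(
    list(one = ms1, two = ms2),
    function(ms) region_class(rcrs_ann, as.data.frame(ms)$position))
  expect_equal(sum(res$table), 5)
  # identical cohorts give p = 1
  same <- contingency_compare(
    list(a = ms1, b = ms1),
    function(ms) region_class(rcrs_ann, as.data.frame(ms)$position))
  expect_equal(same$overall$p_value, 1)
})

test_that("exact Wilcoxon equals brute-force enumeration (n1+n2 <= 10)", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")$p_value,
               1 / 3, tolerance = 1e-12)
  withr::with_seed(55, {
    for (n1 in 2:5) for (n2 in n1:min(10 - n1, 5)) {
      x <- sample(seq(0.01, 0.99, by = 0.01), n1)
      y <- sample(setdiff(seq(0.01, 0.99, by = 0.01), x), n2)
      mine <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
      expect_equal(mine, wilcoxon_brute_force(x, y), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  })
  # identical multisets give p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("normal approximation tracks the exact Wilcoxon p", {
  withr::with_seed(56, {
    for (k in 1:10) {
      n1 <- sample(8:12, 1); n2 <- sample(8:12, 1)
      vals <- sample(seq_len(500), n1 + n2)  # tie-free
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
      pa <- wilcoxon_rank_sum(x, y, mode = "normal_approx")$p_value
      expect_lt(abs(pe - pa), 0.01)
    }
  })
})
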