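test_that("cohort generation is a pure function of spec and seed", {
  spec <- cohort_spec()
  a <- generate_cohort(spec, rcrs_ann, seed = 4, cohort = "ageing")
  b <- generate_cohort(spec, rcrs_ann, seed = 4, cohort = "ageing")
  expect_identical(a$mutations, b$mutations)
  c <- generate_cohort(spec, rcrs_ann, seed = 5, cohort = "ageing")
  expect_false(identical(a$mutations, c$mutations))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_cohort(spec, rcrs_ann, seed = 4))
  expect_identical(runif(1), before)
})

test_that("generated records validate and follow the spec structure", {
  spec <- cohort_spec()
  ms <- generate_cohort(spec, rcrs_ann, seed = 8, cohort = "ageing")
  expect_silent(validate_mutations(ms, ref_genome))
  df <- ms$mutations
  expect_true(all(df$position >= 577L & df$position <= 16023L))
  expect_true(all(df$cohort == "ageing"))
  prof <- cell_mutation_profile(ms)
  expect_lte(max(prof$cells$n_mutations), 4L)
  expect_equal(length(ms) ,
               sum(prof$cells$n_mutations))
  expect_equal(attr(ms, "n_cells_without_mutations") +
                 nrow(prof$cells), spec$n_cells)
})

test_that("positional model matches gene occupancy at large n", {
  big <- cohort_spec(n_cells = 10000L, count_probs = c(`1` = 1),
                     type_mix = c(transition = 1, transversion = 0,
                                  insertion = 0, deletion = 0),
                     transition_pairs = NULL, transversion_pairs = NULL)
  ms <- generate_cohort(big, rcrs_ann, seed = 14)
  nd5 <- rcrs_ann$genes[rcrs_ann$genes$symbol == "MT-ND5", ]
  p_nd5 <- 1812 / 15447
  frac <- mean(ms$mutations$position >= nd5$start &
                 ms$mutations$position <= nd5$end)
  expect_lt(abs(frac - p_nd5), 3 * sqrt(p_nd5 * (1 - p_nd5) / 10000))
})

test_that("type mix and transition pair mix are recovered", {
  big <- cohort_spec(n_cells = 10000L, count_probs = c(`1` = 1),
                     type_mix = c(transition = 0.9, transversion = 0.1,
                                  insertion = 0, deletion = 0))
  ms <- generate_cohort(big, rcrs_ann, seed = 15)
  ct <- classify_change_type(ms$mutations$ref, ms$mutations$alt,
                             ms$mutations$kind)
  frac_ts <- mean(ct == "transition")
  expect_lt(abs(frac_ts - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
  ts <- ms$mutations[ct == "transition", ]
  lab <- strand_symmetric_label(ts$ref, ts$alt)
  frac_cg <- mean(lab == "C:G>T:A")
  expect_lt(abs(frac_cg - 0.65), 3 * sqrt(0.65 * 0.35 / nrow(ts)))
})

test_that("heteroplasmy model hits the homoplasmic point mass", {
  big <- cohort_spec(n_cells = 5000L, count_probs = c(`1` = 1))
  ms <- generate_cohort(big, rcrs_ann, seed = 16)
  frac <- cell_mutation_profile(ms)$homoplasmic_fraction
  expect_lt(abs(frac - 0.39), 3 * sqrt(0.39 * 0.61 / 5000))
  het <- ms$mutations$heteroplasmy_percent
  expect_true(all(het == 100 | (het >= 15 & het <= 95)))
})

test_that("COX deficiency is enriched in high-heteroplasmy cells", {
  big <- cohort_spec(n_cells = 4000L, count_probs = c(`1` = 1))
  ms <- generate_cohort(big, rcrs_ann, seed = 17)
  df <- ms$mutations
  high <- df$heteroplasmy_percent >= 80
  p_high <- mean(df$cox_status[high] == "deficient")
  p_low <- mean(df$cox_status[!high] == "deficient")
  expect_gt(p_high, p_low)
  expect_lt(abs(p_high - 0.85), 0.05)
  expect_lt(abs(p_low - 0.20), 0.05)
})

test_that("selection thinning removes the requested non-synonymous share", {
  big <- cohort_spec(n_cells = 10000L, count_probs = c(`1` = 1))
  ms <- generate_cohort(big, rcrs_ann, seed = 18)
  ann_df <- annotate_mutations(ms, rcrs_ann)
  n_nonsyn <- sum(ann_df$change_class == "non_synonymous")

  ident <- spike_selection(ms, rcrs_ann, retention = 1, seed = 19)
  expect_equal(`rownames<-`(ident$mutations, NULL),
               `rownames<-`(ms$mutations, NULL))

  none <- spike_selection(ms, rcrs_ann, retention = 0, seed = 19)
  none_ann <- annotate_mutations(none, rcrs_ann)
  expect_equal(sum(none_ann$change_class == "non_synonymous"), 0L)
  expect_equal(length(none), length(ms) - n_nonsyn)

  half <- spike_selection(ms, rcrs_ann, retention = 0.5, seed = 19)
  kept <- length(half) - (length(ms) - n_nonsyn)
  expect_lt(abs(kept - 0.5 * n_nonsyn), 3 * sqrt(n_nonsyn * 0.25))
  expect_error(spike_selection(ms, rcrs_ann, retention = 1.5, seed = 1),
               "retention")
})

test_that("synthetic score tables key the enumeration and match Beta moments", {
  enum <- enumerate_protein_variants(rcrs_ann)
  tab <- generate_score_table(enum, seed = 20, shape1 = 5, shape2 = 3)
  mis <- unique(enum$records[enum$records$class == "missense",
                             c("gene", "aa_pos", "aa_ref", "aa_alt")])
  expect_equal(nrow(tab), nrow(mis))
  expect_setequal(paste(tab$gene, tab$aa_pos, tab$aa_ref, tab$aa_alt),
                  paste(mis$gene, mis$aa_pos, mis$aa_ref, mis$aa_alt))
  m <- 5 / 8
  v <- 5 * 3 / ((5 + 3)^2 * 9)
  expect_lt(abs(mean(tab$score) - m), 3 * sqrt(v / nrow(tab)))
  # determinism
  tab2 <- generate_score_table(enum, seed = 20, shape1 = 5, shape2 = 3)
  expect_identical(tab$score, tab2$score)
})
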