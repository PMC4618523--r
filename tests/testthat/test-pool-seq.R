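test_that("rough selection from a wild-type cross is empty", {
  map <- sparse_map(150)
  pop <- simulate_cross(cross_scheme("BYx3S_WT"), 2000, map, seed = 5)
  expect_true(all(pop$phenotype == "SMOOTH"))
  sel <- select_segregants(pop, map, "ROUGH")
  expect_equal(n_segregants(sel), 0L)
})

test_that("selection filters combine phenotype and causal alleles", {
  map <- sparse_map(150)
  pop <- simulate_cross(cross_scheme("BYx3S_WT"), 4000, map, seed = 6)
  all_smooth <- select_segregants(pop, map, "SMOOTH")
  expect_equal(n_segregants(all_smooth), 4000L)
  # Mendelian retention at a segregating marker
  sel <- select_segregants(pop, map, "SMOOTH", c(END3 = "3S"))
  frac <- n_segregants(sel) / 4000
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / 4000))
  expect_error(select_segregants(pop, map, "SMOOTH", c(NOPE = "3S")),
               "causal sites")
})

test_that("true pool frequencies are exact fractions of the pool", {
  map <- sparse_map(150)
  pop <- simulate_cross(cross_scheme("BYx3S_IRA2MUT"), 3000, map, seed = 8)

  one <- bsacross:::subset_pop(pop, 1L)
  f1 <- pool_true_frequencies(one, map)
  expect_true(all(f1$freq %in% c(0, 1)))

  rough <- select_segregants(pop, map, "ROUGH")
  cls <- classify_interactions(rough, map)
  five <- bsacross:::subset_pop(rough, which(cls == "FIVE_WAY"))
  f <- pool_true_frequencies(five, map)
  idx <- causal_marker_index(map)
  # rule constraints force fixation at the four constrained genes
  expect_equal(unname(f$freq[idx[c("FLO8", "TRR1")]]), c(1, 1))
  expect_equal(unname(f$freq[idx[c("END3", "MSS11")]]), c(0, 0))
  expect_equal(unname(f$engineered[["IRA2_D2933"]]), 1)

  big <- pool_true_frequencies(pop, map)
  free <- setdiff(seq_len(nrow(map)), idx)
  expect_lt(max(abs(big$freq[free] - 0.5)), 4 * sqrt(0.25 / 3000))

  expect_error(pool_true_frequencies(bsacross:::subset_pop(pop, integer(0)),
                                     map), "empty")
})

test_that("noise-free sequencing reproduces the pooled frequencies", {
  map <- sparse_map(100)
  freqs <- setNames(rep(1, nrow(map)), map$id)
  counts <- simulate_pool_counts(freqs, pool_seq_params(60, 0, seed = 3),
                                 map)
  expect_true(all(counts$count_3s == counts$depth))
  expect_true(all(counts$count_by == 0L))
  expect_true(all(counts$count_other == 0L))
})

test_that("count conservation holds and coverage matches its mean", {
  n <- 20000L
  freqs <- rep(0.37, n)
  params <- pool_seq_params(80, 0.01, seed = 12)
  counts <- simulate_pool_counts(freqs, params)
  expect_silent(bsacross:::validate_allele_counts(counts))
  expect_lt(abs(mean(counts$depth) - 80) / 80, 0.02)
  # unbiased frequency estimator at zero error rate
  counts0 <- simulate_pool_counts(rep(0.37, n), pool_seq_params(80, 0, 13))
  fhat <- counts0$count_3s / (counts0$count_by + counts0$count_3s)
  se <- sqrt(0.37 * 0.63 / (80 * n))
  expect_lt(abs(mean(fhat, na.rm = TRUE) - 0.37), 4 * se)
})

test_that("law of large numbers at high coverage", {
  counts <- simulate_pool_counts(rep(0.8, 200),
                                 pool_seq_params(5000, 0, seed = 21))
  fhat <- counts$count_3s / counts$depth
  # max over 200 markers: allow the multiplicity of the extreme
  expect_lt(max(abs(fhat - 0.8)), 5 * sqrt(0.8 * 0.2 / 5000))
})

test_that("zero-depth markers yield zero counts and missing frequencies", {
  counts <- simulate_pool_counts(rep(0.5, 3000),
                                 pool_seq_params(1, 0, seed = 31))
  zero <- counts$depth == 0L
  expect_gt(sum(zero), 0L)
  expect_true(all(counts$count_by[zero] == 0L))
  track <- frequencies_from_counts(counts)
  expect_true(all(is.na(track$freq[zero])))
})

test_that("miscalls populate count_other at the configured rate", {
  n <- 50000L
  counts <- simulate_pool_counts(rep(1, n), pool_seq_params(50, 0.03, 41))
  tot <- sum(counts$depth)
  # 2/3 of miscalls leave the parental pair
  expect_lt(abs(sum(counts$count_other) / tot - 0.02), 0.002)
  expect_lt(abs(sum(counts$count_by) / tot - 0.01), 0.002)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(pool_seq_params(0), "mean_coverage")
  expect_error(pool_seq_params(10, 1), "error_rate")
  expect_error(simulate_pool_counts(c(0.5, 1.2), pool_seq_params(10)),
               "frequencies")
})
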