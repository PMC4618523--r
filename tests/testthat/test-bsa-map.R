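test_that("frequency computation excludes non-parental reads", {
  map <- manual_map(c(3))
  tab <- counts_from_freqs(map, c(0, 0, 0))
  tab$count_by <- c(0L, 25L, 30L)
  tab$count_3s <- c(50L, 25L, 60L)
  tab$count_other <- c(0L, 0L, 10L)
  tab$depth <- tab$count_by + tab$count_3s + tab$count_other
  track <- frequencies_from_counts(tab)
  expect_equal(track$freq, c(1, 0.5, 60 / 90))
})

test_that("low-depth markers become missing at the configured floor", {
  map <- manual_map(c(4))
  tab <- counts_from_freqs(map, rep(0.5, 4), depth = 10L)
  tab$count_by[2] <- 1L; tab$count_3s[2] <- 1L; tab$count_other[2] <- 8L
  track <- frequencies_from_counts(tab, mapping_params(min_depth = 5))
  expect_true(is.na(track$freq[2]))
  expect_false(anyNA(track$freq[-2]))
})

test_that("window means are exact arithmetic means stepping one marker", {
  map <- manual_map(c(12))
  f <- c(rep(1, 10), 0, 0.5)
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map)
  expect_equal(nrow(win), 3L)
  expect_equal(win$mean_freq, c(1, 0.9, (8 + 0 + 0.5) / 10))
  expect_equal(win$start_bp, map$pos_bp[1:3])
  expect_equal(win$end_bp, map$pos_bp[10:12])
})

test_that("chromosomes below the window size yield no windows", {
  map <- manual_map(c(9, 15))
  f <- rep(1, nrow(map))
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map)
  expect_true(all(win$chrom == "II"))
  expect_equal(nrow(win), 6L)
})

test_that("missing markers are skipped, not interpolated", {
  map <- manual_map(c(14))
  tab <- counts_from_freqs(map, rep(1, 14))
  tab[3, c("count_by", "count_3s", "count_other", "depth")] <- 0L
  track <- frequencies_from_counts(tab)
  win <- sliding_windows(track, map)
  expect_equal(nrow(win), 4L)          # 13 informative markers
  expect_equal(win$end_bp[1], map$pos_bp[11])  # window spans the gap
})

test_that("window means are bounded by their member frequencies", {
  map <- manual_map(c(60))
  set.seed(17)
  f <- runif(60)
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map)
  roll_min <- vapply(seq_len(51), function(i) min(f[i:(i + 9)]), 0)
  roll_max <- vapply(seq_len(51), function(i) max(f[i:(i + 9)]), 0)
  # counts quantise frequencies to 1/100, keep a matching tolerance
  expect_true(all(win$mean_freq >= roll_min - 0.005))
  expect_true(all(win$mean_freq <= roll_max + 0.005))
})

test_that("overlong windows spanning uninformative gaps are discarded", {
  map <- manual_map(c(30))
  f <- rep(1, 30)
  tab <- counts_from_freqs(map, f)
  informative <- rep(TRUE, 30)
  informative[6:25] <- FALSE   # 20-marker hole = 8 cM gap
  track <- frequencies_from_counts(tab, informative = informative)
  win_all <- sliding_windows(track, map,
                             mapping_params(max_window_cm = Inf))
  win_cap <- sliding_windows(track, map, mapping_params(max_window_cm = 5))
  expect_gt(nrow(win_all), nrow(win_cap))
  expect_equal(nrow(win_cap), 0L)      # every window straddles the hole
})

test_that("an unselected track yields no locus calls", {
  map <- manual_map(c(40, 40))
  f <- rep(0.5, nrow(map))
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map)
  calls <- call_fixed_loci(win, map)
  expect_equal(nrow(calls), 0L)
})

test_that("fixation calls use an inclusive threshold and both alleles", {
  map <- manual_map(c(40))
  f <- rep(0.5, 40)
  f[10:19] <- 0.95             # exactly at threshold
  f[30:39] <- 0.02             # BY-fixed
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map)
  calls <- call_fixed_loci(win, map)
  expect_equal(nrow(calls), 2L)
  expect_setequal(calls$fixed_allele, c("3S", "BY"))
  by_call <- calls[calls$fixed_allele == "BY", ]
  expect_gte(by_call$mean_freq, 0.95)  # frequency of the fixed allele
})

test_that("calls within the merge radius consolidate; distant ones do not", {
  map <- manual_map(c(200))     # 200 kb = 80 cM at 0.4 cM/kb
  f <- rep(0.5, 200)
  f[20:35] <- 1                 # locus A
  f[45:55] <- 1                 # fragment 4 cM away: same locus
  f[150:165] <- 1               # locus B, 38 cM beyond
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map)
  calls <- call_fixed_loci(win, map)
  expect_equal(nrow(calls), 2L)
  calls0 <- call_fixed_loci(win, map, mapping_params(merge_gap_cm = 0))
  expect_equal(nrow(calls0), 3L)
})

test_that("delimitation trims a call to its qualifying windows", {
  map <- manual_map(c(40))
  f <- rep(0.4, 40)   # background clear of the inclusive 0.95 boundary
  f[15:24] <- 1
  params <- mapping_params()
  win <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f)),
                         map, params)
  calls <- call_fixed_loci(win, map, params)
  expect_equal(nrow(calls), 1L)
  iv <- delimit_interval(calls[1, ], win, params)
  expect_equal(unname(iv), c(map$pos_bp[15], map$pos_bp[24]))

  # two overlapping qualifying windows span the 11-marker union
  f2 <- rep(0.4, 40)
  f2[15:25] <- 1
  win2 <- sliding_windows(frequencies_from_counts(counts_from_freqs(map, f2)),
                          map, params)
  calls2 <- call_fixed_loci(win2, map, params)
  iv2 <- delimit_interval(calls2[1, ], win2, params)
  expect_equal(unname(iv2), c(map$pos_bp[15], map$pos_bp[25]))
})

test_that("calls are invariant to flanking all-heterozygous chromosomes", {
  map1 <- manual_map(c(40))
  f1 <- rep(0.5, 40); f1[10:19] <- 1
  win1 <- sliding_windows(frequencies_from_counts(counts_from_freqs(map1, f1)),
                          map1)
  calls1 <- call_fixed_loci(win1, map1)

  map3 <- manual_map(c(30, 40, 30))
  f3 <- c(rep(0.5, 30), f1, rep(0.5, 30))
  win3 <- sliding_windows(frequencies_from_counts(counts_from_freqs(map3, f3)),
                          map3)
  calls3 <- call_fixed_loci(win3, map3)
  expect_equal(nrow(calls3), 1L)
  expect_equal(calls3$chrom, "II")
  expect_equal(calls3$start_bp, calls1$start_bp)
  expect_equal(calls3$end_bp, calls1$end_bp)
})

test_that("engineered-site calls are relabelled MUTANT", {
  map <- dense_map()
  res <- backcross_mapping_experiment(map, "SIX_WAY", seed = 301)
  ira2 <- res$loci[grepl("IRA2", res$loci$causal_genes), ]
  expect_equal(nrow(ira2), 1L)
  expect_equal(ira2$fixed_allele, "MUTANT")
})

test_that("reciprocal panels see complementary subsets of the loci", {
  map <- dense_map()
  res <- backcross_mapping_experiment(map, "SIX_WAY", seed = 302)
  loci <- res$loci
  # founder-BY loci are monomorphic in the BY backcross: 3S panel only
  for (g in c("MGA1", "MSS11", "SFL1")) {
    row <- loci[grepl(g, loci$causal_genes), ]
    expect_equal(row$pool, "3S", info = g)
  }
  for (g in c("END3", "FLO8")) {
    row <- loci[grepl(g, loci$causal_genes), ]
    expect_equal(row$pool, "BY", info = g)
  }
})

test_that("unselected reciprocal pools produce an empty merged report", {
  map <- dense_map()
  set.seed(303)
  founder <- sample_rough_founder(map, "SIX_WAY")
  mk <- function(scheme_name, n, cov) {
    pop <- simulate_cross(cross_scheme(scheme_name, founder), n, map)
    simulate_pool_counts(pool_true_frequencies(pop, map),
                         pool_seq_params(cov), map)
  }
  pool_by <- mk("BACKCROSS_BY", 150, 100)
  pool_3s <- mk("BACKCROSS_3S", 150, 100)
  rep0 <- map_backcross_pools(pool_by, pool_3s, map, founder = founder)
  expect_equal(nrow(rep0), 0L)
})

test_that("rough six-way pools recover every rule-constrained locus", {
  map <- dense_map()
  for (s in 1:3) {
    res <- backcross_mapping_experiment(map, "SIX_WAY", seed = 310 + s)
    expect_setequal(genes_in_report(res$loci),
                    c("END3", "FLO8", "MGA1", "MSS11", "SFL1", "IRA2"))
    for (g in c("END3", "FLO8", "MGA1", "MSS11", "SFL1", "IRA2")) {
      expect_true(locus_contains_gene(res$loci, map, g), info = g)
    }
  }
})
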