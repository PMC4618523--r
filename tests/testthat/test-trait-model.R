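test_that("default rule set encodes the three interaction genotypes", {
  rs <- default_rule_set()
  expect_length(rs$rules, 3L)
  expect_equal(vapply(rs$rules, `[[`, "", "name"),
               c("R_five", "R_six", "R_sfl1"))
  expect_length(rs$rules[[1]]$required_alleles, 4L)  # five-way: 4 cryptics
  expect_length(rs$rules[[2]]$required_alleles, 5L)  # six-way: 5 cryptics
  expect_true(all(vapply(rs$rules, `[[`, 0, "penetrance") == 1))
  expect_equal(rs$default_phenotype, "SMOOTH")
})

test_that("classification reproduces the reported genotype-phenotype pairs", {
  map <- sparse_map(200)
  rs <- default_rule_set()

  five <- causal_haplotype(map, c(END3 = "BY", FLO8 = "3S", MSS11 = "BY",
                                  TRR1 = "3S", MGA1 = "3S", SFL1 = "3S"),
                           ira2 = "D2933")
  expect_equal(classify_phenotype(five, map, rs), "ROUGH")

  six <- causal_haplotype(map, c(END3 = "3S", FLO8 = "3S", MGA1 = "BY",
                                 MSS11 = "BY", SFL1 = "BY", TRR1 = "BY"),
                          ira2 = "D2933")
  expect_equal(classify_phenotype(six, map, rs), "ROUGH")
  six$origins[causal_marker_index(map, "TRR1")] <- 1L  # TRR1 is free
  expect_equal(classify_phenotype(six, map, rs), "ROUGH")

  # without a capacitating perturbation everything is smooth
  wt <- causal_haplotype(map, c(END3 = "BY", FLO8 = "3S", MSS11 = "BY",
                                TRR1 = "3S"))
  expect_equal(classify_phenotype(wt, map, rs), "SMOOTH")

  # parental genomes stay smooth even with the lesion
  expect_equal(classify_phenotype(
    causal_haplotype(map, background = "BY", ira2 = "D2933"), map, rs),
    "SMOOTH")
  expect_equal(classify_phenotype(
    causal_haplotype(map, background = "3S", ira2 = "D2933"), map, rs),
    "SMOOTH")

  # SFL1 deletion reveals the same potentiating genotype
  sfl <- causal_haplotype(map, c(END3 = "BY", FLO8 = "3S", MSS11 = "BY",
                                 TRR1 = "3S"), sfl1 = "DELETED")
  expect_equal(classify_phenotype(sfl, map, rs), "ROUGH")
})

test_that("brute-force enumeration finds 6 and 4 rough combinations", {
  rs <- default_rule_set()
  ira2 <- enumerate_rough_genotypes(rs, "IRA2_D2933")
  expect_equal(nrow(ira2), 6L)  # 4 five-way (MGA1/SFL1 free) + 2 six-way
  sfl1 <- enumerate_rough_genotypes(rs, "SFL1_DELETED")
  expect_equal(nrow(sfl1), 4L)  # MGA1/SFL1 free under R_sfl1
  empty <- enumerate_rough_genotypes(trait_rule_set(), "IRA2_D2933")
  expect_equal(nrow(empty), 0L)
})

test_that("classifier and enumeration agree on all 64 combinations", {
  map <- sparse_map(200)
  rs <- default_rule_set()
  combos <- expand.grid(rep(list(c("BY", "3S")), 6),
                        stringsAsFactors = FALSE)
  names(combos) <- CRYPTIC6
  for (bg in c("IRA2_D2933", "SFL1_DELETED")) {
    rough_tab <- enumerate_rough_genotypes(rs, bg)
    key <- do.call(paste, rough_tab[CRYPTIC6])
    for (i in seq_len(64)) {
      h <- causal_haplotype(
        map, unlist(combos[i, ]),
        ira2 = if (bg == "IRA2_D2933") "D2933" else "WT",
        sfl1 = if (bg == "SFL1_DELETED") "DELETED" else "PRESENT")
      direct <- classify_phenotype(h, map, rs)
      expect_equal(direct != "SMOOTH",
                   do.call(paste, combos[i, ]) %in% key,
                   info = paste(bg, do.call(paste, combos[i, ])))
    }
  }
})

test_that("adding a required allele never broadens a rule", {
  base <- trait_rule_set(list(
    trait_rule("r", "IRA2_D2933", c(FLO8 = "3S", MSS11 = "BY"))))
  wider <- nrow(enumerate_rough_genotypes(base, "IRA2_D2933"))
  for (g in c("END3", "MGA1", "SFL1", "TRR1")) {
    for (a in c("BY", "3S")) {
      ra <- c(FLO8 = "3S", MSS11 = "BY")
      ra[[g]] <- a
      tightened <- trait_rule_set(list(trait_rule("r", "IRA2_D2933", ra)))
      expect_lte(nrow(enumerate_rough_genotypes(tightened, "IRA2_D2933")),
                 wider)
    }
  }
})

test_that("partial penetrance fires at the configured rate", {
  map <- sparse_map(200)
  rs <- trait_rule_set(list(
    trait_rule("weak", "IRA2_D2933",
               c(END3 = "BY", FLO8 = "3S", MSS11 = "BY", TRR1 = "3S"),
               penetrance = 0.3)))
  h <- causal_haplotype(map, c(END3 = "BY", FLO8 = "3S", MSS11 = "BY",
                               TRR1 = "3S"), ira2 = "D2933")
  set.seed(99)
  n <- 10000L
  geno <- matrix(rep(h$origins, each = n), nrow = n,
                 dimnames = list(NULL, map$id))
  phen <- bsacross:::classify_population(geno, rep("D2933", n),
                                         rep("PRESENT", n), map, rs)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(phen == "ROUGH") - 0.3), 3 * se)
})

test_that("first matching rule wins and order is irrelevant for disjoint rules", {
  map <- sparse_map(200)
  rs <- default_rule_set()
  rev_rs <- trait_rule_set(rev(rs$rules))
  combos <- expand.grid(rep(list(c("BY", "3S")), 6),
                        stringsAsFactors = FALSE)
  names(combos) <- CRYPTIC6
  for (i in seq_len(64)) {
    h <- causal_haplotype(map, unlist(combos[i, ]), ira2 = "D2933")
    expect_identical(classify_phenotype(h, map, rs),
                     classify_phenotype(h, map, rev_rs))
  }
})

test_that("rules naming unknown genes are rejected", {
  expect_error(trait_rule("bad", "NONE", c(FLO11 = "BY")), "unknown gene")
  map <- sparse_map(200)
  rs <- default_rule_set()
  attr(map, "causal_sites") <-
    attr(map, "causal_sites")[c("IRA2", "SFL1", "FLO8")]
  h <- haplotype(rep(0L, nrow(map)), ira2 = "D2933")
  expect_error(classify_phenotype(h, map, rs), "causal sites")
})

test_that("rule sets round-trip through YAML and JSON", {
  rs <- trait_rule_set(list(
    trait_rule("R_five", "IRA2_D2933",
               c(END3 = "BY", FLO8 = "3S", MSS11 = "BY", TRR1 = "3S")),
    trait_rule("weak_bumpy", "SFL1_DELETED", c(FLO8 = "3S"),
               phenotype = "BUMPY", penetrance = 0.25)))
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_rule_set(rs, path)
    back <- read_rule_set(path)
    expect_equal(back, rs)
  }
})
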