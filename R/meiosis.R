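# Meiosis under the Haldane (no crossover interference) model.
#
# Crossovers form a Poisson process on the genetic map, so the parental
# strand followed along a chromosome is a two-state Markov chain at the
# markers: between adjacent markers separated by d Morgans the strand
# switches with the Haldane recombination fraction r = (1 - exp(-2d)) / 2,
# and the strand at the first marker of each chromosome is chosen fairly.
# Sampling that chain marker-by-marker is distributionally identical to
# drawing a Poisson crossover count and placing the breakpoints uniformly
# on the genetic map, and vectorises over whole populations.

# Strand matrix for one chromosome: n_markers x n gametes, entries 0/1
# selecting parent A or B.
chrom_strands <- function(pos_cM, n) {
  mc <- length(pos_cM)
  r <- 0.5 * (1 - exp(-2 * diff(pos_cM) / 100))
  draws <- stats::rbinom(mc * n, 1L, prob = c(0.5, r))
  s <- matrix(draws, nrow = mc, ncol = n)
  if (mc > 1L) s <- apply(s, 2, cumsum) %% 2L
  matrix(s, nrow = mc, ncol = n)
}

# Simulate n gametes from a diploid with haploid parental genomes A and B.
# Returns list(geno = n x m integer matrix of origins, ira2, sfl1).
simulate_gametes <- function(parentA, parentB, map, n) {
  check_haplotype_map(parentA, map)
  check_haplotype_map(parentB, map)
  m <- nrow(map)
  geno <- matrix(NA_integer_, nrow = n, ncol = m,
                 dimnames = list(NULL, map$id))
  cs <- attr(map, "causal_sites")
  ira2_idx <- if ("IRA2" %in% names(cs)) match(cs[["IRA2"]], map$id) else NA
  sfl1_idx <- if ("SFL1" %in% names(cs)) match(cs[["SFL1"]], map$id) else NA
  ira2 <- rep(parentA$ira2, n)
  sfl1 <- rep(parentA$sfl1, n)
  if (n == 0L) return(list(geno = geno, ira2 = character(0), sfl1 = character(0)))

  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    strands <- chrom_strands(map$pos_cM[idx], n)
    a <- parentA$origins[idx]
    b <- parentB$origins[idx]
    geno[, idx] <- t((1L - strands) * a + strands * b)
    if (!is.na(ira2_idx) && ira2_idx %in% idx) {
      s <- strands[match(ira2_idx, idx), ]
      ira2 <- ifelse(s == 0L, parentA$ira2, parentB$ira2)
    }
    if (!is.na(sfl1_idx) && sfl1_idx %in% idx) {
      s <- strands[match(sfl1_idx, idx), ]
      sfl1 <- ifelse(s == 0L, parentA$sfl1, parentB$sfl1)
    }
  }
  list(geno = geno, ira2 = ira2, sfl1 = sfl1)
}

#' Simulate one meiotic gamete
#'
#' Draws a single recombinant haploid gamete from the diploid formed by two
#' parental haplotypes, under the Haldane no-interference crossover model
#' (crossover counts Poisson in the genetic length of each chromosome,
#' breakpoints uniform on the genetic map, fair random starting strand).
#' Engineered-site states (ira2-Delta2933, SFL1 deletion) are inherited
#' with the parental strand present at their gene's marker.
#'
#' @param parentA,parentB `haplotype` objects conforming to `map`.
#' @param map A `marker_map`.
#' @param seed Optional integer seed.
#' @return A `haplotype`.
#' @export
simulate_meiosis <- function(parentA, parentB, map, seed = NULL) {
  with_seed(seed, {
    g <- simulate_gametes(parentA, parentB, map, 1L)
    haplotype(g$geno[1L, ], ira2 = g$ira2[[1L]], sfl1 = g$sfl1[[1L]])
  })
}
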