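#' Define a cross scheme
#'
#' The five designs of the mapping system: the plain BYx3S cross
#' (`BYx3S_WT`), the BYx3S cross in which 3S carries the capacitating
#' ira2-Delta2933 lesion (`BYx3S_IRA2MUT`), the BYx3S cross in which both
#' parents have SFL1 deleted (`BYx3S_SFL1DEL`), and the two backcrosses of
#' a recombinant segregant to the wild-type BY or 3S parent
#' (`BACKCROSS_BY`, `BACKCROSS_3S`).
#'
#' @param name One of `"BYx3S_WT"`, `"BYx3S_IRA2MUT"`, `"BYx3S_SFL1DEL"`,
#'   `"BACKCROSS_BY"`, `"BACKCROSS_3S"`.
#' @param founder_segregant A `haplotype`; required for the two backcross
#'   schemes, ignored otherwise.
#' @return A `cross_scheme` object.
#' @export
cross_scheme <- function(name = c("BYx3S_WT", "BYx3S_IRA2MUT",
                                  "BYx3S_SFL1DEL", "BACKCROSS_BY",
                                  "BACKCROSS_3S"),
                         founder_segregant = NULL) {
  name <- match.arg(name)
  if (name %in% c("BACKCROSS_BY", "BACKCROSS_3S") &&
      is.null(founder_segregant))
    stopf("scheme %s requires a founder_segregant haplotype", name)
  structure(list(name = name, founder = founder_segregant),
            class = "cross_scheme")
}

# The two haploid parents of the diploid implied by a scheme.
cross_parents <- function(scheme, map) {
  switch(scheme$name,
    BYx3S_WT = list(A = pure_haplotype(map, "BY"),
                    B = pure_haplotype(map, "3S")),
    BYx3S_IRA2MUT = list(A = pure_haplotype(map, "BY"),
                         B = pure_haplotype(map, "3S", ira2 = "D2933")),
    BYx3S_SFL1DEL = list(A = pure_haplotype(map, "BY", sfl1 = "DELETED"),
                         B = pure_haplotype(map, "3S", sfl1 = "DELETED")),
    BACKCROSS_BY = list(A = scheme$founder, B = pure_haplotype(map, "BY")),
    BACKCROSS_3S = list(A = scheme$founder, B = pure_haplotype(map, "3S"))
  )
}

#' Simulate a population of segregants from a cross
#'
#' Sporulates the diploid implied by the scheme into `n` independent
#' haploid segregants and scores each one's colony-morphology phenotype
#' with the supplied penetrance rules.
#'
#' @param scheme A `cross_scheme`.
#' @param n Number of segregants (>= 0).
#' @param map A `marker_map`.
#' @param rules A `trait_rule_set` (default [default_rule_set()]).
#' @param seed Optional integer seed.
#' @return A `cross_pop`: list with `geno` (n x markers integer matrix,
#'   0 = BY, 1 = 3S), `ira2`, `sfl1`, `phenotype` (character vectors of
#'   length n) and `scheme` (the scheme name).
#' @export
simulate_cross <- function(scheme, n, map, rules = default_rule_set(),
                           seed = NULL) {
  if (n < 0) stopf("n must be >= 0")
  parents <- cross_parents(scheme, map)
  with_seed(seed, {
    g <- simulate_gametes(parents$A, parents$B, map, as.integer(n))
    phen <- classify_population(g$geno, g$ira2, g$sfl1, map, rules)
    structure(list(geno = g$geno, ira2 = g$ira2, sfl1 = g$sfl1,
                   phenotype = phen, scheme = scheme$name),
              class = "cross_pop")
  })
}

#' @export
print.cross_pop <- function(x, ...) {
  tab <- table(factor(x$phenotype, levels = c("SMOOTH", "BUMPY", "ROUGH")))
  cat(sprintf("cross_pop (%s): %d segregants x %d markers\n",
              x$scheme, nrow(x$geno), ncol(x$geno)))
  cat("phenotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of segregants in a population
#' @param pop A `cross_pop`.
#' @return Integer count.
#' @export
n_segregants <- function(pop) nrow(pop$geno)

# Subset a population by row index.
subset_pop <- function(pop, i) {
  structure(list(geno = pop$geno[i, , drop = FALSE], ira2 = pop$ira2[i],
                 sfl1 = pop$sfl1[i], phenotype = pop$phenotype[i],
                 scheme = pop$scheme),
            class = "cross_pop")
}

# Extract one segregant as a haplotype.
pop_haplotype <- function(pop, i) {
  haplotype(pop$geno[i, ], ira2 = pop$ira2[[i]], sfl1 = pop$sfl1[[i]])
}

#' Sample a rough founder segregant of a given interaction class
#'
#' Repeatedly sporulates the BYx3S ira2-Delta2933 diploid until a rough
#' segregant of the requested interaction class (five-way or six-way)
#' appears; used to seed the backcross pedigrees.
#'
#' @param map A `marker_map`.
#' @param class `"SIX_WAY"` or `"FIVE_WAY"`.
#' @param rules A `trait_rule_set`.
#' @param seed Optional integer seed.
#' @param batch,max_batches Internal sampling granularity and cap.
#' @return A `haplotype` classified rough with the requested class.
#' @export
sample_rough_founder <- function(map, class = c("SIX_WAY", "FIVE_WAY"),
                                 rules = default_rule_set(), seed = NULL,
                                 batch = 256L, max_batches = 40L) {
  class <- match.arg(class)
  scheme <- cross_scheme("BYx3S_IRA2MUT")
  with_seed(seed, {
    for (b in seq_len(max_batches)) {
      pop <- simulate_cross(scheme, batch, map, rules)
      cls <- classify_interactions(pop, map)
      hit <- which(pop$phenotype == "ROUGH" & cls == class)
      if (length(hit)) return(pop_haplotype(pop, hit[[1L]]))
    }
    stopf("no %s rough segregant found in %d draws", class,
          batch * max_batches)
  })
}
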