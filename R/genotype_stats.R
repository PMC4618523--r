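# Interaction-class bookkeeping and exact genotype-class expectations.

FIVE_WAY_GENOTYPE <- c(END3 = "BY", FLO8 = "3S", MSS11 = "BY", TRR1 = "3S")
SIX_WAY_GENOTYPE <- c(END3 = "3S", FLO8 = "3S", MGA1 = "BY", MSS11 = "BY",
                      SFL1 = "BY")

# class labels from a gene-origin matrix + ira2 state (vectorised)
interaction_class <- function(gene_mat, ira2) {
  n <- nrow(gene_mat)
  cls <- rep("OTHER", n)
  five <- ira2 == "D2933"
  for (g in names(FIVE_WAY_GENOTYPE))
    five <- five & gene_mat[, g] == FIVE_WAY_GENOTYPE[[g]]
  six <- ira2 == "D2933"
  for (g in names(SIX_WAY_GENOTYPE))
    six <- six & gene_mat[, g] == SIX_WAY_GENOTYPE[[g]]
  cls[five] <- "FIVE_WAY"
  cls[six] <- "SIX_WAY"  # disjoint from five (they differ at END3)
  cls
}

#' Classify a segregant into an interaction class
#'
#' `FIVE_WAY` for the END3-BY FLO8-3S MSS11-BY TRR1-3S genotype and
#' `SIX_WAY` for the END3-3S FLO8-3S MGA1-BY MSS11-BY SFL1-BY genotype
#' (both in the ira2-Delta2933 background); everything else `OTHER`.
#' The two classes are mutually exclusive: they differ at END3.
#'
#' @param h A `haplotype`.
#' @param map A `marker_map` resolving the six cryptic genes.
#' @return `"FIVE_WAY"`, `"SIX_WAY"` or `"OTHER"`.
#' @export
classify_interaction <- function(h, map) {
  og <- gene_origins(h, map, CRYPTIC_GENES)
  interaction_class(matrix(og, nrow = 1, dimnames = list(NULL, names(og))),
                    h$ira2)
}

#' Interaction classes of every segregant in a population
#'
#' @param pop A `cross_pop`.
#' @param map A `marker_map`.
#' @return Character vector of classes.
#' @export
classify_interactions <- function(pop, map) {
  if (nrow(pop$geno) == 0L) return(character(0))
  idx <- causal_marker_index(map, CRYPTIC_GENES)
  gene_mat <- matrix(origin_label(pop$geno[, idx, drop = FALSE]),
                     nrow = nrow(pop$geno),
                     dimnames = list(NULL, names(idx)))
  interaction_class(gene_mat, pop$ira2)
}

# Per-site transmission probabilities implied by a scheme: P(3S) at each
# cryptic gene, P(ira2 = D2933) and P(sfl1 = DELETED) in a random gamete.
scheme_transmission <- function(scheme, map = NULL) {
  half <- stats::setNames(rep(0.5, length(CRYPTIC_GENES)), CRYPTIC_GENES)
  switch(scheme$name,
    BYx3S_WT = list(p3s = half, p_mut = 0, p_del = 0),
    BYx3S_IRA2MUT = list(p3s = half, p_mut = 0.5, p_del = 0),
    BYx3S_SFL1DEL = list(p3s = half, p_mut = 0, p_del = 1),
    {
      if (is.null(map))
        stopf("backcross schemes need the map to locate the causal sites")
      f <- scheme$founder
      check_haplotype_map(f, map)
      idx <- causal_marker_index(map, CRYPTIC_GENES)
      fo <- f$origins[idx]
      rec <- if (scheme$name == "BACKCROSS_BY") 0L else 1L
      # segregating where founder differs from the recurrent parent
      p3s <- ifelse(fo == rec, as.numeric(rec), 0.5)
      list(p3s = stats::setNames(p3s, CRYPTIC_GENES),
           p_mut = if (f$ira2 == "D2933") 0.5 else 0,
           p_del = if (f$sfl1 == "DELETED") 0.5 else 0)
    }
  )
}

#' Exact genotype-class and phenotype expectations for a cross
#'
#' Enumerates all allele combinations at the six cryptic genes together
#' with the two engineered-site states, weighted by the per-site
#' transmission probabilities of the scheme (1/2 at segregating sites, 0
#' or 1 at fixed sites), and classifies every combination. No Monte
#' Carlo is involved.
#'
#' @param rules A `trait_rule_set`.
#' @param scheme A `cross_scheme`.
#' @param map A `marker_map`; only needed for backcross schemes (to locate
#'   the founder's causal alleles).
#' @return List with `p_class` (probabilities of FIVE_WAY / SIX_WAY /
#'   OTHER among all progeny), `p_class_given_rough` (same, conditional on
#'   the ROUGH phenotype), `p_rough`, and `five_to_six_ratio` =
#'   P(FIVE_WAY) / P(SIX_WAY).
#' @export
expected_class_probabilities <- function(rules, scheme, map = NULL) {
  tr <- scheme_transmission(scheme, map)
  grid <- expand.grid(c(rep(list(ORIGIN_LEVELS), length(CRYPTIC_GENES)),
                        list(ira2 = c("WT", "D2933"),
                             sfl1 = c("PRESENT", "DELETED"))),
                      stringsAsFactors = FALSE)
  names(grid)[seq_along(CRYPTIC_GENES)] <- CRYPTIC_GENES
  gene_mat <- as.matrix(grid[CRYPTIC_GENES])

  w <- rep(1, nrow(grid))
  for (g in CRYPTIC_GENES) {
    p <- tr$p3s[[g]]
    w <- w * ifelse(grid[[g]] == "3S", p, 1 - p)
  }
  w <- w * ifelse(grid$ira2 == "D2933", tr$p_mut, 1 - tr$p_mut)
  w <- w * ifelse(grid$sfl1 == "DELETED", tr$p_del, 1 - tr$p_del)

  cls <- interaction_class(gene_mat, grid$ira2)
  # P(rough | combination): penetrance of the first matching rule
  p_rough <- numeric(nrow(grid))
  undecided <- rep(TRUE, nrow(grid))
  for (r in rules$rules) {
    ok <- undecided & background_matches(r$background, grid$ira2, grid$sfl1)
    for (g in names(r$required_alleles))
      ok <- ok & gene_mat[, g] == r$required_alleles[[g]]
    if (r$phenotype == "ROUGH") p_rough[ok] <- r$penetrance
    undecided <- undecided & !ok
  }

  p_class <- vapply(c("FIVE_WAY", "SIX_WAY", "OTHER"),
                    function(k) sum(w[cls == k]), 0)
  pr <- sum(w * p_rough)
  p_given <- if (pr > 0) {
    vapply(c("FIVE_WAY", "SIX_WAY", "OTHER"),
           function(k) sum(w[cls == k] * p_rough[cls == k]) / pr, 0)
  } else {
    stats::setNames(rep(NA_real_, 3), c("FIVE_WAY", "SIX_WAY", "OTHER"))
  }
  ratio <- if (p_class[["SIX_WAY"]] > 0)
    p_class[["FIVE_WAY"]] / p_class[["SIX_WAY"]] else Inf
  list(p_class = p_class, p_class_given_rough = p_given,
       p_rough = pr, five_to_six_ratio = ratio)
}

#' Tabulate phenotypes and interaction classes of a population
#'
#' @param pop A `cross_pop`.
#' @param map A `marker_map`.
#' @return List with `counts` (phenotype x class contingency table as a
#'   data frame), `phenotype_fractions` and `class_fractions_given_rough`.
#' @export
summarize_population <- function(pop, map) {
  cls <- classify_interactions(pop, map)
  phen <- factor(pop$phenotype, levels = c("SMOOTH", "BUMPY", "ROUGH"))
  clf <- factor(cls, levels = c("FIVE_WAY", "SIX_WAY", "OTHER"))
  tab <- as.data.frame(table(phenotype = phen, class = clf))
  n <- length(cls)
  rough <- phen == "ROUGH"
  list(
    counts = tab,
    n = n,
    phenotype_fractions = if (n) prop.table(table(phen)) else table(phen),
    class_fractions_given_rough =
      if (any(rough)) prop.table(table(clf[rough])) else table(clf)
  )
}
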