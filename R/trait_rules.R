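#' Define a penetrance rule mapping a genotype to a colony phenotype
#'
#' A rule fires for a haplotype when its genetic background requirement is
#' met (the ira2-Delta2933 lesion or the SFL1 deletion, or none) and every
#' required cryptic-gene allele matches; a firing rule assigns its
#' phenotype with probability `penetrance`.
#'
#' @param name Unique rule name.
#' @param background `"IRA2_D2933"`, `"SFL1_DELETED"` or `"NONE"`.
#' @param required_alleles Named character vector gene -> `"BY"`/`"3S"`
#'   over the cryptic genes (END3, FLO8, MGA1, MSS11, SFL1, TRR1).
#' @param phenotype `"ROUGH"` or `"BUMPY"`.
#' @param penetrance Probability in [0, 1] (default 1).
#' @return A `trait_rule`.
#' @export
trait_rule <- function(name, background = c("NONE", "IRA2_D2933",
                                            "SFL1_DELETED"),
                       required_alleles, phenotype = c("ROUGH", "BUMPY"),
                       penetrance = 1) {
  background <- match.arg(background)
  phenotype <- match.arg(phenotype)
  if (penetrance < 0 || penetrance > 1)
    stopf("penetrance must be in [0, 1]")
  required_alleles <- unlist(required_alleles)
  if (!all(required_alleles %in% ORIGIN_LEVELS))
    stopf("required alleles must be 'BY' or '3S'")
  bad <- setdiff(names(required_alleles), CRYPTIC_GENES)
  if (length(bad))
    stopf("rule '%s' references unknown gene(s): %s", name,
          paste(bad, collapse = ", "))
  structure(list(name = name, background = background,
                 required_alleles = required_alleles,
                 phenotype = phenotype, penetrance = penetrance),
            class = "trait_rule")
}

#' Bundle trait rules into an ordered rule set
#'
#' Rules are evaluated in order and the first match fires; segregants
#' matched by no rule take the default phenotype (SMOOTH).
#'
#' @param rules List of `trait_rule` objects (names must be unique).
#' @param default_phenotype Phenotype of unmatched segregants.
#' @return A `trait_rule_set`.
#' @export
trait_rule_set <- function(rules = list(), default_phenotype = "SMOOTH") {
  nm <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("rule names must be unique")
  structure(list(rules = rules, default_phenotype = default_phenotype),
            class = "trait_rule_set")
}

#' The rough-morphology rule set of the BYx3S system
#'
#' Three fully penetrant ROUGH rules: the five-way interaction
#' (END3-BY, FLO8-3S, MSS11-BY, TRR1-3S in the ira2-Delta2933 background),
#' the six-way interaction (END3-3S, FLO8-3S, MGA1-BY, MSS11-BY, SFL1-BY
#' in the ira2-Delta2933 background), and the sfl1-deletion rule
#' (END3-BY, FLO8-3S, MSS11-BY, TRR1-3S in the SFL1-deleted background).
#' Everything else is SMOOTH.
#'
#' @return A `trait_rule_set` with three rules.
#' @export
default_rule_set <- function() {
  trait_rule_set(list(
    trait_rule("R_five", "IRA2_D2933",
               c(END3 = "BY", FLO8 = "3S", MSS11 = "BY", TRR1 = "3S")),
    trait_rule("R_six", "IRA2_D2933",
               c(END3 = "3S", FLO8 = "3S", MGA1 = "BY", MSS11 = "BY",
                 SFL1 = "BY")),
    trait_rule("R_sfl1", "SFL1_DELETED",
               c(END3 = "BY", FLO8 = "3S", MSS11 = "BY", TRR1 = "3S"))
  ))
}

#' @export
print.trait_rule_set <- function(x, ...) {
  cat(sprintf("trait_rule_set: %d rule(s), default %s\n",
              length(x$rules), x$default_phenotype))
  for (r in x$rules) {
    cat(sprintf("  %s [%s, pen=%g] %s if %s\n", r$name, r$background,
                r$penetrance, r$phenotype,
                paste(sprintf("%s=%s", names(r$required_alleles),
                              r$required_alleles), collapse = " ")))
  }
  invisible(x)
}

background_matches <- function(background, ira2, sfl1) {
  switch(background,
         NONE = rep(TRUE, length(ira2)),
         IRA2_D2933 = ira2 == "D2933",
         SFL1_DELETED = sfl1 == "DELETED")
}

# Vectorised rule evaluation over a gene-origin matrix (n x genes,
# character "BY"/"3S", columns named by gene) plus engineered states.
# Returns the phenotype vector; first matching rule wins and fires with
# probability penetrance, otherwise the default phenotype applies.
match_rules <- function(gene_mat, ira2, sfl1, rules) {
  n <- nrow(gene_mat)
  phen <- rep(rules$default_phenotype, n)
  undecided <- rep(TRUE, n)
  for (r in rules$rules) {
    bad <- setdiff(names(r$required_alleles), colnames(gene_mat))
    if (length(bad))
      stopf("rule '%s' references gene(s) absent from the map: %s",
            r$name, paste(bad, collapse = ", "))
    ok <- undecided & background_matches(r$background, ira2, sfl1)
    for (g in names(r$required_alleles)) {
      ok <- ok & gene_mat[, g] == r$required_alleles[[g]]
    }
    if (any(ok)) {
      fire <- ok
      if (r$penetrance < 1) {
        fire[ok] <- stats::runif(sum(ok)) < r$penetrance
      }
      phen[fire] <- r$phenotype
      # a matched rule consumes the segregant whether or not it fired
      undecided <- undecided & !ok
    }
  }
  phen
}

# Phenotypes for a whole simulated population.
classify_population <- function(geno, ira2, sfl1, map, rules) {
  if (nrow(geno) == 0L) return(character(0))
  genes <- union(unlist(lapply(rules$rules,
                               function(r) names(r$required_alleles))),
                 character(0))
  if (!length(genes)) return(rep(rules$default_phenotype, nrow(geno)))
  idx <- causal_marker_index(map, genes)
  gene_mat <- matrix(origin_label(geno[, idx, drop = FALSE]),
                     nrow = nrow(geno),
                     dimnames = list(NULL, names(idx)))
  match_rules(gene_mat, ira2, sfl1, rules)
}

#' Classify the colony phenotype of a haplotype
#'
#' Applies the penetrance rules to one segregant: the first rule whose
#' background and required alleles all match fires with probability equal
#' to its penetrance; otherwise the default phenotype (SMOOTH) is
#' returned. Deterministic whenever all penetrances are 0 or 1.
#'
#' @param h A `haplotype`.
#' @param map A `marker_map` resolving the genes named by the rules.
#' @param rules A `trait_rule_set`.
#' @param seed Optional integer seed (only relevant for penetrances
#'   strictly between 0 and 1).
#' @return `"SMOOTH"`, `"BUMPY"` or `"ROUGH"`.
#' @export
classify_phenotype <- function(h, map, rules = default_rule_set(),
                               seed = NULL) {
  check_haplotype_map(h, map)
  with_seed(seed,
    classify_population(matrix(h$origins, nrow = 1,
                               dimnames = list(NULL, map$id)),
                        h$ira2, h$sfl1, map, rules))
}

#' Enumerate the allele combinations scored non-smooth
#'
#' Brute-force oracle over all 2^6 = 64 allele combinations at the six
#' cryptic genes in a fixed engineered background, with penetrance treated
#' as 1 (a combination counts if any rule matches it).
#'
#' @param rules A `trait_rule_set`.
#' @param background `"IRA2_D2933"` or `"SFL1_DELETED"`.
#' @return Data frame with one row per non-smooth combination: the six
#'   gene columns plus `phenotype`.
#' @export
enumerate_rough_genotypes <- function(rules,
                                      background = c("IRA2_D2933",
                                                     "SFL1_DELETED")) {
  background <- match.arg(background)
  combos <- expand.grid(rep(list(ORIGIN_LEVELS), length(CRYPTIC_GENES)),
                        stringsAsFactors = FALSE)
  names(combos) <- CRYPTIC_GENES
  gene_mat <- as.matrix(combos)
  ira2 <- rep(if (background == "IRA2_D2933") "D2933" else "WT", 64L)
  sfl1 <- rep(if (background == "SFL1_DELETED") "DELETED" else "PRESENT", 64L)
  rules_pen1 <- trait_rule_set(lapply(rules$rules, function(r) {
    if (r$penetrance > 0) r$penetrance <- 1
    r
  }), default_phenotype = rules$default_phenotype)
  phen <- match_rules(gene_mat, ira2, sfl1, rules_pen1)
  out <- combos[phen != "SMOOTH", , drop = FALSE]
  out$phenotype <- phen[phen != "SMOOTH"]
  rownames(out) <- NULL
  out
}

#' Write a rule set to YAML or JSON
#'
#' @param rules A `trait_rule_set`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_rule_set <- function(rules, path) {
  obj <- list(
    default_phenotype = rules$default_phenotype,
    rules = lapply(rules$rules, function(r) {
      list(name = r$name, background = r$background,
           required_alleles = as.list(r$required_alleles),
           phenotype = r$phenotype, penetrance = r$penetrance)
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a rule set from YAML or JSON
#'
#' @param path File written by [write_rule_set()] (or hand-authored in the
#'   same layout).
#' @return A `trait_rule_set`.
#' @export
read_rule_set <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  trait_rule_set(
    lapply(obj$rules, function(r) {
      trait_rule(r$name, r$background, unlist(r$required_alleles),
                 r$phenotype, r$penetrance %||% 1)
    }),
    default_phenotype = obj$default_phenotype %||% "SMOOTH"
  )
}
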