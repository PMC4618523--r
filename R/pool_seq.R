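#' Pooled-sequencing simulation parameters
#'
#' @param mean_coverage Mean per-site depth (> 0). The study pools were
#'   sequenced to 73x (BY backcross) and 122x (3S backcross).
#' @param error_rate Per-read miscall probability in [0, 1); a miscall
#'   lands uniformly on the three other bases, so cross-contamination
#'   between the BY and 3S alleles occurs at `error_rate / 3`.
#' @param seed Optional integer seed used by [simulate_pool_counts()].
#' @return A `pool_seq_params` object.
#' @export
pool_seq_params <- function(mean_coverage, error_rate = 0.005, seed = NULL) {
  if (mean_coverage <= 0) stopf("mean_coverage must be > 0")
  if (error_rate < 0 || error_rate >= 1)
    stopf("error_rate must be in [0, 1)")
  structure(list(mean_coverage = mean_coverage, error_rate = error_rate,
                 seed = seed),
            class = "pool_seq_params")
}

#' Select segregants by phenotype and causal-gene alleles
#'
#' Emulates the study's picking of rough colonies followed by
#' restriction-marker genotyping: retains segregants with the requested
#' phenotype and, optionally, required origins at named causal genes
#' (e.g. `c(END3 = "3S")` for the BY-backcross pools).
#'
#' @param pop A `cross_pop`.
#' @param map A `marker_map`.
#' @param phenotype Phenotype to keep (default `"ROUGH"`).
#' @param allele_filter Optional named character vector gene -> origin.
#' @return A `cross_pop` containing the selected segregants.
#' @export
select_segregants <- function(pop, map, phenotype = "ROUGH",
                              allele_filter = NULL) {
  keep <- pop$phenotype == phenotype
  if (length(allele_filter)) {
    idx <- causal_marker_index(map, names(allele_filter))
    for (g in names(allele_filter)) {
      keep <- keep & pop$geno[, idx[[g]]] == origin_code(allele_filter[[g]])
    }
  }
  subset_pop(pop, which(keep))
}

#' True pooled allele frequencies of a subpopulation
#'
#' Equimolar pooling of the selected haploids: the 3S-allele frequency at
#' a marker is the fraction of pooled segregants with 3S origin there.
#' The engineered sites report their mutant-state fractions separately.
#'
#' @param pop A nonempty `cross_pop` (the pool).
#' @param map A `marker_map`.
#' @return List with `freq` (named numeric vector, one entry per marker)
#'   and `engineered` (fractions `IRA2_D2933` and `SFL1_DELETED`).
#' @export
pool_true_frequencies <- function(pop, map) {
  if (nrow(pop$geno) == 0L) stopf("cannot pool an empty selection")
  if (ncol(pop$geno) != nrow(map)) stopf("population does not conform to map")
  list(freq = colMeans(pop$geno),
       engineered = c(IRA2_D2933 = mean(pop$ira2 == "D2933"),
                      SFL1_DELETED = mean(pop$sfl1 == "DELETED")))
}

# Sequence one biallelic site class: depths Poisson(mean_coverage), each
# read reports its true allele with probability 1 - e, else one of the
# three other bases uniformly. Returns counts for allele1 ("by"),
# allele2 ("3s") and other; conservation holds exactly.
sequence_biallelic <- function(freq, mean_coverage, error_rate) {
  m <- length(freq)
  depth <- stats::rpois(m, mean_coverage)
  n2_true <- stats::rbinom(m, depth, freq)   # reads from the 3S allele
  n1_true <- depth - n2_true
  e <- error_rate
  keep2 <- stats::rbinom(m, n2_true, 1 - e)
  mis2_to1 <- stats::rbinom(m, n2_true - keep2, 1 / 3)
  keep1 <- stats::rbinom(m, n1_true, 1 - e)
  mis1_to2 <- stats::rbinom(m, n1_true - keep1, 1 / 3)
  count_3s <- keep2 + mis1_to2
  count_by <- keep1 + mis2_to1
  data.frame(depth = depth, count_by = count_by, count_3s = count_3s,
             count_other = depth - count_by - count_3s)
}

#' Simulate pooled-sequencing allele counts
#'
#' Per-marker depths are Poisson with the configured mean coverage; each
#' read reports the true pooled allele with probability
#' `1 - error_rate` and one of the three other bases uniformly otherwise,
#' so BY/3S cross-contamination occurs at `error_rate / 3` and the
#' remaining miscalls land in `count_other`.
#'
#' @param freqs Numeric vector of true 3S-allele frequencies in [0, 1]
#'   (one per marker), or the list returned by [pool_true_frequencies()].
#' @param params A `pool_seq_params`.
#' @param map Optional `marker_map` used to annotate the output rows.
#' @return An `allele_counts` data frame with columns `id`, `chrom`,
#'   `pos_bp`, `depth`, `count_by`, `count_3s`, `count_other`, and — when
#'   `freqs` carries engineered-site fractions — an `engineered` attribute
#'   (data frame with `site`, `depth`, `count_mut`, `count_wt`,
#'   `mut_fraction`).
#' @export
simulate_pool_counts <- function(freqs, params, map = NULL) {
  engineered_freq <- NULL
  if (is.list(freqs) && !is.data.frame(freqs)) {
    engineered_freq <- freqs$engineered
    freqs <- freqs$freq
  }
  if (any(freqs < 0 | freqs > 1)) stopf("frequencies must lie in [0, 1]")
  with_seed(params$seed, {
    counts <- sequence_biallelic(freqs, params$mean_coverage,
                                 params$error_rate)
    if (!is.null(map)) {
      out <- data.frame(id = map$id, chrom = map$chrom, pos_bp = map$pos_bp,
                        counts, stringsAsFactors = FALSE)
    } else {
      ids <- names(freqs) %||% sprintf("m%d", seq_along(freqs))
      out <- data.frame(id = ids, chrom = NA_character_,
                        pos_bp = NA_integer_, counts,
                        stringsAsFactors = FALSE)
    }
    if (!is.null(engineered_freq)) {
      es <- sequence_biallelic(engineered_freq, params$mean_coverage,
                               params$error_rate)
      attr(out, "engineered") <- data.frame(
        site = names(engineered_freq),
        depth = es$depth, count_mut = es$count_3s, count_wt = es$count_by,
        mut_fraction = ifelse(es$count_3s + es$count_by > 0,
                              es$count_3s / (es$count_3s + es$count_by),
                              NA_real_),
        stringsAsFactors = FALSE
      )
    }
    class(out) <- c("allele_counts", "data.frame")
    out
  })
}

validate_allele_counts <- function(tab) {
  need <- c("id", "chrom", "pos_bp", "depth", "count_by", "count_3s",
            "count_other")
  if (!all(need %in% names(tab))) stopf("allele-count table missing columns")
  if (any(tab$count_by + tab$count_3s + tab$count_other != tab$depth))
    stopf("allele counts do not sum to depth at every marker")
  invisible(tab)
}

#' Select, pool and sequence one pool in a single call
#'
#' Convenience wrapper: phenotype/allele selection, equimolar pooling and
#' pooled-sequencing count simulation.
#'
#' @inheritParams select_segregants
#' @param params A `pool_seq_params`.
#' @return An `allele_counts` table (see [simulate_pool_counts()]); the
#'   number of pooled segregants is recorded in attribute `pool_size`.
#' @export
simulate_pool <- function(pop, map, params, phenotype = "ROUGH",
                          allele_filter = NULL) {
  sel <- select_segregants(pop, map, phenotype, allele_filter)
  freqs <- pool_true_frequencies(sel, map)
  out <- simulate_pool_counts(freqs, params, map)
  attr(out, "pool_size") <- n_segregants(sel)
  out
}
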