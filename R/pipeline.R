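# End-to-end drivers replaying the study's mapping designs in silico.

# Simulate batches of a cross until `target` segregants passing the
# phenotype/allele filter have been collected (or `max_batches` spent);
# returns the selected subpopulation, truncated to exactly `target`.
collect_selected <- function(scheme, map, rules, target,
                             phenotype = "ROUGH", allele_filter = NULL,
                             batch = 512L, max_batches = 60L) {
  got <- NULL
  for (b in seq_len(max_batches)) {
    pop <- simulate_cross(scheme, batch, map, rules)
    sel <- select_segregants(pop, map, phenotype, allele_filter)
    got <- if (is.null(got)) sel else
      structure(list(geno = rbind(got$geno, sel$geno),
                     ira2 = c(got$ira2, sel$ira2),
                     sfl1 = c(got$sfl1, sel$sfl1),
                     phenotype = c(got$phenotype, sel$phenotype),
                     scheme = pop$scheme),
                class = "cross_pop")
    if (n_segregants(got) >= target) return(subset_pop(got, seq_len(target)))
  }
  stopf("collected only %d of %d segregants; raise max_batches",
        n_segregants(got), target)
}

#' Replay a reciprocal-backcross bulk segregant mapping experiment
#'
#' Samples a rough founder of the requested interaction class from the
#' BYx3S ira2-Delta2933 cross, backcrosses it to wild-type BY and 3S,
#' screens rough segregants (genotyping END3 as in the study, so that the
#' BY-backcross pool carries only the informative END3 allele), pools
#' them equimolarly, simulates pooled sequencing, and maps both panels
#' with the sliding-window fixation caller.
#'
#' @param map A `marker_map` (typically [scaled_marker_map()]).
#' @param class `"SIX_WAY"` or `"FIVE_WAY"` (which interaction the
#'   founder carries).
#' @param pool_sizes Named or unnamed pair: rough segregants pooled from
#'   the BY and 3S backcross (defaults 63 and 88, the study's pools).
#' @param coverage Mean sequencing depth per pool (one value or a pair;
#'   the study obtained 73x and 122x).
#' @param error_rate Per-read miscall probability.
#' @param rules A `trait_rule_set`.
#' @param params A `mapping_params`.
#' @param seed Optional integer seed for the whole experiment.
#' @return List: `founder` (haplotype), `pool_by` / `pool_3s`
#'   (`allele_counts`), `loci` (merged `locus_calls` report).
#' @export
backcross_mapping_experiment <- function(map, class = "SIX_WAY",
                                         pool_sizes = c(by = 63L, s3 = 88L),
                                         coverage = 100,
                                         error_rate = 0.005,
                                         rules = default_rule_set(),
                                         params = mapping_params(),
                                         seed = NULL) {
  if (length(coverage) == 1L) coverage <- rep(coverage, 2L)
  with_seed(seed, {
    founder <- sample_rough_founder(map, class, rules)
    # the END3 allele required by the founder's interaction class
    end3 <- if (class == "SIX_WAY") "3S" else "BY"

    sel_by <- collect_selected(cross_scheme("BACKCROSS_BY", founder), map,
                               rules, pool_sizes[[1]],
                               allele_filter = c(END3 = end3))
    sel_3s <- collect_selected(cross_scheme("BACKCROSS_3S", founder), map,
                               rules, pool_sizes[[2]],
                               allele_filter = c(END3 = end3))

    pool_by <- simulate_pool_counts(pool_true_frequencies(sel_by, map),
                                    pool_seq_params(coverage[[1]],
                                                    error_rate), map)
    pool_3s <- simulate_pool_counts(pool_true_frequencies(sel_3s, map),
                                    pool_seq_params(coverage[[2]],
                                                    error_rate), map)
    loci <- map_backcross_pools(pool_by, pool_3s, map, params,
                                founder = founder)
    list(founder = founder, pool_by = pool_by, pool_3s = pool_3s,
         loci = loci)
  })
}

#' Replay the BYx3S sfl1-deletion cross mapping
#'
#' Simulates the cross of SFL1-deleted BY and 3S parents, selects rough
#' segregants, pools and sequences them, and calls fixed loci; all
#' markers segregate in this F1 design so no mask is needed.
#'
#' @param map A `marker_map`.
#' @param n_rough Number of rough segregants to pool (default 44, the
#'   study's cohort).
#' @param coverage Mean sequencing depth.
#' @param error_rate Per-read miscall probability.
#' @param rules A `trait_rule_set`.
#' @param params A `mapping_params`.
#' @param seed Optional integer seed.
#' @return List: `pool` (the selected `cross_pop`), `counts`
#'   (`allele_counts`), `loci` (`locus_calls`).
#' @export
sfl1_cross_experiment <- function(map, n_rough = 44L, coverage = 100,
                                  error_rate = 0.005,
                                  rules = default_rule_set(),
                                  params = mapping_params(),
                                  seed = NULL) {
  with_seed(seed, {
    sel <- collect_selected(cross_scheme("BYx3S_SFL1DEL"), map, rules,
                            n_rough)
    counts <- simulate_pool_counts(pool_true_frequencies(sel, map),
                                   pool_seq_params(coverage, error_rate),
                                   map)
    track <- frequencies_from_counts(counts, params)
    win <- sliding_windows(track, map, params)
    loci <- call_fixed_loci(win, map, params, attr(counts, "engineered"))
    list(pool = sel, counts = counts, loci = loci)
  })
}
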