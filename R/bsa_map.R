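#' Locus-calling parameters
#'
#' @param window_snps Number of consecutive informative SNPs per sliding
#'   window (default 10, as in the study design).
#' @param fix_threshold Windowed allele-frequency threshold for calling a
#'   locus fixed (default 0.95; comparison is inclusive, "95% or
#'   higher"). Must satisfy 0.5 < threshold <= 1.
#' @param min_depth Minimum informative depth (`count_by + count_3s`) for
#'   a marker to contribute a frequency (default 1).
#' @param max_window_cm Maximum genetic span of a window in centimorgans
#'   (default 10). Windows of consecutive informative markers that
#'   straddle a long uninformative stretch (for instance a founder block
#'   monomorphic in a backcross) average markers tens of cM apart, where
#'   the expected pooled frequency around a selected site, 1 - r(d), is
#'   already below ~0.91; such windows cannot support a 95% call and are
#'   discarded. Set to `Inf` to disable.
#' @param merge_gap_cm Calls on the same chromosome separated by at most
#'   this genetic distance are reported as one locus (default 25 cM). A
#'   selected locus's above-threshold shoulder extends ~5 cM (where
#'   r = 0.05) and correlated sampling noise in pools of tens of
#'   segregants pushes detached qualifying windows 10-20 cM further,
#'   while distinct causal loci on one chromosome sit many tens of cM
#'   apart. Set to 0 to merge only overlapping calls.
#' @return A `mapping_params` object.
#' @export
mapping_params <- function(window_snps = 10L, fix_threshold = 0.95,
                           min_depth = 1L, max_window_cm = 10,
                           merge_gap_cm = 25) {
  if (window_snps < 1) stopf("window_snps must be >= 1")
  if (fix_threshold <= 0.5 || fix_threshold > 1)
    stopf("fix_threshold must be in (0.5, 1]")
  if (min_depth < 0) stopf("min_depth must be >= 0")
  if (max_window_cm <= 0) stopf("max_window_cm must be > 0")
  if (merge_gap_cm < 0) stopf("merge_gap_cm must be >= 0")
  structure(list(window_snps = as.integer(window_snps),
                 fix_threshold = fix_threshold,
                 min_depth = as.integer(min_depth),
                 max_window_cm = max_window_cm,
                 merge_gap_cm = merge_gap_cm),
            class = "mapping_params")
}

#' Per-marker 3S-allele frequencies from pooled counts
#'
#' `f = count_3s / (count_by + count_3s)`; reads matching neither
#' parental allele are excluded from the denominator. Markers with
#' informative depth below `min_depth`, and optionally markers flagged
#' uninformative (monomorphic in the cross), become missing.
#'
#' @param table An `allele_counts` data frame.
#' @param params A `mapping_params`.
#' @param informative Optional logical vector (one per marker); markers
#'   with `FALSE` are set to missing. In a backcross, markers where the
#'   founder matches the recurrent parent do not segregate and must be
#'   masked; see [segregating_markers()].
#' @return A `freq_track` data frame: `id`, `chrom`, `pos_bp`, `freq`
#'   (NA where missing).
#' @export
frequencies_from_counts <- function(table, params = mapping_params(),
                                    informative = NULL) {
  validate_allele_counts(table)
  denom <- table$count_by + table$count_3s
  f <- ifelse(denom >= max(1L, params$min_depth), table$count_3s / denom,
              NA_real_)
  if (!is.null(informative)) {
    if (length(informative) != nrow(table))
      stopf("informative mask length does not match the table")
    f[!informative] <- NA_real_
  }
  structure(data.frame(id = table$id, chrom = table$chrom,
                       pos_bp = table$pos_bp, freq = f,
                       stringsAsFactors = FALSE),
            class = c("freq_track", "data.frame"))
}

#' Markers segregating in a backcross
#'
#' A backcross marker segregates only where the founder segregant carries
#' the allele opposite the recurrent parent.
#'
#' @param founder The founder `haplotype`.
#' @param recurrent `"BY"` or `"3S"` (the recurrent parent).
#' @param map A `marker_map`.
#' @return Logical vector, `TRUE` at segregating markers.
#' @export
segregating_markers <- function(founder, recurrent = c("BY", "3S"), map) {
  recurrent <- match.arg(recurrent)
  check_haplotype_map(founder, map)
  founder$origins != origin_code(recurrent)
}

#' Sliding-window mean allele frequencies
#'
#' Windows contain `window_snps` consecutive non-missing markers on the
#' same chromosome and advance one marker at a time; the window statistic
#' is the arithmetic mean frequency. Chromosomes with fewer informative
#' markers than the window size yield no windows. When the map is
#' supplied, each window also records its genetic span and windows wider
#' than `max_window_cm` are discarded (see [mapping_params()]).
#'
#' @param track A `freq_track` from [frequencies_from_counts()].
#' @param map Optional `marker_map` supplying genetic positions.
#' @param params A `mapping_params`.
#' @return A `window_track` data frame: `chrom`, `start_bp`, `end_bp`
#'   (positions of the first and last member marker), `start_cm`,
#'   `end_cm` (NA without a map), `mean_freq`, `n_snps`.
#' @export
sliding_windows <- function(track, map = NULL, params = mapping_params()) {
  w <- params$window_snps
  cm <- if (!is.null(map)) {
    stats::setNames(map$pos_cM, map$id)[track$id]
  } else {
    rep(NA_real_, nrow(track))
  }
  out <- lapply(unique(track$chrom), function(ch) {
    keep <- track$chrom == ch & !is.na(track$freq)
    rows <- track[keep, , drop = FALSE]
    k <- nrow(rows)
    if (k < w) return(NULL)
    rcm <- cm[keep]
    cs <- cumsum(c(0, rows$freq))
    i <- seq_len(k - w + 1L)
    data.frame(chrom = ch,
               start_bp = rows$pos_bp[i],
               end_bp = rows$pos_bp[i + w - 1L],
               start_cm = rcm[i],
               end_cm = rcm[i + w - 1L],
               mean_freq = (cs[i + w] - cs[i]) / w,
               n_snps = w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out) %||%
    data.frame(chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), start_cm = numeric(0),
               end_cm = numeric(0), mean_freq = numeric(0),
               n_snps = integer(0))
  if (!is.null(map) && is.finite(params$max_window_cm) && nrow(out)) {
    out <- out[out$end_cm - out$start_cm <= params$max_window_cm, ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("window_track", "data.frame"))
}

# Qualification of windows toward a fixed allele.
window_qualifies <- function(windows, allele, thr) {
  if (allele == "3S") windows$mean_freq >= thr
  else windows$mean_freq <= 1 - thr
}

#' Call fixed loci from windowed allele frequencies
#'
#' Windows with mean 3S frequency at or above the fixation threshold
#' support 3S-fixed loci; windows at or below one minus the threshold
#' support BY-fixed loci. A locus is the maximal region covered by
#' qualifying windows closer than `merge_gap_cm` to each other:
#' consecutive windows share all but one marker, so ragged threshold
#' crossings at a locus boundary — and detached shoulder windows a few cM
#' out — belong to the same selected region, while loci farther apart
#' than the merge gap stay distinct. A call whose interval covers an
#' engineered-site marker whose mutant fraction also reaches the
#' threshold is relabelled MUTANT (the grey-bar loci of the study's
#' frequency plots).
#'
#' @param windows A `window_track` from [sliding_windows()].
#' @param map A `marker_map` (used for genetic distances and to annotate
#'   causal genes inside each interval).
#' @param params A `mapping_params`.
#' @param engineered Optional engineered-site table (the `engineered`
#'   attribute of [simulate_pool_counts()] output, or any data frame with
#'   `site` and `mut_fraction`).
#' @return A `locus_calls` data frame: `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive), `start_cm`, `end_cm`, `fixed_allele` (`"BY"`,
#'   `"3S"` or `"MUTANT"`), `mean_freq` (frequency of the fixed allele
#'   averaged over the qualifying windows), `n_windows`, `causal_genes`
#'   (comma-separated causal sites inside the interval, `""` if none).
#' @export
call_fixed_loci <- function(windows, map, params = mapping_params(),
                            engineered = NULL) {
  thr <- params$fix_threshold
  calls <- list()
  for (ch in unique(windows$chrom)) {
    wch <- windows[windows$chrom == ch, , drop = FALSE]
    for (allele in c("3S", "BY")) {
      q <- wch[window_qualifies(wch, allele, thr), , drop = FALSE]
      if (!nrow(q)) next
      # cluster qualifying windows: overlapping spans, or gaps below the
      # merge radius, are one locus
      gap_ok <- if (all(is.finite(q$start_cm))) {
        q$start_cm[-1L] - cummax(q$end_cm)[-nrow(q)] > params$merge_gap_cm
      } else {
        q$start_bp[-1L] > cummax(q$end_bp)[-nrow(q)]
      }
      grp <- cumsum(c(1L, as.integer(gap_ok)))
      for (j in unique(grp)) {
        run <- q[grp == j, , drop = FALSE]
        f <- mean(run$mean_freq)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch,
          start_bp = min(run$start_bp),
          end_bp = max(run$end_bp),
          start_cm = min(run$start_cm),
          end_cm = max(run$end_cm),
          fixed_allele = allele,
          mean_freq = if (allele == "3S") f else 1 - f,
          n_windows = nrow(run),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, calls) %||% empty_locus_calls()
  out <- out[order(match(out$chrom, CHROMOSOMES), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$causal_genes <- causal_genes_in_intervals(out, map)
  out <- relabel_mutant_calls(out, map, params, engineered)
  structure(out, class = c("locus_calls", "data.frame"))
}

empty_locus_calls <- function() {
  data.frame(chrom = character(0), start_bp = integer(0),
             end_bp = integer(0), start_cm = numeric(0),
             end_cm = numeric(0), fixed_allele = character(0),
             mean_freq = numeric(0), n_windows = integer(0))
}

# MUTANT relabelling: a call covering (or merged across) an
# engineered-site marker whose mutant fraction reaches the threshold.
relabel_mutant_calls <- function(calls, map, params, engineered) {
  if (is.null(engineered) || !nrow(calls)) return(calls)
  site_gene <- c(IRA2_D2933 = "IRA2", SFL1_DELETED = "SFL1")
  for (i in seq_len(nrow(engineered))) {
    gene <- site_gene[[engineered$site[[i]]]]
    frac <- engineered$mut_fraction[[i]]
    if (is.na(frac) || frac < params$fix_threshold) next
    if (!gene %in% names(attr(map, "causal_sites"))) next
    idx <- causal_marker_index(map, gene)
    hit <- calls$chrom == map$chrom[idx] &
      calls$start_bp <= map$pos_bp[idx] & calls$end_bp >= map$pos_bp[idx]
    calls$fixed_allele[hit] <- "MUTANT"
  }
  calls
}

# comma-joined causal genes falling inside each interval
causal_genes_in_intervals <- function(intervals, map) {
  cs <- attr(map, "causal_sites")
  idx <- match(cs, map$id)
  vapply(seq_len(nrow(intervals)), function(i) {
    inside <- map$chrom[idx] == intervals$chrom[[i]] &
      map$pos_bp[idx] >= intervals$start_bp[[i]] &
      map$pos_bp[idx] <= intervals$end_bp[[i]]
    paste(names(cs)[inside], collapse = ",")
  }, "")
}

#' Delimit the smallest interval supporting a locus call
#'
#' Trims a call to span from the first to the last marker belonging to
#' any window (on the locus chromosome, overlapping the call) whose mean
#' crosses the fixation threshold for the call's allele.
#'
#' @param locus One row of a `locus_calls` data frame.
#' @param windows The `window_track` the call was made from.
#' @param params A `mapping_params`.
#' @return Named numeric vector `c(start_bp =, end_bp =)` (1-based,
#'   inclusive).
#' @export
delimit_interval <- function(locus, windows, params = mapping_params()) {
  allele <- if (locus$fixed_allele == "MUTANT") "3S" else locus$fixed_allele
  wch <- windows[windows$chrom == locus$chrom, , drop = FALSE]
  qual <- window_qualifies(wch, allele, params$fix_threshold) &
    wch$end_bp >= locus$start_bp & wch$start_bp <= locus$end_bp
  if (locus$fixed_allele == "MUTANT" && !any(qual)) {
    qual <- window_qualifies(wch, "BY", params$fix_threshold) &
      wch$end_bp >= locus$start_bp & wch$start_bp <= locus$end_bp
  }
  if (!any(qual)) stopf("locus has no qualifying window")
  c(start_bp = min(wch$start_bp[qual]), end_bp = max(wch$end_bp[qual]))
}

#' Map a pair of reciprocal backcross pools and merge the locus calls
#'
#' Runs the frequency / sliding-window / fixation-call pipeline
#' independently on the BY-backcross and 3S-backcross allele-count
#' tables, masking markers that do not segregate in each cross, then
#' unions the calls: calls from the two panels that share a causal site,
#' or whose intervals lie within `merge_gap_cm` on the same chromosome,
#' are one locus (a selected site can appear in both panels — the
#' engineered IRA2 lesion does — fixed for different alleles). Loci
#' mappable in only one backcross (monomorphic in the other) keep their
#' panel provenance.
#'
#' @param pool_by,pool_3s `allele_counts` tables for the BY and 3S
#'   backcross pools, on the same map.
#' @param map A `marker_map`.
#' @param params A `mapping_params`.
#' @param founder Optional founder `haplotype`; when given, segregation
#'   masks for both panels are derived from it. Alternatively supply
#'   explicit masks.
#' @param informative_by,informative_3s Optional logical masks (one per
#'   marker) of segregating markers per panel.
#' @return A `locus_calls`-style data frame with an extra `pool` column.
#' @export
map_backcross_pools <- function(pool_by, pool_3s, map,
                                params = mapping_params(),
                                founder = NULL,
                                informative_by = NULL,
                                informative_3s = NULL) {
  if (nrow(pool_by) != nrow(map) || nrow(pool_3s) != nrow(map))
    stopf("count tables do not conform to the map")
  if (!is.null(founder)) {
    informative_by <- segregating_markers(founder, "BY", map)
    informative_3s <- segregating_markers(founder, "3S", map)
  }
  one <- function(pool, informative, label) {
    track <- frequencies_from_counts(pool, params, informative)
    win <- sliding_windows(track, map, params)
    calls <- call_fixed_loci(win, map, params, attr(pool, "engineered"))
    if (nrow(calls)) calls$pool <- label else calls$pool <- character(0)
    calls
  }
  by_calls <- one(pool_by, informative_by, "BY")
  s3_calls <- one(pool_3s, informative_3s, "3S")
  merge_locus_calls(rbind(by_calls, s3_calls), params)
}

# Cluster calls on a chromosome whose intervals overlap, lie within the
# merge radius, or share a causal gene; one merged row per cluster.
merge_locus_calls <- function(all_calls, params = mapping_params()) {
  if (!nrow(all_calls)) {
    out <- empty_locus_calls()
    out$causal_genes <- character(0)
    out$pool <- character(0)
    return(structure(out, class = c("locus_calls", "data.frame")))
  }
  merged <- list()
  for (ch in unique(all_calls$chrom)) {
    rows <- all_calls[all_calls$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$start_bp), , drop = FALSE]
    n <- nrow(rows)
    grp <- seq_len(n)
    # proximity clustering
    if (n > 1L) {
      near <- if (all(is.finite(rows$start_cm))) {
        rows$start_cm[-1L] - cummax(rows$end_cm)[-n] <= params$merge_gap_cm
      } else {
        rows$start_bp[-1L] <= cummax(rows$end_bp)[-n]
      }
      grp <- cumsum(c(1L, as.integer(!near)))
    }
    # shared causal gene joins clusters (same chromosome)
    genes <- strsplit(rows$causal_genes, ",")
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (grp[i] != grp[j] &&
            length(intersect(genes[[i]], genes[[j]]))) {
          grp[grp == grp[i]] <- grp[j]
        }
      }
    }
    for (g in unique(grp)) {
      r <- rows[grp == g, , drop = FALSE]
      merged[[length(merged) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = min(r$start_bp), end_bp = max(r$end_bp),
        start_cm = min(r$start_cm), end_cm = max(r$end_cm),
        fixed_allele = if ("MUTANT" %in% r$fixed_allele) "MUTANT"
                       else paste(sort(unique(r$fixed_allele)),
                                  collapse = "/"),
        mean_freq = max(r$mean_freq),
        n_windows = sum(r$n_windows),
        causal_genes = paste(sort(unique(unlist(genes[grp == g]))),
                             collapse = ","),
        pool = paste(sort(unique(r$pool)), collapse = "+"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(match(out$chrom, CHROMOSOMES), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("locus_calls", "data.frame"))
}
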