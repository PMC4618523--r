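#' Physical lengths of the sixteen S. cerevisiae chromosomes
#'
#' Lengths in base pairs of chromosomes I-XVI of the S288c reference
#' assembly, used as the default genome for simulated marker maps.
#'
#' @return Named integer vector of length 16 (names are roman-numeral
#'   chromosome labels).
#' @export
yeast_chrom_lengths <- function() {
  stats::setNames(
    c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
      1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
      924431L, 784333L, 1091291L, 948066L),
    CHROMOSOMES
  )
}

# Default placement of the causal genes, as (chromosome, fractional position
# along the chromosome). Fractions approximate the genes' real coordinates so
# that maps built on rescaled chromosomes keep proportional placements.
# FLO8 on V, MGA1 on VII, MSS11 on XIII, END3 on XIV, IRA2 and SFL1 on XV;
# TRR1 defaults to IV (its native chromosome) and is configurable.
default_causal_layout <- function() {
  list(
    FLO8  = list(chrom = "V",    frac = 0.656),
    MGA1  = list(chrom = "VII",  frac = 0.907),
    MSS11 = list(chrom = "XIII", frac = 0.644),
    END3  = list(chrom = "XIV",  frac = 0.597),
    IRA2  = list(chrom = "XV",   frac = 0.156),
    SFL1  = list(chrom = "XV",   frac = 0.536),
    TRR1  = list(chrom = "IV",   frac = 0.770)
  )
}

CAUSAL_GENES <- c("END3", "FLO8", "MGA1", "MSS11", "SFL1", "TRR1", "IRA2")
# The six cryptic genes scored in interaction genotypes (IRA2 is the
# capacitor locus, tracked separately as an engineered site).
CRYPTIC_GENES <- c("END3", "FLO8", "MGA1", "MSS11", "SFL1", "TRR1")

#' Build a biallelic SNP marker map
#'
#' Generates an ordered map of biallelic BY/3S markers spread over 16
#' chromosomes proportionally to their physical length, with a genetic map
#' obtained from a constant cM/kb rate, and places one causal marker per
#' gene of the rough-morphology interaction system (END3, FLO8, MGA1,
#' MSS11, SFL1, TRR1, IRA2).
#'
#' @param n_markers Total number of markers (>= 16; every chromosome
#'   receives at least one marker). The study design used 36,756 SNPs.
#' @param chrom_lengths_bp Named (or karyotype-ordered) vector of 16
#'   positive chromosome lengths in bp. Defaults to the real genome.
#' @param cm_per_kb Genetic map density in centimorgans per kilobase
#'   (default 0.4, a typical yeast genome-wide average).
#' @param causal_overrides Optional named list overriding causal gene
#'   placement; each element is `list(chrom =, pos_bp =)` (or
#'   `frac =` for a fractional position).
#' @param seed Optional integer seed; the same seed reproduces the same map
#'   without disturbing the caller's RNG stream.
#' @return A `marker_map`: data frame with columns `id`, `chrom`, `pos_bp`,
#'   `pos_cM`, `allele_by`, `allele_3s` and an attribute `causal_sites`
#'   (named character vector gene -> marker id).
#' @export
build_marker_map <- function(n_markers,
                             chrom_lengths_bp = yeast_chrom_lengths(),
                             cm_per_kb = 0.4,
                             causal_overrides = NULL,
                             seed = NULL) {
  if (length(n_markers) != 1L || n_markers < 16)
    stopf("n_markers must be a single integer >= 16")
  n_markers <- as.integer(n_markers)
  if (length(chrom_lengths_bp) != 16L || any(chrom_lengths_bp <= 0))
    stopf("chrom_lengths_bp must be 16 positive lengths")
  chrom_lengths_bp <- as.integer(chrom_lengths_bp)
  names(chrom_lengths_bp) <- CHROMOSOMES
  if (cm_per_kb < 0) stopf("cm_per_kb must be >= 0")

  layout <- default_causal_layout()
  for (g in names(causal_overrides)) {
    ov <- causal_overrides[[g]]
    if (!g %in% CAUSAL_GENES) stopf("unknown causal gene '%s'", g)
    if (!ov$chrom %in% CHROMOSOMES) stopf("unknown chromosome '%s'", ov$chrom)
    if (!is.null(ov$pos_bp)) {
      ov$frac <- ov$pos_bp / chrom_lengths_bp[[ov$chrom]]
    }
    layout[[g]] <- list(chrom = ov$chrom, frac = ov$frac)
  }

  # Allocate markers proportionally to length (largest remainder, min 1).
  share <- n_markers * (chrom_lengths_bp / sum(as.numeric(chrom_lengths_bp)))
  k <- pmax(floor(share), 1L)   # keeps names (pmax takes them from arg 1)
  rem <- n_markers - sum(k)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(k, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      if (k[ord[i]] > 1L) { k[ord[i]] <- k[ord[i]] - 1L; rem <- rem + 1L }
      i <- if (i == 16L) 1L else i + 1L
    }
  }

  with_seed(seed, {
    pos <- lapply(CHROMOSOMES, function(ch) {
      sort(sample.int(chrom_lengths_bp[[ch]], k[[ch]]))
    })
    names(pos) <- CHROMOSOMES

    chrom <- rep(CHROMOSOMES, times = k)
    pos_bp <- unlist(pos, use.names = FALSE)
    m <- length(pos_bp)
    id <- sprintf("%s_%d", chrom, pos_bp)
    pos_cM <- (pos_bp - 1) / 1000 * cm_per_kb

    bases <- c("A", "C", "G", "T")
    allele_by <- sample(bases, m, replace = TRUE)
    shift <- sample.int(3L, m, replace = TRUE)
    allele_3s <- bases[(match(allele_by, bases) - 1L + shift) %% 4L + 1L]

    map <- data.frame(
      id = id, chrom = chrom, pos_bp = pos_bp, pos_cM = pos_cM,
      allele_by = allele_by, allele_3s = allele_3s,
      stringsAsFactors = FALSE
    )

    # Explicitly requested placements must be distinct.
    placement <- vapply(layout, function(l)
      sprintf("%s:%d", l$chrom,
              as.integer(round(l$frac * chrom_lengths_bp[[l$chrom]]))), "")
    if (anyDuplicated(placement))
      stopf("duplicate causal placements at the same marker: %s",
            paste(names(placement)[duplicated(placement)], collapse = ", "))

    # Snap each causal gene to the nearest still-free marker on its
    # chromosome; on maps too sparse to separate co-located genes the
    # nearest marker is shared.
    causal <- character(0)
    taken <- integer(0)
    for (g in names(layout)) {
      ch <- layout[[g]]$chrom
      target <- layout[[g]]$frac * chrom_lengths_bp[[ch]]
      on_ch <- which(map$chrom == ch)
      free <- setdiff(on_ch, taken)
      pick_from <- if (length(free)) free else on_ch
      hit <- pick_from[which.min(abs(map$pos_bp[pick_from] - target))]
      taken <- c(taken, hit)
      causal[[g]] <- map$id[[hit]]
    }

    structure(map,
              causal_sites = causal,
              cm_per_kb = cm_per_kb,
              class = c("marker_map", "data.frame"))
  })
}

#' Build a scaled-down marker map that preserves the mapping regime
#'
#' A map with fewer markers than the study's 36,756 SNPs must be shrunk
#' with care, because two dimensionless quantities govern whether
#' window-level fixation calling behaves as in the full-density design:
#'
#' * marker density per centimorgan, which sets the genetic width of a
#'   10-SNP window (the study design has ~7.7 SNPs/cM, so its windows
#'   span ~1.2 cM; a window much wider than a few cM dips below the 95%
#'   threshold even at a perfectly selected locus, because the expected
#'   pooled frequency at genetic distance d from the causal site is
#'   1 - r(d));
#' * the genetic separation of the two chromosome-XV loci (IRA2 and
#'   SFL1, ~166 cM apart in the real genome and hence quasi-unlinked),
#'   which must stay large enough that the two loci neither fuse into a
#'   single fixed block nor distort segregation ratios.
#'
#' This constructor therefore shrinks chromosome physical lengths so that
#' the map keeps `markers_per_cm` markers per centimorgan everywhere,
#' while giving chromosome XV the genetic length needed to keep the
#' IRA2-SFL1 separation at `xv_sep_cm` centimorgans; the remaining
#' genetic length is distributed over the other 15 chromosomes
#' proportionally to their real sizes.
#'
#' @inheritParams build_marker_map
#' @param markers_per_cm Marker density of the scaled map (default 4
#'   SNPs/cM; the full design has ~7.7).
#' @param min_flank_cm Minimum genetic distance between a causal site and
#'   either end of its chromosome (default 6 cM). Fixation calling needs
#'   the above-threshold plateau around a selected site (roughly the
#'   region where 1 - r(d) >= 0.95, i.e. +/- 5 cM) covered by whole
#'   windows on both sides; a causal site squeezed against a telomere by
#'   proportional shrinking loses one flank entirely (on the real map
#'   every causal gene has >= 40 cM of flank). Chromosomes without
#'   causal sites carry no such floor — they need no mapping power.
#' @param xv_sep_cm Genetic separation to preserve between the IRA2 and
#'   SFL1 markers on chromosome XV (default 80 cM, recombination
#'   fraction ~0.40, close to the real ~166 cM / r ~0.48).
#' @param ... Passed on to [build_marker_map()].
#' @return A `marker_map` (see [build_marker_map()]).
#' @export
scaled_marker_map <- function(n_markers, markers_per_cm = 4,
                              xv_sep_cm = 120, min_flank_cm = 6,
                              cm_per_kb = 0.4, seed = NULL, ...) {
  total_cm <- n_markers / markers_per_cm
  real <- yeast_chrom_lengths()
  layout <- default_causal_layout()
  sep_frac <- abs(layout$SFL1$frac - layout$IRA2$frac)
  xv_cm <- max(xv_sep_cm / sep_frac, total_cm * real[["XV"]] / sum(real))
  rest_cm <- total_cm - xv_cm
  others <- real[names(real) != "XV"]

  # genetic-length floor per causal chromosome: both flanks of every
  # causal site must reach min_flank_cm
  floor_cm <- stats::setNames(numeric(16), CHROMOSOMES)
  for (g in names(layout)) {
    ch <- layout[[g]]$chrom
    if (ch == "XV") next
    f <- layout[[g]]$frac
    floor_cm[[ch]] <- max(floor_cm[[ch]], min_flank_cm / min(f, 1 - f))
  }
  cm <- stats::setNames(numeric(16), CHROMOSOMES)
  cm[names(others)] <- rest_cm * others / sum(others)
  cm[["XV"]] <- xv_cm
  causal_ch <- setdiff(names(floor_cm)[floor_cm > 0], "XV")
  cm[causal_ch] <- pmax(cm[causal_ch], floor_cm[causal_ch])
  # the non-causal chromosomes absorb the difference, proportionally
  noncausal <- setdiff(names(others), causal_ch)
  left <- rest_cm - sum(cm[causal_ch])
  if (left < length(noncausal) * 0.5)
    stopf("n_markers too small for this density; increase n_markers or lower markers_per_cm")
  cm[noncausal] <- left * others[noncausal] / sum(others[noncausal])

  lens <- as.integer(round(cm / cm_per_kb * 1000))
  build_marker_map(n_markers, chrom_lengths_bp = lens,
                   cm_per_kb = cm_per_kb, seed = seed, ...)
}

#' @export
print.marker_map <- function(x, ...) {
  cs <- attr(x, "causal_sites")
  cat(sprintf("marker_map: %d markers on %d chromosomes (%.1f cM total)\n",
              nrow(x), length(unique(x$chrom)),
              sum(tapply(x$pos_cM, x$chrom, function(p) diff(range(p))))))
  cat("causal sites:", paste(sprintf("%s=%s", names(cs), cs), collapse = ", "),
      "\n")
  invisible(x)
}

#' Causal-site marker indices of a map
#'
#' @param map A `marker_map`.
#' @param genes Genes to resolve (default: all causal sites of the map).
#' @return Named integer vector of row indices into `map`.
#' @export
causal_marker_index <- function(map, genes = NULL) {
  cs <- attr(map, "causal_sites")
  if (is.null(cs)) stopf("map carries no causal_sites attribute")
  genes <- genes %||% names(cs)
  missing <- setdiff(genes, names(cs))
  if (length(missing))
    stopf("gene(s) not in the map's causal sites: %s",
          paste(missing, collapse = ", "))
  idx <- match(cs[genes], map$id)
  stats::setNames(idx, genes)
}

validate_marker_map <- function(map) {
  need <- c("id", "chrom", "pos_bp", "pos_cM", "allele_by", "allele_3s")
  if (!all(need %in% names(map))) stopf("marker map missing required columns")
  if (anyDuplicated(map$id)) stopf("marker ids must be unique")
  if (any(map$pos_bp < 1)) stopf("pos_bp must be >= 1")
  if (any(map$pos_cM < 0)) stopf("pos_cM must be >= 0")
  if (any(map$allele_by == map$allele_3s))
    stopf("allele_by and allele_3s must differ at every marker")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    g <- map$pos_cM[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE) || is.unsorted(g, strictly = FALSE))
      stopf("positions must be sorted increasing within chromosome %s", ch)
  }
  invisible(map)
}
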