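# Shared fixtures, built in code at test time.

# Full-size genome with sparse markers: causal genes assort
# (quasi-)independently, as in the real map. Used for segregation-ratio
# and meiosis tests where window power is irrelevant.
sparse_map <- function(n = 320, seed = 2024, ...) {
  build_marker_map(n, seed = seed, ...)
}

# Density-preserving scaled map for locus-recovery tests.
dense_map <- function(n = 2000, seed = 7) {
  scaled_marker_map(n, seed = seed)
}

CRYPTIC6 <- c("END3", "FLO8", "MGA1", "MSS11", "SFL1", "TRR1")

# A haplotype with prescribed origins at causal genes and a uniform
# background elsewhere.
causal_haplotype <- function(map, genes = character(0),
                             background = "BY", ira2 = "WT",
                             sfl1 = "PRESENT") {
  org <- rep(if (background == "BY") 0L else 1L, nrow(map))
  if (length(genes)) {
    idx <- causal_marker_index(map, names(genes))
    org[idx] <- ifelse(genes == "3S", 1L, 0L)
  }
  haplotype(org, ira2 = ira2, sfl1 = sfl1)
}

# Hand-built map: `sizes` markers per chromosome, evenly spaced, no
# causal sites unless requested. Deterministic; for window arithmetic
# and parser tests.
manual_map <- function(sizes, spacing_bp = 1000, cm_per_kb = 0.4,
                       causal = character(0)) {
  chroms <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
              "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")
  stopifnot(length(sizes) <= 16)
  rows <- lapply(seq_along(sizes), function(i) {
    pos <- seq_len(sizes[[i]]) * spacing_bp
    data.frame(id = sprintf("%s_%d", chroms[[i]], pos),
               chrom = chroms[[i]], pos_bp = pos,
               pos_cM = (pos - 1) / 1000 * cm_per_kb,
               allele_by = "A", allele_3s = "G",
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  structure(map, causal_sites = causal, cm_per_kb = cm_per_kb,
            class = c("marker_map", "data.frame"))
}

# Allele-count table realising exact frequencies with depth 100 and no
# noise (count_3s = round(100 * f)).
counts_from_freqs <- function(map, freqs, depth = 100L) {
  c3 <- as.integer(round(depth * freqs))
  structure(data.frame(id = map$id, chrom = map$chrom, pos_bp = map$pos_bp,
                       depth = depth, count_by = depth - c3,
                       count_3s = c3, count_other = 0L,
                       stringsAsFactors = FALSE),
            class = c("allele_counts", "data.frame"))
}

expected_cryptics <- c("END3", "FLO8", "MGA1", "MSS11", "SFL1", "TRR1")

locus_contains_gene <- function(loci, map, gene) {
  idx <- causal_marker_index(map, gene)
  any(loci$chrom == map$chrom[idx] & loci$start_bp <= map$pos_bp[idx] &
        loci$end_bp >= map$pos_bp[idx])
}

genes_in_report <- function(loci) {
  sort(unique(unlist(strsplit(loci$causal_genes[nzchar(loci$causal_genes)],
                              ","))))
}
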