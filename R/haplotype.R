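#' Construct a haplotype
#'
#' A haplotype records, for every marker of a map, the parental origin of
#' the allele (BY or 3S) plus the state of the two engineered sites: the
#' ira2-Delta2933 lesion carried at the IRA2 marker and the SFL1 deletion
#' carried at the SFL1 marker.
#'
#' @param origins Character (`"BY"`/`"3S"`) or integer (0/1) vector, one
#'   element per marker.
#' @param ira2 `"WT"` or `"D2933"`.
#' @param sfl1 `"PRESENT"` or `"DELETED"`.
#' @return An object of class `haplotype`.
#' @export
haplotype <- function(origins, ira2 = "WT", sfl1 = "PRESENT") {
  if (is.character(origins)) origins <- origin_code(origins)
  origins <- as.integer(origins)
  if (any(!origins %in% c(0L, 1L))) stopf("origins must code BY=0 / 3S=1")
  if (!ira2 %in% c("WT", "D2933")) stopf("ira2 must be 'WT' or 'D2933'")
  if (!sfl1 %in% c("PRESENT", "DELETED"))
    stopf("sfl1 must be 'PRESENT' or 'DELETED'")
  structure(list(origins = origins, ira2 = ira2, sfl1 = sfl1),
            class = "haplotype")
}

#' Non-recombinant parental haplotype
#'
#' @param map A `marker_map`.
#' @param parent `"BY"` or `"3S"`.
#' @param ira2,sfl1 Engineered-site states carried by this strain.
#' @return A `haplotype` with a uniform parental origin.
#' @export
pure_haplotype <- function(map, parent = c("BY", "3S"),
                           ira2 = "WT", sfl1 = "PRESENT") {
  parent <- match.arg(parent)
  haplotype(rep(origin_code(parent), nrow(map)), ira2 = ira2, sfl1 = sfl1)
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("haplotype: %d markers (%.1f%% 3S), ira2=%s, sfl1=%s\n",
              length(x$origins), 100 * mean(x$origins), x$ira2, x$sfl1))
  invisible(x)
}

check_haplotype_map <- function(h, map) {
  if (length(h$origins) != nrow(map))
    stopf("haplotype has %d markers but map has %d",
          length(h$origins), nrow(map))
  invisible(h)
}

#' Origins of a haplotype at the causal genes
#'
#' @param h A `haplotype`.
#' @param map A `marker_map`.
#' @param genes Genes to extract (default all causal sites).
#' @return Named character vector gene -> `"BY"`/`"3S"`.
#' @export
gene_origins <- function(h, map, genes = NULL) {
  check_haplotype_map(h, map)
  idx <- causal_marker_index(map, genes)
  stats::setNames(origin_label(h$origins[idx]), names(idx))
}
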