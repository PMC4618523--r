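# samtools mpileup entry point: derive per-SNP BY/3S allele counts from a
# plain (no-BAQ, no extended tag) pileup stream and a SNP list.

# Expand one pileup base string into upper-case base calls.
# Markup handled: '^' + mapping-quality char (read start), '$' (read end),
# '+n'/'-n' followed by n inserted/deleted bases (attached to the
# preceding call), '*' (deleted base placeholder), '>'/'<' (reference
# skips). '.'/',' resolve to the reference base.
parse_pileup_bases <- function(bases, ref) {
  chars <- strsplit(bases, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  ref <- toupper(ref)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "^") {
      i <- i + 2L                       # caret + mapping quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[[j]])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(len)) return(NULL)
      i <- j + len                      # skip the indel sequence
    } else if (ch == "." || ch == ",") {
      out <- c(out, ref)
      i <- i + 1L
    } else if (grepl("[ACGTNacgtn*<>]", ch)) {
      out <- c(out, toupper(ch))
      i <- i + 1L
    } else {
      return(NULL)                      # unrecognised markup
    }
  }
  out
}

#' Allele counts from an mpileup stream
#'
#' For each SNP in the list, counts pileup base calls matching the BY
#' allele, the 3S allele, and anything else (including deletion
#' placeholders). SNPs absent from the stream yield zero-depth rows.
#' Only the plain samtools pileup dialect is supported.
#'
#' @param path Path to (or connection of) an mpileup text stream with
#'   columns chrom, pos (1-based), ref, depth, bases, quals.
#' @param snp_list A `marker_map` (or data frame with `id`, `chrom`,
#'   `pos_bp`, `allele_by`, `allele_3s`).
#' @return An `allele_counts` table aligned to `snp_list`.
#' @export
read_mpileup_counts <- function(path, snp_list) {
  lines <- readLines(path)
  key <- paste(snp_list$chrom, snp_list$pos_bp)
  depth <- count_by <- count_3s <- count_other <-
    integer(nrow(snp_list))
  wanted <- stats::setNames(seq_along(key), key)

  for (ln in seq_along(lines)) {
    if (!nzchar(lines[[ln]])) next
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      stopf("malformed pileup line %d: expected >= 5 tab-separated fields", ln)
    pos <- suppressWarnings(as.integer(f[[2]]))
    if (is.na(pos)) stopf("malformed pileup line %d: bad position", ln)
    i <- wanted[paste(f[[1]], pos)]
    if (is.na(i)) next
    calls <- parse_pileup_bases(f[[5]], f[[3]])
    if (is.null(calls))
      stopf("malformed pileup line %d: unparseable base string", ln)
    depth[i] <- length(calls)
    count_by[i] <- sum(calls == toupper(snp_list$allele_by[[i]]))
    count_3s[i] <- sum(calls == toupper(snp_list$allele_3s[[i]]))
    count_other[i] <- depth[i] - count_by[i] - count_3s[i]
  }
  structure(data.frame(id = snp_list$id, chrom = snp_list$chrom,
                       pos_bp = snp_list$pos_bp, depth = depth,
                       count_by = count_by, count_3s = count_3s,
                       count_other = count_other, stringsAsFactors = FALSE),
            class = c("allele_counts", "data.frame"))
}
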