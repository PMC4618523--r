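# Plain-text interchange formats. All TSVs are 1-based inclusive in bp;
# BED exports convert to 0-based half-open. '#'-prefixed header lines
# carry run metadata (seed, parameters) and, for marker maps, the causal
# gene assignments.

write_tsv_with_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_meta_lines <- function(path) {
  lines <- readLines(path, n = 200L)
  sub("^#\\s*", "", lines[startsWith(lines, "#")])
}

read_tsv_body <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write / read a marker map TSV
#'
#' Columns `id`, `chrom`, `pos_bp`, `pos_cM`, `allele_by`, `allele_3s`;
#' causal gene assignments and the cM/kb rate travel in `#` header lines
#' so that write-then-read round-trips the full object.
#'
#' @param map A `marker_map`.
#' @param path File path.
#' @param meta Extra header lines (e.g. `"seed: 1"`).
#' @return `path` (write) / a `marker_map` (read).
#' @export
write_marker_map <- function(map, path, meta = character()) {
  cs <- attr(map, "causal_sites")
  hdr <- c(meta,
           sprintf("cm_per_kb: %s", format(attr(map, "cm_per_kb") %||% NA)),
           sprintf("causal: %s=%s", names(cs), cs))
  df <- as.data.frame(map)
  names(df) <- c("id", "chrom", "pos_bp", "pos_cM", "allele_by", "allele_3s")
  write_tsv_with_meta(df, path, hdr)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  df <- read_tsv_body(path,
                      colClasses = c(id = "character", chrom = "character",
                                     allele_by = "character",
                                     allele_3s = "character"))
  meta <- read_meta_lines(path)
  causal <- meta[startsWith(meta, "causal:")]
  kv <- do.call(rbind, strsplit(sub("^causal:\\s*", "", causal), "="))
  cs <- stats::setNames(kv[, 2], kv[, 1])
  rate <- suppressWarnings(as.numeric(sub("^cm_per_kb:\\s*", "",
                                          meta[startsWith(meta, "cm_per_kb:")])))
  map <- structure(df, causal_sites = cs,
                   cm_per_kb = if (length(rate)) rate[[1]] else NA_real_,
                   class = c("marker_map", "data.frame"))
  validate_marker_map(map)
}

#' Write / read a genotype matrix TSV
#'
#' Rows are segregants; the first columns are `segregant`, `ira2_state`,
#' `sfl1_state`, `phenotype`, followed by one `BY`/`3S` column per
#' marker.
#'
#' @param pop A `cross_pop`.
#' @param path File path.
#' @param meta Extra header lines.
#' @return `path` (write) / a `cross_pop` (read).
#' @export
write_genotypes <- function(pop, path, meta = character()) {
  geno <- matrix(origin_label(pop$geno), nrow = nrow(pop$geno),
                 dimnames = dimnames(pop$geno))
  df <- data.frame(segregant = sprintf("seg%04d", seq_len(nrow(geno))),
                   ira2_state = pop$ira2, sfl1_state = pop$sfl1,
                   phenotype = pop$phenotype,
                   geno, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_meta(df, path, c(meta, sprintf("scheme: %s", pop$scheme)))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_body(path, check.names = FALSE)
  meta <- read_meta_lines(path)
  scheme <- sub("^scheme:\\s*", "", meta[startsWith(meta, "scheme:")])
  side <- c("segregant", "ira2_state", "sfl1_state", "phenotype")
  markers <- setdiff(names(df), side)
  geno <- as.matrix(df[markers])
  geno <- matrix(origin_code(geno), nrow = nrow(df),
                 dimnames = list(NULL, markers))
  structure(list(geno = geno, ira2 = df$ira2_state, sfl1 = df$sfl1_state,
                 phenotype = df$phenotype,
                 scheme = if (length(scheme)) scheme[[1]] else NA_character_),
            class = "cross_pop")
}

#' Write / read a pooled allele-count TSV
#'
#' Columns `id`, `chrom`, `pos_bp`, `depth`, `count_by`, `count_3s`,
#' `count_other`; engineered-site rows (if any) travel in `#` header
#' lines `engineered: site depth count_mut count_wt`.
#'
#' @param counts An `allele_counts` table.
#' @param path File path.
#' @param meta Extra header lines.
#' @return `path` (write) / an `allele_counts` table (read).
#' @export
write_allele_counts <- function(counts, path, meta = character()) {
  eng <- attr(counts, "engineered")
  if (!is.null(eng)) {
    meta <- c(meta, sprintf("engineered: %s %d %d %d", eng$site, eng$depth,
                            eng$count_mut, eng$count_wt))
  }
  cols <- c("id", "chrom", "pos_bp", "depth", "count_by", "count_3s",
            "count_other")
  write_tsv_with_meta(as.data.frame(counts)[cols], path, meta)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  df <- read_tsv_body(path, colClasses = c(id = "character",
                                           chrom = "character"))
  meta <- read_meta_lines(path)
  eng_lines <- meta[startsWith(meta, "engineered:")]
  out <- structure(df, class = c("allele_counts", "data.frame"))
  if (length(eng_lines)) {
    parts <- strsplit(sub("^engineered:\\s*", "", eng_lines), "\\s+")
    eng <- data.frame(site = vapply(parts, `[[`, "", 1L),
                      depth = as.integer(vapply(parts, `[[`, "", 2L)),
                      count_mut = as.integer(vapply(parts, `[[`, "", 3L)),
                      count_wt = as.integer(vapply(parts, `[[`, "", 4L)),
                      stringsAsFactors = FALSE)
    eng$mut_fraction <- ifelse(eng$count_mut + eng$count_wt > 0,
                               eng$count_mut / (eng$count_mut + eng$count_wt),
                               NA_real_)
    attr(out, "engineered") <- eng
  }
  validate_allele_counts(out)
  out
}

#' Write / read a locus report TSV
#'
#' One row per called locus: `chrom`, `start_bp`, `end_bp` (1-based
#' inclusive), `fixed_allele`, `mean_freq`, `n_windows`, `causal_genes`,
#' and `pool` when present.
#'
#' @param calls A `locus_calls` data frame.
#' @param path File path.
#' @param meta Extra header lines.
#' @return `path` (write) / a `locus_calls` data frame (read).
#' @export
write_locus_report <- function(calls, path, meta = character()) {
  write_tsv_with_meta(as.data.frame(calls), path, meta)
}

#' @rdname write_locus_report
#' @export
read_locus_report <- function(path) {
  df <- read_tsv_body(path, colClasses = c(chrom = "character"))
  if ("causal_genes" %in% names(df))
    df$causal_genes <- ifelse(is.na(df$causal_genes), "",
                              as.character(df$causal_genes))
  structure(df, class = c("locus_calls", "data.frame"))
}

#' Export locus calls as BED6
#'
#' Converts the 1-based inclusive intervals to BED's 0-based half-open
#' convention; `name` is the fixed allele and `score` is
#' `round(1000 * mean_freq)`.
#'
#' @param calls A `locus_calls` data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom,
                   start = calls$start_bp - 1L,
                   end = calls$end_bp,
                   name = calls$fixed_allele,
                   score = round(1000 * calls$mean_freq),
                   strand = rep(".", nrow(calls)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
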