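#' Read and write BED intervals
#'
#' BED is tab-separated, 0-based half-open, minimum three columns
#' (`chrom`, `start`, `end`); a fourth column is read as `name`.
#' Malformed lines are reported with their line numbers.
#'
#' @param path file path.
#' @param chrom_sizes optional tibble `chrom`, `length` used to validate
#'   coordinates against chromosome bounds.
#' @return tibble `chrom`, `start`, `end` (+ `name` when present).
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf(
      "BED line(s) with fewer than 3 fields: %s",
      paste(head(which(nf < 3L), 5L), collapse = ", ")
    ))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end |
    start != floor(start) | end != floor(end))
  if (length(bad) > 0L) {
    abort(sprintf(
      "invalid BED coordinates (need 0 <= start < end, integers) at line(s): %s",
      paste(head(bad, 5L), collapse = ", ")
    ))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end
  )
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (!is.null(chrom_sizes)) {
    check_chrom_namespace(out$chrom, chrom_sizes$chrom, "BED records")
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    over <- which(out$end > len[out$chrom])
    if (length(over) > 0L) {
      abort(sprintf(
        "BED coordinate exceeds chromosome length at line(s): %s",
        paste(head(over, 5L), collapse = ", ")
      ))
    }
  }
  out
}

#' @rdname read_bed
#' @param intervals tibble `chrom`, `start`, `end` (+ optional `name`).
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("chrom", "start", "end"), arg = "intervals")
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read and write gene-level count tables
#'
#' Counts are tab-separated with a `gene_id` column and one integer column
#' per sample; the round trip through [write_counts()] and
#' [read_counts()] is lossless. Non-integer or negative cells are
#' rejected with their position named.
#'
#' @param path file path.
#' @return tibble `gene_id` + sample columns.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, "gene_id", arg = "counts file")
  samp <- setdiff(names(df), "gene_id")
  for (s in samp) {
    v <- df[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-integer or negative count in column '%s', row %d (value %s)",
        s, bad[1], format(v[bad[1]])
      ))
    }
  }
  df
}

#' @rdname read_counts
#' @param counts tibble `gene_id` + one column per sample.
#' @export
write_counts <- function(counts, path) {
  assert_cols(counts, "gene_id", arg = "counts")
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample_id`, `genotype`, `treatment`,
#' `time`, `replicate`; duplicated sample ids are rejected.
#'
#' @param path file path.
#' @return design tibble.
#' @export
read_design <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_design(df)
  df
}

#' @rdname read_design
#' @param design design tibble.
#' @export
write_design <- function(design, path) {
  check_design(design)
  readr::write_tsv(design, path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return tibble `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "length"), show_col_types = FALSE
  )
  if (any(!is.finite(df$length) | df$length <= 0)) {
    abort("chromosome lengths must be positive.")
  }
  df
}

#' Read and write TSS tables
#'
#' Tab-separated `gene_id`, `chrom`, `tss` (0-based bp), `strand`.
#'
#' @param path file path.
#' @param chrom_sizes optional bounds check.
#' @return tibble.
#' @export
read_tss <- function(path, chrom_sizes = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, c("gene_id", "chrom", "tss"), arg = "TSS file")
  if (!is.null(chrom_sizes)) {
    check_chrom_namespace(df$chrom, chrom_sizes$chrom, "TSSs")
    len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
    if (any(df$tss < 0 | df$tss >= len[df$chrom])) {
      abort("TSS position outside chromosome bounds.")
    }
  }
  df
}

#' @rdname read_tss
#' @param tss tibble `gene_id`, `chrom`, `tss` (+ optional columns).
#' @export
write_tss <- function(tss, path) {
  assert_cols(tss, c("gene_id", "chrom", "tss"), arg = "tss")
  readr::write_tsv(tss, path)
  invisible(path)
}
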