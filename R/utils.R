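# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, otherwise use
# the current RNG stream. All user-facing stochastic functions funnel
# through this so that a recorded seed reproduces a run bit-for-bit.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

assert_cols <- function(df, cols, arg = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", arg))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# counts tibble (gene_id + one column per sample) -> integer matrix
counts_to_matrix <- function(counts) {
  assert_cols(counts, "gene_id", arg = "counts")
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (!is.numeric(mat)) abort("count columns must be numeric.")
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort("counts must be finite and non-negative.")
  }
  if (any(mat != round(mat))) abort("counts must be integers.")
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  mat
}

check_design <- function(design, sample_ids = NULL) {
  assert_cols(design, c("sample_id", "genotype", "treatment", "time", "replicate"),
    arg = "design")
  if (anyDuplicated(design$sample_id)) {
    abort("duplicated sample_id in design.")
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    if (length(missing) > 0L) {
      abort(sprintf(
        "design does not cover sample(s): %s",
        paste(head(missing, 5L), collapse = ", ")
      ))
    }
  }
  invisible(design)
}

# tibble(chrom, start, end) in 0-based half-open coords -> GRanges (1-based)
peaks_to_granges <- function(peaks, chrom_sizes = NULL) {
  assert_cols(peaks, c("chrom", "start", "end"), arg = "peaks")
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end)) {
    abort("peak intervals must satisfy 0 <= start < end.")
  }
  seqlengths <- NULL
  if (!is.null(chrom_sizes)) {
    assert_cols(chrom_sizes, c("chrom", "length"), arg = "chrom_sizes")
    seqlengths <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  }
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    seqlengths = seqlengths
  )
}

granges_to_peaks <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

check_chrom_namespace <- function(query_chroms, known_chroms, what = "intervals") {
  unknown <- setdiff(unique(query_chroms), known_chroms)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "%s reference unknown chromosome(s): %s",
      what, paste(unknown, collapse = ", ")
    ))
  }
  invisible(TRUE)
}
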