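#' Intersect two interval sets
#'
#' Returns the records of `peaks_a` overlapping at least one base of
#' `peaks_b`, with overlap defined on 0-based half-open coordinates:
#' \[s1, e1) overlaps \[s2, e2) iff `s1 < e2 && s2 < e1`. Used to select
#' peaks present in both of two ChIP-seq datasets.
#'
#' @param peaks_a,peaks_b tibbles with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_sizes optional tibble `chrom`, `length`; when supplied,
#'   both sets are checked against this chromosome namespace.
#' @return the overlapping rows of `peaks_a` (records preserved).
#' @export
intersect_peaks <- function(peaks_a, peaks_b, chrom_sizes = NULL) {
  assert_cols(peaks_a, c("chrom", "start", "end"), arg = "peaks_a")
  assert_cols(peaks_b, c("chrom", "start", "end"), arg = "peaks_b")
  if (!is.null(chrom_sizes)) {
    check_chrom_namespace(
      c(peaks_a$chrom, peaks_b$chrom), chrom_sizes$chrom, "peaks"
    )
  }
  if (nrow(peaks_a) == 0L || nrow(peaks_b) == 0L) {
    return(peaks_a[integer(), , drop = FALSE])
  }
  gr_a <- peaks_to_granges(peaks_a)
  gr_b <- peaks_to_granges(peaks_b)
  # the two sets may legitimately cover different chromosome subsets
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = 1L)
  )
  peaks_a[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Relative distance between TSSs and peak midpoints
#'
#' For each TSS lying strictly between two consecutive peak midpoints L
#' and R on its chromosome, the relative distance is
#' `min(t - L, R - t) / (R - L)`, a value in \[0, 0.5\]. Under
#' independence of TSSs and peaks the values are Uniform\[0, 0.5\]; an
#' excess of small values indicates co-occurrence. TSSs not flanked by two
#' midpoints (outside the outermost peaks, or on a chromosome with fewer
#' than two peaks) are skipped and counted.
#'
#' @param tss tibble `gene_id`, `chrom`, `tss` (0-based bp).
#' @param peaks tibble `chrom`, `start`, `end`; reduced to midpoints
#'   `floor((start + end) / 2)`.
#' @param n_bins number of histogram bins over \[0, 0.5\].
#' @return list with `values` (tibble `gene_id`, `chrom`, `tss`,
#'   `rel_dist`), `n_skipped`, and `histogram` (tibble `bin_lo`, `bin_hi`,
#'   `count`, `fraction`).
#' @export
relative_distance <- function(tss, peaks, n_bins = 50) {
  assert_cols(tss, c("gene_id", "chrom", "tss"), arg = "tss")
  assert_cols(peaks, c("chrom", "start", "end"), arg = "peaks")
  mids <- peaks |>
    mutate(mid = floor((.data$start + .data$end) / 2)) |>
    group_by(.data$chrom) |>
    summarise(mids = list(sort(.data$mid)), .groups = "drop")
  mid_of <- setNames(mids$mids, mids$chrom)

  vals <- tss |>
    group_by(.data$chrom) |>
    group_split() |>
    map(function(df) {
      m <- mid_of[[df$chrom[1]]]
      if (is.null(m) || length(m) < 2L) {
        warn(sprintf(
          "chromosome %s has < 2 peaks; skipping its %d TSS(s).",
          df$chrom[1], nrow(df)
        ))
        return(df |> mutate(rel_dist = NA_real_))
      }
      i <- findInterval(df$tss, m)
      ok <- i >= 1L & i < length(m) & df$tss >= m[1]
      left <- m[pmax(i, 1L)]
      right <- m[pmin(i + 1L, length(m))]
      rd <- ifelse(ok, pmin(df$tss - left, right - df$tss) / (right - left),
        NA_real_)
      df |> mutate(rel_dist = rd)
    }) |>
    list_rbind()
  n_skipped <- sum(is.na(vals$rel_dist))
  values <- vals |>
    filter(!is.na(.data$rel_dist)) |>
    select("gene_id", "chrom", "tss", "rel_dist")
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  counts <- tabulate(
    pmin(findInterval(values$rel_dist, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  )
  histogram <- tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = counts,
    fraction = if (sum(counts) > 0) counts / sum(counts) else rep(0, n_bins)
  )
  list(values = values, n_skipped = n_skipped, histogram = histogram)
}

#' Fraction of TSSs with a peak within a window
#'
#' A TSS counts as covered when some peak interval lies within `window`
#' bp: the distance is 0 if the TSS position falls inside the half-open
#' interval, otherwise the bp gap to the nearest included base. The 30-kb
#' default reflects that GR binds regulatory elements distal to gene
#' TSSs.
#'
#' @param tss tibble `gene_id`, `chrom`, `tss` (non-empty).
#' @param peaks tibble `chrom`, `start`, `end`.
#' @param window maximum gap in bp (> 0), default 30000.
#' @return list with `ratio` (fraction in \[0, 1\]) and `flags` (tibble
#'   `gene_id`, `chrom`, `tss`, `covered`).
#' @export
window_overlap_ratio <- function(tss, peaks, window = 30000) {
  assert_cols(tss, c("gene_id", "chrom", "tss"), arg = "tss")
  assert_cols(peaks, c("chrom", "start", "end"), arg = "peaks")
  if (nrow(tss) == 0L) abort("tss set is empty.")
  if (window <= 0) abort("window must be > 0.")
  if (nrow(peaks) == 0L) {
    flags <- tss |> mutate(covered = FALSE)
    return(list(ratio = 0, flags = flags |> select("gene_id", "chrom", "tss", "covered")))
  }
  covered <- rep(FALSE, nrow(tss))
  for (ch in unique(tss$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    idx <- which(tss$chrom == ch)
    if (nrow(p) == 0L) next
    t <- tss$tss[idx]
    # gap from point t to interval [s, e): 0 inside, else bp to nearest base
    # distance to nearest peak via sorted starts/last-bases
    s <- p$start
    last <- p$end - 1
    gap <- vapply(t, function(ti) {
      inside <- any(ti >= s & ti < p$end)
      if (inside) return(0)
      min(pmax(s - ti, ti - last))
    }, numeric(1))
    covered[idx] <- gap <= window
  }
  flags <- tss |> mutate(covered = covered)
  list(
    ratio = mean(covered),
    flags = flags |> select("gene_id", "chrom", "tss", "covered")
  )
}

#' Randomize TSS positions over the genome
#'
#' Re-places each TSS uniformly at random, by default anywhere in the
#' genome with chromosomes weighted by length (mirroring the default of
#' the standard interval-shuffling tool); with `keep_chromosome = TRUE`
#' each TSS stays on its own chromosome. The shuffled set is the empirical
#' null for the co-occurrence statistics.
#'
#' @param tss tibble `gene_id`, `chrom`, `tss`.
#' @param chrom_sizes tibble `chrom`, `length` covering all chromosomes.
#' @param keep_chromosome keep each TSS on its original chromosome.
#' @param seed integer seed; same seed, same shuffle.
#' @return tibble with the same columns and row count as `tss`.
#' @export
shuffle_tss <- function(tss, chrom_sizes, keep_chromosome = FALSE, seed = NULL) {
  assert_cols(tss, c("gene_id", "chrom", "tss"), arg = "tss")
  assert_cols(chrom_sizes, c("chrom", "length"), arg = "chrom_sizes")
  check_chrom_namespace(tss$chrom, chrom_sizes$chrom, "TSSs")
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  with_seed_if(seed, {
    n <- nrow(tss)
    out <- tss
    if (keep_chromosome) {
      out$tss <- floor(runif(n, 0, len[tss$chrom]))
    } else {
      new_chrom <- sample(chrom_sizes$chrom, n,
        replace = TRUE, prob = chrom_sizes$length)
      out$chrom <- new_chrom
      out$tss <- floor(runif(n, 0, len[new_chrom]))
    }
    out
  })
}

#' Expected shuffle-null window overlap ratio
#'
#' Analytic expectation of [window_overlap_ratio()] for uniformly placed
#' TSSs: the fraction of the genome covered by the union of peak
#' intervals extended by `window` on both sides (clipped to chromosome
#' bounds).
#'
#' @param peaks tibble `chrom`, `start`, `end`.
#' @param chrom_sizes tibble `chrom`, `length`.
#' @param window extension in bp.
#' @return scalar fraction in \[0, 1\].
#' @export
expected_shuffle_ratio <- function(peaks, chrom_sizes, window = 30000) {
  assert_cols(chrom_sizes, c("chrom", "length"), arg = "chrom_sizes")
  if (nrow(peaks) == 0L) return(0)
  check_chrom_namespace(peaks$chrom, chrom_sizes$chrom, "peaks")
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  ext <- peaks |>
    mutate(
      start = pmax(0, .data$start - window),
      end = pmin(len[.data$chrom], .data$end + window)
    )
  gr <- GenomicRanges::reduce(peaks_to_granges(ext))
  sum(GenomicRanges::width(gr)) / sum(chrom_sizes$length)
}
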