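#' Per-chromosome enrichment of a gene set
#'
#' Hypergeometric upper-tail test per chromosome: drawing the K set genes
#' from the N universe genes, with m universe genes on the chromosome, the
#' p-value is P(X >= k) for the k set genes observed there; BH adjustment
#' across chromosomes.
#'
#' @param gene_set character vector of gene ids (non-empty, subset of the
#'   universe).
#' @param universe a `sofdex_genome` or a tibble `gene_id`, `chrom`, `tss`.
#' @return tibble `chrom`, `k`, `m`, `K`, `N`, `p`, `padj`, sorted by `p`.
#' @export
chromosome_enrichment <- function(gene_set, universe) {
  genes <- universe_genes(universe)
  if (length(gene_set) == 0L) abort("gene_set is empty.")
  missing <- setdiff(gene_set, genes$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("gene_set has gene(s) outside the universe: %s",
      paste(head(missing, 5L), collapse = ", ")))
  }
  N <- nrow(genes)
  K <- length(unique(gene_set))
  res <- genes |>
    mutate(in_set = .data$gene_id %in% gene_set) |>
    group_by(.data$chrom) |>
    summarise(k = sum(.data$in_set), m = dplyr::n(), .groups = "drop") |>
    mutate(
      K = K, N = N,
      p = phyper(.data$k - 1, .data$m, N - .data$m, K, lower.tail = FALSE),
      padj = bh_adjust(.data$p)
    ) |>
    arrange(.data$p)
  res
}

universe_genes <- function(universe) {
  if (inherits(universe, "sofdex_genome")) universe <- universe$genes
  assert_cols(universe, c("gene_id", "chrom", "tss"), arg = "universe")
  universe
}

#' Positional scan for contiguous enriched regions
#'
#' Evaluates every window of consecutive position-sorted universe genes
#' (up to `max_region_genes` long) on each chromosome with the
#' hypergeometric upper tail, BH-adjusts over all tested windows, and
#' greedily reports non-overlapping regions in order of ascending adjusted
#' p (ties broken by raw p, then smaller gene span, then leftmost) with
#' `padj < alpha`. This is an exhaustive bounded-window analog of
#' positional gene-enrichment scans.
#'
#' @param gene_set character vector of gene ids.
#' @param universe a `sofdex_genome` or tibble `gene_id`, `chrom`, `tss`.
#' @param max_region_genes maximum window length in genes (default 100).
#' @param alpha adjusted-p threshold for reporting (default 0.05).
#' @return tibble of regions: `chrom`, `first_gene`, `last_gene`
#'   (indices in the position-sorted per-chromosome universe), `start`,
#'   `end` (genomic span in bp, 0-based; `end` = last TSS + 1), `k`, `m`,
#'   `K`, `N`, `p`, `padj`.
#' @export
positional_scan <- function(gene_set, universe, max_region_genes = 100,
                            alpha = 0.05) {
  genes <- universe_genes(universe)
  N <- nrow(genes)
  K <- length(intersect(unique(gene_set), genes$gene_id))
  if (N == 0L || K == 0L) {
    return(empty_regions())
  }
  windows <- genes |>
    mutate(in_set = .data$gene_id %in% gene_set) |>
    group_by(.data$chrom) |>
    group_split() |>
    map(function(df) {
      df <- df |> arrange(.data$tss)
      n_c <- nrow(df)
      cs <- c(0, cumsum(df$in_set))
      lens <- seq_len(min(max_region_genes, n_c))
      grid <- list_rbind(map(lens, function(L) {
        first <- seq_len(n_c - L + 1L)
        tibble(
          chrom = df$chrom[1],
          first_gene = first,
          last_gene = first + L - 1L,
          start = df$tss[first],
          end = df$tss[first + L - 1L] + 1,
          k = as.integer(cs[first + L] - cs[first]),
          m = L
        )
      }))
      grid
    }) |>
    list_rbind()
  windows <- windows |>
    mutate(
      K = K, N = N,
      p = phyper(.data$k - 1, K, N - K, .data$m, lower.tail = FALSE)
    )
  windows$padj <- bh_adjust(windows$p)
  cand <- windows |>
    filter(.data$padj < alpha, .data$k > 0) |>
    arrange(.data$padj, .data$p, .data$m, .data$chrom, .data$first_gene)
  # greedy non-overlapping selection (per-chromosome gene-index overlap)
  keep <- logical(nrow(cand))
  occupied <- new.env(parent = emptyenv())
  ch <- cand$chrom; fg <- cand$first_gene; lg <- cand$last_gene
  for (i in seq_len(nrow(cand))) {
    occ <- get0(ch[i], envir = occupied, inherits = FALSE)
    if (!is.null(occ) && any(fg[i] <= occ$last & lg[i] >= occ$first)) next
    assign(ch[i], list(
      first = c(occ$first, fg[i]), last = c(occ$last, lg[i])
    ), envir = occupied)
    keep[i] <- TRUE
  }
  if (!any(keep)) {
    return(empty_regions())
  }
  cand[keep, , drop = FALSE]
}

empty_regions <- function() {
  tibble(
    chrom = character(), first_gene = integer(), last_gene = integer(),
    start = numeric(), end = numeric(), k = integer(), m = integer(),
    K = integer(), N = integer(), p = numeric(), padj = numeric()
  )
}
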