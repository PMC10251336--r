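#' Simulate negative-binomial 4sU-seq counts for the genotype x time design
#'
#' Draws gene x sample counts from NB(mean = sizefactor * baseline *
#' 2^log2FC, dispersion alpha) with Var = mu + alpha * mu^2, where the
#' per-gene log2FC is determined by the gene's truth class, the sample's
#' genotype and the treatment time (see [sim_params()]). Time 0 samples are
#' ethanol (vehicle) controls; all later times are dexamethasone-treated.
#' With `dispersion = 0` counts are Poisson.
#'
#' @param genome a [simulate_genome()] result (carries the truth labels).
#' @param params the [sim_params()] used to build the genome.
#' @param seed integer seed for reproducibility.
#'
#' @return a list with
#'   \item{counts}{tibble: `gene_id` plus one integer column per sample}
#'   \item{design}{tibble: `sample_id`, `genotype`, `treatment`
#'     (`ethanol` at time 0, `dex` otherwise), `time` (h), `replicate`}
#'   \item{size_factors}{named numeric, the true library-size factors}
#' @export
simulate_counts <- function(genome, params = sim_params(), seed = NULL) {
  stopifnot(inherits(genome, "sofdex_genome"), inherits(params, "sofdex_params"))
  with_seed_if(seed, {
    design <- tidyr::expand_grid(
      genotype = params$genotypes,
      time = params$times,
      replicate = seq_len(params$n_replicates)
    ) |>
      mutate(
        treatment = if_else(.data$time == 0, "ethanol", "dex"),
        sample_id = sprintf("%s_t%g_r%d", .data$genotype, .data$time, .data$replicate)
      ) |>
      select("sample_id", "genotype", "treatment", "time", "replicate")

    n_genes <- nrow(genome$genes)
    n_samples <- nrow(design)
    sf <- exp(runif(n_samples, log(params$libsize_range[1]), log(params$libsize_range[2])))
    names(sf) <- design$sample_id
    baseline <- exp(rnorm(n_genes, params$baseline_meanlog, params$baseline_sdlog))

    # per-gene, per-condition log2FC matrix
    l2fc <- matrix(0, n_genes, n_samples)
    for (j in seq_len(n_samples)) {
      gt <- design$genotype[j]
      tt <- design$time[j]
      l2fc[, j] <- vapply(seq_len(n_genes), function(i) {
        class_log2fc(
          genome$genes$class[i], gt, tt, genome$genes$l2fc_max[i], params
        )
      }, numeric(1))
    }
    mu <- baseline * 2^l2fc * rep(sf, each = n_genes)
    counts <- if (params$dispersion == 0) {
      matrix(rpois(length(mu), mu), n_genes, n_samples)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / params$dispersion),
        n_genes, n_samples)
    }
    colnames(counts) <- design$sample_id
    counts_tbl <- bind_cols(
      tibble(gene_id = genome$genes$gene_id),
      as_tibble(counts)
    )
    list(counts = counts_tbl, design = design, size_factors = sf)
  })
}

#' Simulate ChIP peaks enriched near direct-target TSSs
#'
#' Each direct dexamethasone target (`direct_dex` or `sof_dexdep`) receives
#' one peak with probability `p_near`, centered uniformly within
#' `window` bp of its TSS; `n_background` peaks are placed uniformly over
#' the genome. Peaks are clipped to chromosome bounds and returned sorted.
#'
#' @param genome a [simulate_genome()] result.
#' @param p_near probability in \[0, 1\] that a direct-target TSS gets a
#'   nearby peak.
#' @param window half-width (bp) of the placement window around the TSS.
#' @param n_background number of uniformly placed background peaks.
#' @param peak_width width of each simulated peak in bp.
#' @param seed integer seed.
#'
#' @return tibble `chrom`, `start`, `end` (0-based half-open), `name`,
#'   sorted by chromosome then start.
#' @export
simulate_chip_peaks <- function(genome, p_near = 0.8, window = 30000,
                                n_background = 500, peak_width = 400,
                                seed = NULL) {
  stopifnot(inherits(genome, "sofdex_genome"))
  if (p_near < 0 || p_near > 1) abort("p_near must be in [0, 1].")
  if (window <= 0) abort("window must be > 0.")
  with_seed_if(seed, {
    chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    targets <- genome$genes |>
      filter(.data$class %in% c("direct_dex", "sof_dexdep"))
    near <- targets[runif(nrow(targets)) < p_near, , drop = FALSE]
    near_centers <- near$tss + round(runif(nrow(near), -window, window))
    near_tbl <- tibble(
      chrom = near$chrom,
      center = near_centers,
      name = sprintf("peak_near_%s", near$gene_id)
    )
    bg_chrom <- if (n_background > 0) {
      sample(genome$chromosomes$chrom, n_background,
        replace = TRUE, prob = genome$chromosomes$length)
    } else {
      character()
    }
    bg_tbl <- tibble(
      chrom = bg_chrom,
      center = floor(runif(n_background, 0, chrom_len[bg_chrom])),
      name = sprintf("peak_bg_%05d", seq_len(n_background))
    )
    peaks <- bind_rows(near_tbl, bg_tbl) |>
      mutate(
        start = pmax(0, .data$center - peak_width %/% 2),
        end = pmin(chrom_len[.data$chrom], .data$center + peak_width %/% 2)
      ) |>
      filter(.data$start < .data$end) |>
      select("chrom", "start", "end", "name") |>
      arrange(.data$chrom, .data$start, .data$end)
    peaks
  })
}
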