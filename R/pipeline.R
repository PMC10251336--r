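#' Run the end-to-end synthetic analysis pipeline
#'
#' Chains the stages: simulate (genome, counts, ChIP peaks), differential
#' expression (time-vs-baseline per genotype at the classification time
#' plus pooled SoF-vs-wt), gene-set classification, ChIP/TSS
#' co-occurrence with a shuffle null, and the positional enrichment scan.
#' All stage outputs plus a JSON summary (set sizes, overlap ratios,
#' enriched regions, and sensitivity/FDR against the simulation truth) are
#' written under `out_dir`; a manifest records every parameter and seed.
#' Two runs with the same config produce identical summaries.
#'
#' @param params a [sim_params()] object.
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; stage seeds are derived from it.
#' @param alpha significance level used throughout.
#' @param class_time treatment time (h) for the outlier classification.
#' @param window co-occurrence window in bp.
#' @param n_shuffles shuffle replicates for the co-occurrence null.
#' @param p_near,n_background ChIP-peak simulation parameters.
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(params = sim_params(), out_dir = tempfile("sofdex_run_"),
                         seed = 1, alpha = 0.05, class_time = 3,
                         window = 30000, n_shuffles = 50,
                         p_near = 0.8, n_background = 500) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(
    genome = seed, counts = seed + 1000L, peaks = seed + 2000L,
    shuffle = seed + 3000L, mcd = seed + 4000L
  )
  log_stage <- function(...) message(sprintf(...))

  log_stage("[simulate] genome + truth labels (seed %d)", seeds$genome)
  genome <- simulate_genome(params, seed = seeds$genome)
  sim <- simulate_counts(genome, params, seed = seeds$counts)
  peaks <- simulate_chip_peaks(genome,
    p_near = p_near, n_background = n_background, seed = seeds$peaks
  )
  chrom_sizes <- genome$chromosomes
  write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  write_design(sim$design, file.path(out_dir, "design.tsv"))
  write_bed(peaks, file.path(out_dir, "peaks.bed"))
  write_tss(genome$genes, file.path(out_dir, "tss.tsv"))
  readr::write_tsv(chrom_sizes, file.path(out_dir, "chrom.sizes"),
    col_names = FALSE)
  readr::write_tsv(
    genome$genes |> select("gene_id", "class", "cluster_id"),
    file.path(out_dir, "truth_labels.tsv")
  )

  log_stage("[de] size factors, dispersion, contrasts")
  sf <- median_of_ratios(sim$counts)
  disp <- estimate_dispersion(sim$counts, sim$design, sf)
  de_sof <- de_time_contrast(sim$counts, sim$design, "SoF", class_time, sf, disp)
  de_ctrl <- de_time_contrast(sim$counts, sim$design, "Ctrl", class_time, sf, disp)
  de_wt <- de_time_contrast(sim$counts, sim$design, "wt", class_time, sf, disp)
  de_sof_wt <- de_genotype_contrast(sim$counts, sim$design, "SoF", "wt", sf, disp)
  for (de in list(de_sof, de_ctrl, de_wt, de_sof_wt)) {
    readr::write_tsv(
      as_tibble(de),
      file.path(out_dir, sprintf("de_%s.tsv", attr(de, "contrast")))
    )
  }

  log_stage("[classify] regression + MCD outliers + constitutive sets")
  cls <- classify_gene_sets(de_sof, de_ctrl, de_sof_wt,
    alpha = alpha, mcd_seed = seeds$mcd
  )
  readr::write_tsv(cls$labels, file.path(out_dir, "gene_sets.tsv"))

  log_stage("[cooccur] relative distance + %d-bp window + %d shuffles",
    window, n_shuffles)
  dexdep_tss <- genome$genes |>
    filter(.data$gene_id %in%
      cls$labels$gene_id[cls$labels$class == "sof_dexdep"])
  cooccur <- NULL
  if (nrow(dexdep_tss) > 0L) {
    obs <- window_overlap_ratio(dexdep_tss, peaks, window)
    shuf_ratios <- vapply(seq_len(n_shuffles), function(i) {
      st <- shuffle_tss(dexdep_tss, chrom_sizes, seed = seeds$shuffle + i)
      window_overlap_ratio(st, peaks, window)$ratio
    }, numeric(1))
    cooccur <- list(
      observed_ratio = obs$ratio,
      shuffle_mean = mean(shuf_ratios),
      shuffle_sd = sd(shuf_ratios),
      expected_null = expected_shuffle_ratio(peaks, chrom_sizes, window)
    )
  }

  log_stage("[positional] chromosome + region scan for sof_dexind")
  dexind_ids <- cls$labels$gene_id[cls$labels$class == "sof_dexind"]
  regions <- empty_regions()
  chrom_enrich <- NULL
  if (length(dexind_ids) > 0L) {
    chrom_enrich <- chromosome_enrichment(dexind_ids, genome)
    regions <- positional_scan(dexind_ids, genome, alpha = alpha)
    readr::write_tsv(chrom_enrich, file.path(out_dir, "chromosome_enrichment.tsv"))
    readr::write_tsv(regions, file.path(out_dir, "enriched_regions.tsv"))
  }

  truth_metrics <- purrr::imap(
    list(sof_dexdep = "sof_dexdep", sof_dexind = "sof_dexind"),
    function(class, nm) {
      truth_ids <- genome$genes$gene_id[genome$genes$class == class]
      called <- cls$labels$gene_id[cls$labels$class == class]
      recovery_metrics(called, truth_ids)
    }
  )

  summary <- list(
    params = unclass(params),
    seeds = seeds,
    alpha = alpha,
    class_time = class_time,
    set_sizes = as.list(table(cls$labels$class)),
    regression = glance(cls$line),
    cooccurrence = cooccur,
    n_enriched_regions = nrow(regions),
    truth_metrics = truth_metrics
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  manifest <- list(params = unclass(params), seeds = seeds, alpha = alpha,
    class_time = class_time, window = window, n_shuffles = n_shuffles,
    p_near = p_near, n_background = n_background)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Sensitivity and FDR of a recovered gene set against truth
#'
#' @param called character vector of called gene ids.
#' @param truth character vector of true gene ids.
#' @return list `sensitivity`, `fdr`, `n_called`, `n_truth`.
#' @export
recovery_metrics <- function(called, truth) {
  tp <- length(intersect(called, truth))
  list(
    sensitivity = if (length(truth) > 0) tp / length(truth) else NA_real_,
    fdr = if (length(called) > 0) 1 - tp / length(called) else 0,
    n_called = length(called),
    n_truth = length(truth)
  )
}
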