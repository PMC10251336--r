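#' Simulate a gene annotation with truth-labeled gene classes
#'
#' Places `n_genes` transcription start sites (TSSs) on `n_chromosomes`
#' chromosomes and assigns each gene one of six truth classes. Genes of the
#' dexamethasone-independent SoF-up class (`sof_dexind`) are partly planted
#' as runs of consecutive genes on a small set of designated chromosomes,
#' emulating contiguous chromosomal clustering of such genes; all other
#' classes are placed uniformly at random over gene indices.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; the same seed reproduces the genome exactly.
#'
#' @return a list of class `sofdex_genome` with elements
#'   \item{chromosomes}{tibble `chrom`, `length`}
#'   \item{genes}{tibble `gene_id`, `chrom`, `tss` (0-based bp), `strand`,
#'     `class`, `cluster_id` (NA except for planted runs), and `l2fc_max`,
#'     the per-gene 3-h dex-response magnitude used by [simulate_counts()]}
#' @export
simulate_genome <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sofdex_params"))
  with_seed_if(seed, {
    chromosomes <- tibble(
      chrom = sprintf("chr%d", seq_len(params$n_chromosomes)),
      length = rep(params$chrom_length, params$n_chromosomes)
    )
    n <- params$n_genes
    if (n == 0L) {
      genes <- tibble(
        gene_id = character(), chrom = character(), tss = numeric(),
        strand = character(), class = character(), cluster_id = integer(),
        l2fc_max = numeric()
      )
      return(structure(list(chromosomes = chromosomes, genes = genes),
        class = "sofdex_genome"))
    }
    # genes per chromosome proportional to length (equal lengths -> near-even)
    chrom_of <- sort(sample.int(params$n_chromosomes, n,
      replace = TRUE,
      prob = chromosomes$length
    ))
    pos <- unlist(lapply(split(seq_len(n), chrom_of), function(idx) {
      sort(floor(runif(length(idx), 0, params$chrom_length)))
    }), use.names = FALSE)
    genes <- tibble(
      gene_id = sprintf("gene%05d", seq_len(n)),
      chrom = chromosomes$chrom[chrom_of],
      tss = pos,
      strand = "+",
      class = "background",
      cluster_id = NA_integer_,
      l2fc_max = 0
    )

    # plant clustered sof_dexind runs first, on designated chromosomes
    n_dexind <- params$n_sof_dexind
    n_clustered <- round(params$cluster_fraction * n_dexind)
    k_chroms <- min(params$n_cluster_chroms, params$n_chromosomes)
    taken <- rep(FALSE, n)
    if (n_clustered > 0 && k_chroms > 0) {
      run_chroms <- sample(chromosomes$chrom, k_chroms)
      run_sizes <- diff(round(seq(0, n_clustered, length.out = k_chroms + 1)))
      for (i in seq_len(k_chroms)) {
        if (run_sizes[i] == 0) next
        idx_on <- which(genes$chrom == run_chroms[i] & !taken)
        # need a run of consecutive untaken gene indices on this chromosome
        if (length(idx_on) < run_sizes[i]) {
          abort("not enough genes on designated chromosome to plant a run.")
        }
        start <- sample.int(length(idx_on) - run_sizes[i] + 1L, 1L)
        run <- idx_on[start:(start + run_sizes[i] - 1L)]
        genes$class[run] <- "sof_dexind"
        genes$cluster_id[run] <- i
        taken[run] <- TRUE
      }
    }

    # remaining classes uniform over untaken gene indices
    remaining <- c(
      rep("direct_dex", params$n_direct),
      rep("sof_dexdep", params$n_sof_dexdep),
      rep("sof_3h_rep", params$n_sof_3h_rep),
      rep("sof_dexind", n_dexind - n_clustered),
      rep("sof_const_rep", params$n_sof_const_rep)
    )
    free <- which(!taken)
    pick <- sample(free, length(remaining))
    genes$class[pick] <- remaining

    # per-gene dex-response magnitude at 3 h
    is_direct <- genes$class == "direct_dex"
    is_planted <- genes$class %in% c("sof_dexdep", "sof_3h_rep")
    genes$l2fc_max[is_direct] <- runif(
      sum(is_direct), params$direct_l2fc[1], params$direct_l2fc[2]
    )
    genes$l2fc_max[is_planted] <- runif(
      sum(is_planted), params$planted_l2fc[1], params$planted_l2fc[2]
    )

    structure(list(chromosomes = chromosomes, genes = genes),
      class = "sofdex_genome")
  })
}

#' @export
print.sofdex_genome <- function(x, ...) {
  cat(sprintf(
    "<sofdex_genome> %d genes on %d chromosome(s)\n",
    nrow(x$genes), nrow(x$chromosomes)
  ))
  print(table(x$genes$class))
  invisible(x)
}
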