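#' Simulation parameters for the synthetic study design
#'
#' Builds the parameter block consumed by [simulate_genome()],
#' [simulate_counts()] and [simulate_chip_peaks()]. Defaults emulate the
#' statistical structure of a three-genotype (wt, SoF, Ctrl glucocorticoid
#' receptor) dexamethasone time course at 0, 1, 2 and 3 h: negative-binomial
#' counts with class-specific log2 fold-change trajectories, a SoF-amplified
#' subset of direct dexamethasone targets, dexamethasone-independent SoF-up
#' genes partly clustered on a few chromosomes, and constitutively repressed
#' genes.
#'
#' Gene classes and their default trajectories (log2 fold change relative to
#' the genotype's own untreated baseline, linear ramp over 0--3 h):
#' \describe{
#'   \item{background}{no effect anywhere.}
#'   \item{direct_dex}{dex-activated equally in all genotypes; per-gene
#'     3-h log2FC drawn Uniform(`direct_l2fc[1]`, `direct_l2fc[2]`).}
#'   \item{sof_dexdep}{dex-activated, with the response log2FC multiplied by
#'     `amplification` in the SoF genotype only.}
#'   \item{sof_3h_rep}{dex-activated, with the response multiplied by
#'     `repression_factor` (< 1) in the SoF genotype (higher fold change in
#'     Ctrl).}
#'   \item{sof_dexind}{constant `dexind_l2fc` in SoF at every time including
#'     0 h; a fraction `cluster_fraction` of them is planted as runs of
#'     consecutive genes on `n_cluster_chroms` chromosomes.}
#'   \item{sof_const_rep}{constant `const_rep_l2fc` (negative) in SoF.}
#' }
#'
#' @param n_genes total number of genes.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_direct,n_sof_dexdep,n_sof_3h_rep,n_sof_dexind,n_sof_const_rep
#'   class sizes; the remainder is background.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   mean expression.
#' @param dispersion negative-binomial dispersion alpha in
#'   Var = mu + alpha * mu^2; must be >= 0 (0 gives Poisson counts).
#' @param direct_l2fc,planted_l2fc length-2 ranges of the per-gene 3-h
#'   dex-response log2FC for direct targets and for the planted SoF sets.
#' @param amplification multiplier (> 0) on the dex-response log2FC in the
#'   SoF genotype for `sof_dexdep` genes.
#' @param repression_factor multiplier on the dex response in SoF for
#'   `sof_3h_rep` genes.
#' @param dexind_l2fc,const_rep_l2fc constant SoF-vs-wt log2FC of the
#'   dex-independent and constitutively repressed classes.
#' @param cluster_fraction fraction of `sof_dexind` genes placed as
#'   contiguous runs.
#' @param n_cluster_chroms number of chromosomes carrying those runs.
#' @param n_replicates replicates per genotype x time condition (>= 2).
#' @param libsize_range range of library-size factors, drawn log-uniform.
#' @param times treatment times in hours; time 0 is the ethanol control.
#' @param genotypes genotype labels; the first is the wild-type reference.
#'
#' @return a list of class `sofdex_params`.
#' @export
sim_params <- function(n_genes = 2000,
                       n_chromosomes = 10,
                       chrom_length = 5e7,
                       n_direct = 150,
                       n_sof_dexdep = 50,
                       n_sof_3h_rep = 25,
                       n_sof_dexind = 60,
                       n_sof_const_rep = 60,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1,
                       dispersion = 0.05,
                       direct_l2fc = c(0.5, 3),
                       planted_l2fc = c(1.5, 3),
                       amplification = 2.5,
                       repression_factor = 0.5,
                       dexind_l2fc = 1.5,
                       const_rep_l2fc = -1.5,
                       cluster_fraction = 0.35,
                       n_cluster_chroms = 3,
                       n_replicates = 3,
                       libsize_range = c(0.5, 2),
                       times = c(0, 1, 2, 3),
                       genotypes = c("wt", "SoF", "Ctrl")) {
  p <- as.list(environment())
  n_classed <- n_direct + n_sof_dexdep + n_sof_3h_rep + n_sof_dexind +
    n_sof_const_rep
  if (n_genes < 0) abort("n_genes must be >= 0.")
  if (n_genes > 0 && n_classed > n_genes) {
    abort("class sizes exceed n_genes.")
  }
  if (p$dispersion < 0) abort("dispersion must be >= 0.")
  if (p$n_replicates < 2) abort("n_replicates must be >= 2.")
  if (p$amplification <= 0) abort("amplification must be > 0.")
  if (p$cluster_fraction < 0 || p$cluster_fraction > 1) {
    abort("cluster_fraction must be in [0, 1].")
  }
  if (p$n_chromosomes < 1) abort("n_chromosomes must be >= 1.")
  # enough room for all genes at >= 1 bp spacing
  if (n_genes > n_chromosomes * chrom_length) {
    abort("n_genes exceeds what the chromosome lengths can hold.")
  }
  structure(p, class = "sofdex_params")
}

gene_classes <- c(
  "background", "direct_dex", "sof_dexdep", "sof_3h_rep",
  "sof_dexind", "sof_const_rep"
)

# log2FC of a gene at a given genotype/time given its class and per-gene
# 3-h response magnitude b. Ramp is linear in time over [0, max(times)].
class_log2fc <- function(class, genotype, time, b, params) {
  ramp <- if (max(params$times) > 0) time / max(params$times) else 0
  switch(class,
    background = 0,
    direct_dex = b * ramp,
    sof_dexdep = b * ramp * if (genotype == "SoF") params$amplification else 1,
    sof_3h_rep = b * ramp * if (genotype == "SoF") params$repression_factor else 1,
    sof_dexind = if (genotype == "SoF") params$dexind_l2fc else 0,
    sof_const_rep = if (genotype == "SoF") params$const_rep_l2fc else 0,
    abort(sprintf("unknown gene class '%s'", class))
  )
}
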