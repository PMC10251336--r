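# Small fixtures built in code, shared across test files.

# tiny deterministic count table: genes x samples as a tibble
make_counts <- function(mat, gene_ids = sprintf("g%d", seq_len(nrow(mat))),
                        sample_ids = sprintf("s%d", seq_len(ncol(mat)))) {
  colnames(mat) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), tibble::as_tibble(mat))
}

make_design <- function(sample_ids, genotype = "wt", treatment = "ethanol",
                        time = 0, replicate = seq_along(sample_ids)) {
  tibble::tibble(
    sample_id = sample_ids,
    genotype = rep_len(genotype, length(sample_ids)),
    treatment = rep_len(treatment, length(sample_ids)),
    time = rep_len(time, length(sample_ids)),
    replicate = replicate
  )
}

# simple two-group design: n per group, groups A (dex 3 h) and B (t0)
two_group_design <- function(n_a, n_b, genotype = "wt") {
  rbind(
    make_design(sprintf("a%d", seq_len(n_a)), genotype, "dex", 3, seq_len(n_a)),
    make_design(sprintf("b%d", seq_len(n_b)), genotype, "ethanol", 0, seq_len(n_b))
  )
}

# brute-force BH step-up, independent of the implementation
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- rep(NA_real_, m)
  out[o] <- q
  out
}

# exhaustive-minimum MCD determinant over all h-subsets (oracle, n small)
mcd_bruteforce_det <- function(x, h) {
  subsets <- utils::combn(nrow(x), h)
  dets <- apply(subsets, 2, function(idx) det(stats::cov(x[idx, , drop = FALSE])))
  min(dets)
}

# exhaustive Otsu: maximize between-class variance over all bin boundaries
otsu_bruteforce <- function(v, n_bins = 256) {
  lo <- min(v); hi <- max(v)
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  best_sigma <- -Inf
  best_t <- NA_real_
  for (b in seq_len(n_bins - 1)) {
    w0 <- sum(counts[1:b]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:b] * mids[1:b]) / w0
    mu1 <- sum(counts[(b + 1):n_bins] * mids[(b + 1):n_bins]) / w1
    sigma <- w0 * w1 * (mu0 - mu1)^2
    if (sigma > best_sigma + 1e-12) {
      best_sigma <- sigma
      best_t <- breaks[b + 1]
    }
  }
  best_t
}

# standard small simulation used by several end-to-end tests
small_sim_pipeline <- function(seed, params = sim_params()) {
  g <- simulate_genome(params, seed = seed)
  sim <- simulate_counts(g, params, seed = seed + 100)
  sf <- median_of_ratios(sim$counts)
  disp <- estimate_dispersion(sim$counts, sim$design, sf)
  list(genome = g, sim = sim, sf = sf, disp = disp)
}
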