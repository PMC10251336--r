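#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against a geometric-mean
#' pseudo-reference: the reference for each gene is the geometric mean of
#' its counts over all samples, computed on genes with no zero count; each
#' sample's size factor is the median over those genes of count/reference.
#'
#' @param counts tibble: `gene_id` plus one numeric column per sample.
#' @param pseudo_reference if `TRUE`, fall back to a positive-count
#'   geometric mean (zeros ignored in the per-gene log mean, but the
#'   divisor stays the number of samples) so that data with no zero-free
#'   gene can still be normalized.
#'
#' @return tibble `sample_id`, `size_factor`.
#' @export
median_of_ratios <- function(counts, pseudo_reference = FALSE) {
  mat <- counts_to_matrix(counts)
  if (ncol(mat) < 1L) abort("counts has no sample columns.")
  if (!pseudo_reference) {
    keep <- rowSums(mat == 0) == 0
    if (!any(keep)) {
      abort(paste(
        "no gene has all-positive counts;",
        "re-run with pseudo_reference = TRUE to use a positive-count",
        "geometric-mean reference."
      ))
    }
    ref <- exp(rowMeans(log(mat[keep, , drop = FALSE])))
    ratios <- mat[keep, , drop = FALSE] / ref
  } else {
    logmat <- log(mat)
    logmat[!is.finite(logmat)] <- NA
    ref <- exp(rowSums(logmat, na.rm = TRUE) / ncol(mat))
    keep <- rowSums(!is.na(logmat)) > 0
    ref <- ref[keep]
    ratios <- mat[keep, , drop = FALSE] / ref
    ratios[mat[keep, , drop = FALSE] == 0] <- NA
  }
  sf <- apply(ratios, 2, median, na.rm = TRUE)
  tibble(sample_id = colnames(mat), size_factor = unname(sf))
}

#' Method-of-moments negative-binomial dispersion estimates
#'
#' Estimates the per-gene NB dispersion alpha (Var = mu + alpha * mu^2) by
#' the method of moments on size-factor-normalized counts within each
#' condition group (genotype x treatment x time), pooling the per-group
#' estimates weighted by degrees of freedom, then flooring at `alpha_min`.
#' Genes whose variance does not exceed their mean get the floor.
#'
#' @param counts tibble: `gene_id` plus one column per sample.
#' @param design tibble with `sample_id`, `genotype`, `treatment`, `time`,
#'   `replicate` covering all samples.
#' @param size_factors optional tibble from [median_of_ratios()]; computed
#'   if missing.
#' @param alpha_min dispersion floor.
#'
#' @return tibble `gene_id`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, design, size_factors = NULL,
                                alpha_min = 1e-8) {
  mat <- counts_to_matrix(counts)
  check_design(design, colnames(mat))
  if (is.null(size_factors)) size_factors <- median_of_ratios(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(mat)]
  norm <- sweep(mat, 2, sf, "/")
  design <- design[match(colnames(mat), design$sample_id), ]
  group <- interaction(design$genotype, design$treatment, design$time, drop = TRUE)
  sizes <- table(group)
  if (all(sizes < 2)) {
    abort("dispersion estimation needs >= 2 replicates in some condition.")
  }
  num <- rep(0, nrow(mat)) # sum over groups of df * alpha_g
  den <- 0
  for (g in levels(group)) {
    cols <- which(group == g)
    if (length(cols) < 2L) next
    sub <- norm[, cols, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, var)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    df <- length(cols) - 1L
    num <- num + df * a
    den <- den + df
  }
  alpha <- pmax(alpha_min, num / den)
  tibble(gene_id = rownames(mat), dispersion = alpha)
}

#' Negative-binomial Wald test between two sample groups
#'
#' Fits per-gene normalized group means and tests their log2 ratio with a
#' Wald statistic. The log2 fold change is
#' `log2(mean_A / mean_B)` of size-factor-normalized counts, so a positive
#' value means higher expression in `samples_a` (the treated/mutant group
#' by convention). The standard error comes from the NB variance
#' `mu + alpha * mu^2` by the delta method on the log of the mean
#' estimator. Genes with zero counts in both groups are excluded (flagged,
#' no statistics); genes with a zero mean in exactly one group get an
#' infinite log2FC and `NA` p-value.
#'
#' @param counts,design as in [estimate_dispersion()].
#' @param samples_a,samples_b character vectors of sample ids defining the
#'   contrast groups (A vs B; B is the baseline).
#' @param size_factors optional tibble from [median_of_ratios()] computed
#'   on the full count table; computed if missing.
#' @param dispersion optional tibble from [estimate_dispersion()];
#'   computed if missing.
#' @param contrast name to attach to the result.
#'
#' @return tibble of class `sofdex_de`: `gene_id`, `baseMean`, `log2FC`,
#'   `SE`, `pvalue`, `padj`, `excluded`.
#' @export
nb_wald_test <- function(counts, design, samples_a, samples_b,
                         size_factors = NULL, dispersion = NULL,
                         contrast = "A_vs_B") {
  mat <- counts_to_matrix(counts)
  check_design(design, colnames(mat))
  if (length(samples_a) == 0L || length(samples_b) == 0L) {
    abort(sprintf("contrast '%s' has an empty group.", contrast))
  }
  missing <- setdiff(c(samples_a, samples_b), colnames(mat))
  if (length(missing) > 0L) {
    abort(sprintf(
      "contrast '%s' names unknown sample(s): %s",
      contrast, paste(missing, collapse = ", ")
    ))
  }
  if (is.null(size_factors)) size_factors <- median_of_ratios(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(mat)]
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, design, size_factors)
  alpha <- setNames(dispersion$dispersion, dispersion$gene_id)[rownames(mat)]

  norm <- sweep(mat, 2, sf, "/")
  a <- norm[, samples_a, drop = FALSE]
  b <- norm[, samples_b, drop = FALSE]
  qa <- rowMeans(a)
  qb <- rowMeans(b)
  sfa <- sf[samples_a]
  sfb <- sf[samples_b]

  # Var(q_hat) for q_hat = mean_i(y_i / s_i), y_i ~ NB(s_i q, alpha):
  # (1/n^2) * sum_i (q / s_i + alpha q^2)
  var_q <- function(q, s) (q * sum(1 / s) + length(s) * alpha * q^2) / length(s)^2
  va <- var_q(qa, sfa)
  vb <- var_q(qb, sfb)
  # delta method on log2 q
  se <- sqrt(va / qa^2 + vb / qb^2) / log(2)

  excluded <- qa == 0 & qb == 0
  log2fc <- log2(qa / qb)
  z <- log2fc / se
  pvalue <- 2 * pnorm(-abs(z))
  one_zero <- xor(qa == 0, qb == 0)
  pvalue[one_zero] <- NA_real_
  log2fc[one_zero] <- ifelse(qa[one_zero] == 0, -Inf, Inf)
  se[one_zero] <- NA_real_

  base_mean <- rowMeans(norm[, c(samples_a, samples_b), drop = FALSE])
  res <- tibble(
    gene_id = rownames(mat),
    baseMean = unname(base_mean),
    log2FC = unname(log2fc),
    SE = unname(se),
    pvalue = unname(pvalue),
    padj = unname(bh_adjust(replace(pvalue, excluded, NA))),
    excluded = unname(excluded)
  )
  res$log2FC[excluded] <- NA_real_
  res$SE[excluded] <- NA_real_
  res$pvalue[excluded] <- NA_real_
  attr(res, "contrast") <- contrast
  class(res) <- c("sofdex_de", class(res))
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Missing values are excluded from the number of tests `m` and propagate
#' as `NA` in the output; original order is preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (or `NA`).
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Time-point-vs-baseline contrast within a genotype
#'
#' Mirrors the design in which each dexamethasone treatment time is tested
#' against that genotype's own untreated (time 0, ethanol) samples.
#'
#' @inheritParams nb_wald_test
#' @param genotype genotype to test within.
#' @param time treatment time (h) of the test group.
#' @return a `sofdex_de` tibble (see [nb_wald_test()]).
#' @export
de_time_contrast <- function(counts, design, genotype, time,
                             size_factors = NULL, dispersion = NULL) {
  check_design(design)
  a <- design$sample_id[design$genotype == genotype & design$time == time]
  b <- design$sample_id[design$genotype == genotype & design$time == 0]
  nb_wald_test(counts, design, a, b,
    size_factors = size_factors, dispersion = dispersion,
    contrast = sprintf("%s_t%g_vs_t0", genotype, time)
  )
}

#' Mutant-vs-wild-type contrast pooled over treatment times
#'
#' Tests a mutant genotype against the wild-type reference using all
#' samples of each genotype regardless of treatment time ("ignorant of
#' treatment time" pooling).
#'
#' @inheritParams nb_wald_test
#' @param genotype mutant genotype (group A).
#' @param reference reference genotype (group B), default `"wt"`.
#' @return a `sofdex_de` tibble (see [nb_wald_test()]).
#' @export
de_genotype_contrast <- function(counts, design, genotype, reference = "wt",
                                 size_factors = NULL, dispersion = NULL) {
  check_design(design)
  a <- design$sample_id[design$genotype == genotype]
  b <- design$sample_id[design$genotype == reference]
  nb_wald_test(counts, design, a, b,
    size_factors = size_factors, dispersion = dispersion,
    contrast = sprintf("%s_vs_%s", genotype, reference)
  )
}

#' @export
tidy.sofdex_de <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.sofdex_de <- function(x, alpha = 0.05, ...) {
  tibble(
    contrast = attr(x, "contrast") %||% NA_character_,
    n_genes = nrow(x),
    n_excluded = sum(x$excluded),
    n_significant = sum(x$padj < alpha, na.rm = TRUE)
  )
}
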