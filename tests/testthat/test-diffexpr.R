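test_that("median_of_ratios matches the geometric-mean-reference definition", {
  # sample 2 is exactly double sample 1 -> factors (1/sqrt(2), sqrt(2))
  m <- matrix(c(10, 20, 50, 20, 40, 100), ncol = 2)
  sf <- median_of_ratios(make_counts(m))
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical samples -> all factors 1
  m2 <- matrix(rep(c(3, 7, 11), 3), ncol = 3)
  expect_equal(median_of_ratios(make_counts(m2))$size_factor, c(1, 1, 1))

  # [[0,5],[10,10]] genes x samples: reference uses gene 2 only -> (1,1)
  m3 <- matrix(c(0, 10, 5, 10), ncol = 2)
  expect_equal(median_of_ratios(make_counts(m3))$size_factor, c(1, 1))
})

test_that("median_of_ratios errors without a zero-free gene, offering the fallback", {
  m <- matrix(c(0, 5, 5, 0), ncol = 2)
  expect_error(median_of_ratios(make_counts(m)), "pseudo_reference")
  sf <- median_of_ratios(make_counts(m), pseudo_reference = TRUE)
  expect_true(all(is.finite(sf$size_factor) & sf$size_factor > 0))
})

test_that("size factors scale linearly with a sample's counts", {
  withr::with_seed(4, {
    m <- matrix(rpois(60, 50) + 1, ncol = 3)
  })
  sf <- median_of_ratios(make_counts(m))
  m_scaled <- m
  m_scaled[, 2] <- m[, 2] * 3
  sf2 <- median_of_ratios(make_counts(m_scaled))
  # multiplying one sample by c multiplies its factor by c (relative to the
  # unchanged geometric-mean reference the other factors shift by c^(-1/n))
  expect_equal(sf2$size_factor[2] / sf$size_factor[2],
    3 * (sf2$size_factor[1] / sf$size_factor[1]), tolerance = 1e-12)
})

test_that("dispersion estimation matches its contract", {
  des <- two_group_design(6, 6)
  # Poisson counts -> median alpha near the floor
  withr::with_seed(8, {
    m <- matrix(rpois(500 * 12, 200), ncol = 12)
  })
  counts <- make_counts(m, sample_ids = des$sample_id)
  disp <- estimate_dispersion(counts, des)
  expect_lte(median(disp$dispersion), 0.01)

  # constant counts within groups -> exactly the floor
  m2 <- matrix(rep(c(rep(10, 6), rep(40, 6)), each = 1), nrow = 1)
  counts2 <- make_counts(m2, sample_ids = des$sample_id)
  sf1 <- tibble::tibble(sample_id = des$sample_id, size_factor = 1)
  disp2 <- estimate_dispersion(counts2, des, sf1)
  expect_equal(disp2$dispersion, 1e-8)

  # NB alpha = 0.1 recovered within [0.05, 0.2] in the median
  withr::with_seed(9, {
    m3 <- matrix(rnbinom(2000 * 12, mu = 300, size = 1 / 0.1), ncol = 12)
  })
  counts3 <- make_counts(m3, sample_ids = des$sample_id)
  disp3 <- estimate_dispersion(counts3, des, sf1)
  expect_gte(median(disp3$dispersion), 0.05)
  expect_lte(median(disp3$dispersion), 0.2)

  # single replicate everywhere -> error
  des1 <- make_design(c("s1", "s2"), genotype = c("wt", "SoF"))
  counts1 <- make_counts(matrix(c(5, 6), nrow = 1), sample_ids = des1$sample_id)
  expect_error(estimate_dispersion(counts1, des1, NULL), "replicates")
})

test_that("nb_wald_test fixes the log2FC convention and handles zeros", {
  des <- two_group_design(2, 2)
  counts <- make_counts(
    matrix(c(200, 200, 100, 100), nrow = 1),
    sample_ids = des$sample_id
  )
  sf <- tibble::tibble(sample_id = des$sample_id, size_factor = 1)
  disp <- tibble::tibble(gene_id = "g1", dispersion = 1e-12)
  res <- nb_wald_test(counts, des, c("a1", "a2"), c("b1", "b2"), sf, disp)
  expect_identical(res$log2FC, 1) # exactly, the ratio is forced

  # identical groups -> log2FC 0, p = 1
  counts0 <- make_counts(
    matrix(c(50, 50, 50, 50), nrow = 1), sample_ids = des$sample_id
  )
  res0 <- nb_wald_test(counts0, des, c("a1", "a2"), c("b1", "b2"), sf, disp)
  expect_identical(res0$log2FC, 0)
  expect_equal(res0$pvalue, 1)

  # all-zero gene excluded, no statistics; one-sided zero -> +/-Inf, NA p
  m <- matrix(c(
    0, 0, 0, 0,
    9, 11, 0, 0,
    0, 0, 9, 11
  ), nrow = 3, byrow = TRUE)
  counts2 <- make_counts(m, sample_ids = des$sample_id)
  disp2 <- tibble::tibble(gene_id = sprintf("g%d", 1:3), dispersion = 0.01)
  res2 <- nb_wald_test(counts2, des, c("a1", "a2"), c("b1", "b2"), sf, disp2)
  expect_identical(res2$excluded, c(TRUE, FALSE, FALSE))
  expect_true(is.na(res2$pvalue[1]) && is.na(res2$log2FC[1]))
  expect_identical(res2$log2FC[2:3], c(Inf, -Inf))
  expect_true(all(is.na(res2$pvalue[2:3])))

  # empty group -> error naming the contrast
  expect_error(
    nb_wald_test(counts, des, character(), c("b1", "b2"), sf, disp,
      contrast = "my_contrast"),
    "my_contrast"
  )
})

test_that("log2FC sign always matches the normalized group-mean difference", {
  des <- two_group_design(3, 3)
  withr::with_seed(15, {
    m <- matrix(rnbinom(200 * 6, mu = 100, size = 20), ncol = 6)
  })
  counts <- make_counts(m, sample_ids = des$sample_id)
  sf <- median_of_ratios(counts)
  res <- nb_wald_test(counts, des, sprintf("a%d", 1:3), sprintf("b%d", 1:3),
    sf, estimate_dispersion(counts, des, sf))
  mat <- as.matrix(m)
  norm <- sweep(mat, 2, sf$size_factor, "/")
  diff <- rowMeans(norm[, 1:3]) - rowMeans(norm[, 4:6])
  ok <- !res$excluded & is.finite(res$log2FC)
  expect_true(all(sign(res$log2FC[ok]) == sign(diff[ok])))
})

test_that("null p-values are approximately uniform", {
  des <- two_group_design(6, 6)
  withr::with_seed(22, {
    mu <- exp(rnorm(1500, log(500), 0.5))
    m <- matrix(rnbinom(1500 * 12, mu = rep(mu, 12), size = 1 / 0.05), ncol = 12)
  })
  counts <- make_counts(m, sample_ids = des$sample_id)
  sf <- tibble::tibble(sample_id = des$sample_id, size_factor = 1)
  disp <- tibble::tibble(
    gene_id = sprintf("g%d", 1:1500), dispersion = 0.05
  )
  res <- nb_wald_test(counts, des, sprintf("a%d", 1:6), sprintf("b%d", 1:6),
    sf, disp)
  p <- res$pvalue[!is.na(res$pvalue)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # and no padj significance beyond the nominal FDR under this null
  frac <- mean(res$padj < 0.05, na.rm = TRUE)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("bh_adjust implements step-up and handles missing values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.5)), "\\[0, 1\\]")

  # NA excluded from m, propagated in place
  out <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_adjust(c(0.01, 0.04)))

  # brute-force equivalence on random vectors
  withr::with_seed(7, {
    for (n in c(1, 5, 100, 1000)) {
      p <- runif(n)
      expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    }
  })
})

test_that("contrast helpers pick the documented sample groups", {
  p <- sim_params(n_genes = 100, n_direct = 0, n_sof_dexdep = 0,
    n_sof_3h_rep = 0, n_sof_dexind = 0, n_sof_const_rep = 0)
  pipe <- small_sim_pipeline(33, p)
  de <- de_time_contrast(pipe$sim$counts, pipe$sim$design, "SoF", 3,
    pipe$sf, pipe$disp)
  expect_identical(attr(de, "contrast"), "SoF_t3_vs_t0")
  expect_s3_class(de, "sofdex_de")
  de2 <- de_genotype_contrast(pipe$sim$counts, pipe$sim$design, "SoF", "wt",
    pipe$sf, pipe$disp)
  expect_identical(attr(de2, "contrast"), "SoF_vs_wt")
  g <- glance(de)
  expect_identical(g$contrast, "SoF_t3_vs_t0")
  expect_identical(g$n_genes, 100L)
  expect_s3_class(tidy(de), "tbl_df")
})
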