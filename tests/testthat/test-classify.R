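make_pairs <- function(x, y, padj_sof = 0.01, padj_ctrl = 0.01) {
  tibble::tibble(
    gene_id = sprintf("g%d", seq_along(x)),
    log2FC_SoF = x, padj_SoF = rep_len(padj_sof, length(x)),
    log2FC_Ctrl = y, padj_Ctrl = rep_len(padj_ctrl, length(x))
  )
}

test_that("regression_fit recovers exact lines and honours the gate", {
  x <- seq(-2, 3, length.out = 10)
  fit <- regression_fit(make_pairs(x, 2 * x + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_identical(fit$n_genes_used, 10L)

  # displaced but non-significant points leave the fit unchanged
  pairs2 <- dplyr::bind_rows(
    make_pairs(x, 2 * x + 1),
    make_pairs(c(10, -10), c(-50, 50), padj_sof = 0.9, padj_ctrl = 0.9)
  )
  fit2 <- regression_fit(pairs2)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 1, tolerance = 1e-12)

  # noisy cloud: matches the closed-form normal equations
  withr::with_seed(3, {
    xs <- rnorm(200)
    ys <- 1.5 * xs - 0.3 + rnorm(200, 0, 0.4)
  })
  fit3 <- regression_fit(make_pairs(xs, ys))
  sxx <- sum((xs - mean(xs))^2)
  sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
  slope_hat <- sxy / sxx
  expect_equal(fit3$slope, slope_hat, tolerance = 1e-10)
  expect_equal(fit3$intercept, mean(ys) - slope_hat * mean(xs),
    tolerance = 1e-10)

  expect_error(regression_fit(make_pairs(xs[1:5], ys[1:5], padj_sof = 0.9,
    padj_ctrl = 0.9)), "at least 3")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(glance(fit)$n_genes_used, 10L)
})

test_that("mcd_outliers equals the exhaustive h-subset minimum and flags the planted point", {
  withr::with_seed(10, {
    x <- cbind(rnorm(9, 0, 0.1), rnorm(9, 0, 0.1))
  })
  x <- rbind(x, c(10, 10))
  fit <- mcd_outliers(x, seed = 1)
  expect_true(fit$outlier[10])
  # the distant point dominates the robust distances
  expect_gt(fit$distance2[10], 100 * max(fit$distance2[1:9]))
  h <- floor((10 + 2 + 1) / 2)
  expect_identical(fit$h, h)
  brute <- mcd_bruteforce_det(x, h)
  expect_lte(abs(fit$raw_det - brute) / brute, 1e-9)
})

test_that("mcd_outliers rejects degenerate scatter", {
  same <- matrix(1, 10, 2)
  expect_error(mcd_outliers(same), "degenerate|identical")
  coll <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(mcd_outliers(coll), "degenerate")
  expect_error(mcd_outliers(cbind(1:10, c(1:9, NA))), "finite")
  expect_error(mcd_outliers(matrix(rnorm(30), ncol = 3)), "2 columns")
})

test_that("mcd_outliers is calibrated on bivariate normal data", {
  withr::with_seed(42, {
    x <- matrix(rnorm(2000), ncol = 2)
  })
  fit <- mcd_outliers(x, seed = 1)
  expect_gte(mean(fit$outlier), 0.015)
  expect_lte(mean(fit$outlier), 0.035)
})

test_that("mcd_outliers is affine equivariant with a fixed seed", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(10, 6), ncol = 2))
  })
  A <- matrix(c(2, 0.5, -1, 1.5), 2, 2)
  b <- c(3, -7)
  y <- sweep(x %*% t(A), 2, b, "+")
  f1 <- mcd_outliers(x, seed = 9)
  f2 <- mcd_outliers(y, seed = 9)
  expect_identical(f1$outlier, f2$outlier)
  expect_equal(f2$center, as.numeric(A %*% f1$center + b),
    tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(f2$cov), unname(A %*% f1$cov %*% t(A)), tolerance = 1e-8)
})

test_that("mcd_outliers agrees with an independent robust-covariance implementation", {
  withr::with_seed(77, {
    x <- rbind(matrix(rnorm(160), ncol = 2),
      cbind(rnorm(8, 5, 0.2), rnorm(8, -5, 0.2)))
  })
  fit <- mcd_outliers(x, seed = 2)
  ref <- withr::with_seed(1,
    MASS::cov.mcd(x, quantile.used = fit$h, nsamp = 2000))
  # our h-subset is at least as concentrated as the one reachable from the
  # reference estimate (its `best` subset can be smaller than h, so compare
  # the h nearest points under the reference's robust distances)
  d2_ref <- stats::mahalanobis(x, ref$center, ref$cov)
  ref_subset <- order(d2_ref)[seq_len(fit$h)]
  expect_lte(fit$raw_det, det(stats::cov(x[ref_subset, ])) * (1 + 1e-9))
  # and the shifted cluster is flagged by our estimate and distant under both
  expect_true(all(fit$outlier[81:88]))
  expect_true(all(d2_ref[81:88] > qchisq(0.975, 2)))
})

test_that("side-of-line set selection applies all three gates", {
  x <- seq(1, 10)
  pairs <- make_pairs(x, x) # line y = x
  line <- structure(list(slope = 1, intercept = 0, n_genes_used = 10),
    class = "sofdex_fcline")
  mask <- rep(FALSE, 10)
  mask[c(3, 4)] <- TRUE
  pairs$log2FC_Ctrl[3] <- 0 # below the line
  pairs$log2FC_Ctrl[4] <- 9 # above the line
  expect_identical(select_sof_dexdep(pairs, line, mask), "g3")
  expect_identical(select_sof_3h_rep(pairs, line, mask), "g4")

  # outlier below the line but not significant in SoF -> excluded
  pairs$padj_SoF[3] <- 0.2
  pairs$padj_Ctrl[3] <- 0.2
  expect_identical(select_sof_dexdep(pairs, line, mask), character(0))

  # exact mirror property: swapping the axes swaps the two selectors
  withr::with_seed(13, {
    px <- rnorm(50)
    py <- 0.8 * px + rnorm(50, 0, 0.3)
  })
  p1 <- make_pairs(px, py)
  m <- rep(FALSE, 50); m[sample.int(50, 12)] <- TRUE
  l1 <- regression_fit(p1)
  swapped <- p1 |>
    dplyr::rename(
      log2FC_SoF = "log2FC_Ctrl", padj_SoF = "padj_Ctrl",
      log2FC_Ctrl = "log2FC_SoF", padj_Ctrl = "padj_SoF"
    )
  l2 <- regression_fit(swapped)
  # a point below y = a + bx maps to a point above the inverse line
  expect_setequal(
    select_sof_dexdep(p1, l1, m),
    select_sof_3h_rep(swapped, structure(
      list(slope = 1 / l1$slope, intercept = -l1$intercept / l1$slope,
        n_genes_used = l1$n_genes_used), class = "sofdex_fcline"), m)
  )
  expect_s3_class(l2, "sofdex_fcline")
})

test_that("constitutive set selection is signed, exclusive and optionally strict", {
  de <- tibble::tibble(
    gene_id = c("up1", "up2", "down1", "ns"),
    log2FC = c(2, 1.2, -1.5, 0.4),
    padj = c(0.001, 0.01, 0.001, 0.4)
  )
  sets <- select_constitutive_sets(de)
  expect_setequal(sets$sof_dexind, c("up1", "up2"))
  expect_identical(sets$sof_const_rep, "down1")

  # a gene already labeled sof_dexdep stays there only
  sets2 <- select_constitutive_sets(de, exclude = "up1")
  expect_identical(sets2$sof_dexind, "up2")

  # strictness flag removes genes with a significant wt dex response
  wt <- tibble::tibble(gene_id = c("up1", "up2"), padj = c(0.001, 0.8))
  sets3 <- select_constitutive_sets(de, strict_dexind = TRUE,
    wt_dex_response = wt)
  expect_identical(sets3$sof_dexind, "up2")
  expect_error(select_constitutive_sets(de, strict_dexind = TRUE),
    "wt_dex_response")
})

test_that("classify_gene_sets produces mutually exclusive labels with provenance", {
  p <- sim_params(n_genes = 600, n_direct = 60, n_sof_dexdep = 25,
    n_sof_3h_rep = 10, n_sof_dexind = 30, n_sof_const_rep = 30)
  pipe <- small_sim_pipeline(51, p)
  de_sof <- de_time_contrast(pipe$sim$counts, pipe$sim$design, "SoF", 3,
    pipe$sf, pipe$disp)
  de_ctrl <- de_time_contrast(pipe$sim$counts, pipe$sim$design, "Ctrl", 3,
    pipe$sf, pipe$disp)
  de_sw <- de_genotype_contrast(pipe$sim$counts, pipe$sim$design, "SoF", "wt",
    pipe$sf, pipe$disp)
  cls <- classify_gene_sets(de_sof, de_ctrl, de_sw)
  expect_identical(anyDuplicated(cls$labels$gene_id), 0L)
  expect_true(all(cls$labels$class %in% c(
    "background", "sof_dexdep", "sof_3h_rep", "sof_dexind", "sof_const_rep"
  )))
  labeled <- cls$labels[cls$labels$class != "background", ]
  expect_false(any(is.na(labeled$rule)))
  # every sof_dexdep gene is a gated outlier strictly below the line
  dd <- cls$pairs[cls$pairs$gene_id %in%
    cls$labels$gene_id[cls$labels$class == "sof_dexdep"], ]
  expect_true(all(dd$outlier))
  yhat <- cls$line$intercept + cls$line$slope * dd$log2FC_SoF
  expect_true(all(dd$log2FC_Ctrl < yhat))
})

test_that("zscore_abundance standardizes per gene and genotype", {
  des <- make_design(c("s1", "s2"))
  counts <- make_counts(matrix(c(1, 3), nrow = 1), sample_ids = c("s1", "s2"))
  sf <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 1))
  z <- zscore_abundance(counts, des, "g1", sf)
  expect_equal(sort(z$zscore), c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-12)

  # constant gene -> all zero; and z-scores always sum to 0 per gene
  counts2 <- make_counts(matrix(c(5, 5, 2, 8), nrow = 2, byrow = TRUE),
    sample_ids = c("s1", "s2"))
  sf2 <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 1))
  z2 <- zscore_abundance(counts2, des, c("g1", "g2"), sf2)
  expect_equal(z2$zscore[z2$gene_id == "g1"], c(0, 0))
  sums <- tapply(z2$zscore, z2$gene_id, sum)
  expect_equal(as.numeric(sums), c(0, 0), tolerance = 1e-12)
  expect_error(zscore_abundance(counts2, des, character(), sf2), "empty")
  expect_error(zscore_abundance(counts2, des, "nope", sf2), "unknown")
})

test_that("mann_whitney matches enumeration, ties convention and the base implementation", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(r$U, 0)
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5, 5))$p.value, 1)

  # exact vs normal approximation at n = 15 per group
  withr::with_seed(6, {
    a <- rnorm(15)
    b <- rnorm(15, 0.8)
  })
  exact <- mann_whitney(a, b)
  expect_identical(exact$method, "exact")
  w <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(exact$p.value, w$p.value, tolerance = 1e-12)

  # n > 20 switches to the tie-corrected normal approximation
  withr::with_seed(7, {
    a2 <- rnorm(25)
    b2 <- rnorm(25, 0.5)
  })
  approx <- mann_whitney(a2, b2)
  expect_identical(approx$method, "normal_approx")
  w_approx <- stats::wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
  expect_equal(approx$p.value, w_approx$p.value, tolerance = 1e-9)
  # large-sample approximation is within 0.01 of the exact value
  expect_lte(abs(exact$p.value -
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value), 0.01)

  expect_error(mann_whitney(numeric(), 1), "non-empty")
})
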