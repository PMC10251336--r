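#' Pair mutant fold changes for a fixed treatment time
#'
#' Joins the SoF and Ctrl time-vs-baseline differential expression results
#' into one record per gene, the input of the regression/outlier
#' classification.
#'
#' @param de_sof,de_ctrl `sofdex_de` tibbles for the same treatment time in
#'   the SoF and Ctrl genotypes.
#' @return tibble `gene_id`, `log2FC_SoF`, `padj_SoF`, `log2FC_Ctrl`,
#'   `padj_Ctrl`.
#' @export
foldchange_pairs <- function(de_sof, de_ctrl) {
  assert_cols(de_sof, c("gene_id", "log2FC", "padj"), arg = "de_sof")
  assert_cols(de_ctrl, c("gene_id", "log2FC", "padj"), arg = "de_ctrl")
  inner_join(
    de_sof |> select("gene_id", log2FC_SoF = "log2FC", padj_SoF = "padj"),
    de_ctrl |> select("gene_id", log2FC_Ctrl = "log2FC", padj_Ctrl = "padj"),
    by = "gene_id"
  )
}

gate_pairs <- function(pairs, alpha) {
  sig <- (!is.na(pairs$padj_SoF) & pairs$padj_SoF < alpha) |
    (!is.na(pairs$padj_Ctrl) & pairs$padj_Ctrl < alpha)
  sig & is.finite(pairs$log2FC_SoF) & is.finite(pairs$log2FC_Ctrl)
}

#' Significance-gated fold-change regression
#'
#' Ordinary least squares of the Ctrl fold change on the SoF fold change,
#' fit only over genes whose time-vs-baseline adjusted p-value is below
#' `alpha` in either mutant (or both). The fitted line is the stringent
#' fold-change reference against which outliers are classified as more
#' activated with SoF (below the line) or with Ctrl (above).
#'
#' @param pairs a [foldchange_pairs()] tibble.
#' @param alpha significance gate on `padj` (default 0.05).
#' @return object of class `sofdex_fcline`: list with `slope`,
#'   `intercept`, `n_genes_used`.
#' @export
regression_fit <- function(pairs, alpha = 0.05) {
  assert_cols(pairs, c("log2FC_SoF", "padj_SoF", "log2FC_Ctrl", "padj_Ctrl"),
    arg = "pairs")
  use <- gate_pairs(pairs, alpha)
  if (sum(use) < 3L) {
    abort(sprintf(
      "regression gate left %d gene(s); need at least 3.", sum(use)
    ))
  }
  x <- pairs$log2FC_SoF[use]
  y <- pairs$log2FC_Ctrl[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    n_genes_used = sum(use)
  ), class = "sofdex_fcline")
}

#' @export
print.sofdex_fcline <- function(x, ...) {
  cat(sprintf(
    "<sofdex_fcline> Ctrl ~ %.4f + %.4f * SoF (n = %d gated genes)\n",
    x$intercept, x$slope, x$n_genes_used
  ))
  invisible(x)
}

#' @export
tidy.sofdex_fcline <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' @export
glance.sofdex_fcline <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n_genes_used = x$n_genes_used)
}

# genes strictly below (side = -1) / above (side = +1) the line
line_side <- function(pairs, line) {
  yhat <- line$intercept + line$slope * pairs$log2FC_SoF
  sign(pairs$log2FC_Ctrl - yhat)
}

#' Select SoF dexamethasone-dependent de-repressed genes
#'
#' Genes that are (i) MCD bivariate outliers of the (SoF, Ctrl) fold-change
#' pair, (ii) strictly below the gated regression line (Ctrl fold change
#' lower than predicted from SoF, i.e. more activated with SoF), and
#' (iii) significant for the dexamethasone response in the SoF sample
#' (`padj_SoF < alpha`, which covers "SoF or both").
#'
#' @param pairs a [foldchange_pairs()] tibble.
#' @param line a [regression_fit()] result.
#' @param outlier_mask logical vector aligned with `pairs` rows (from
#'   [mcd_outliers()] on the gated genes, expanded back; see
#'   [classify_gene_sets()] for the assembled pipeline).
#' @param alpha significance level.
#' @return character vector of gene ids.
#' @export
select_sof_dexdep <- function(pairs, line, outlier_mask, alpha = 0.05) {
  stopifnot(length(outlier_mask) == nrow(pairs))
  sel <- outlier_mask &
    line_side(pairs, line) < 0 &
    !is.na(pairs$padj_SoF) & pairs$padj_SoF < alpha
  pairs$gene_id[sel & !is.na(sel)]
}

#' Select SoF 3-h repressed genes
#'
#' Mirror of [select_sof_dexdep()]: outliers strictly above the regression
#' line (higher fold change in Ctrl), significant in the Ctrl sample.
#'
#' @inheritParams select_sof_dexdep
#' @return character vector of gene ids.
#' @export
select_sof_3h_rep <- function(pairs, line, outlier_mask, alpha = 0.05) {
  stopifnot(length(outlier_mask) == nrow(pairs))
  sel <- outlier_mask &
    line_side(pairs, line) > 0 &
    !is.na(pairs$padj_Ctrl) & pairs$padj_Ctrl < alpha
  pairs$gene_id[sel & !is.na(sel)]
}

#' Select constitutive mutation-dependent gene sets
#'
#' From the time-pooled SoF-vs-wt contrast: genes significantly up are the
#' dexamethasone-independent SoF set, genes significantly down the
#' constitutively repressed set. Genes already labeled by the 3-h outlier
#' rules are excluded so classes stay mutually exclusive. With
#' `strict_dexind = TRUE`, dexamethasone-independent genes must in
#' addition show no significant 3-h dexamethasone response in wild type.
#'
#' @param mutant_vs_wt `sofdex_de` tibble for SoF vs wt pooled over times.
#' @param alpha significance level.
#' @param exclude gene ids already labeled (e.g. the two outlier sets).
#' @param strict_dexind require non-significance of the wt dex response.
#' @param wt_dex_response `sofdex_de` for the wt 3-h contrast; needed when
#'   `strict_dexind = TRUE`.
#' @return list with `sof_dexind` and `sof_const_rep` gene-id vectors.
#' @export
select_constitutive_sets <- function(mutant_vs_wt, alpha = 0.05,
                                     exclude = character(),
                                     strict_dexind = FALSE,
                                     wt_dex_response = NULL) {
  assert_cols(mutant_vs_wt, c("gene_id", "log2FC", "padj"), arg = "mutant_vs_wt")
  sig <- !is.na(mutant_vs_wt$padj) & mutant_vs_wt$padj < alpha
  up <- mutant_vs_wt$gene_id[sig & mutant_vs_wt$log2FC > 0]
  down <- mutant_vs_wt$gene_id[sig & mutant_vs_wt$log2FC < 0]
  up <- setdiff(up, exclude)
  down <- setdiff(down, c(exclude, up))
  if (strict_dexind) {
    if (is.null(wt_dex_response)) {
      abort("strict_dexind = TRUE requires wt_dex_response.")
    }
    nonresp <- wt_dex_response$gene_id[
      is.na(wt_dex_response$padj) | wt_dex_response$padj >= alpha
    ]
    up <- intersect(up, nonresp)
  }
  list(sof_dexind = up, sof_const_rep = down)
}

#' Full gene-set classification at a treatment time
#'
#' Chains the selection pipeline: significance-gated regression over the
#' (SoF, Ctrl) fold-change pairs, MCD bivariate outliers over the gated
#' genes, below-line selection (SoF Dex-dep.), above-line selection (SoF
#' 3h Rep.), and the constitutive sets from the pooled SoF-vs-wt contrast.
#'
#' @param de_sof,de_ctrl time-vs-baseline `sofdex_de` results for the SoF
#'   and Ctrl genotypes at the classification time (typically 3 h).
#' @param de_sof_vs_wt pooled SoF-vs-wt `sofdex_de` result.
#' @param alpha significance level for all gates.
#' @param mcd_q chi-square cutoff quantile for the MCD outlier mask.
#' @param mcd_seed seed for the MCD elemental starts.
#' @param strict_dexind,wt_dex_response see [select_constitutive_sets()].
#' @return list of class `sofdex_classification`: `labels` (tibble
#'   `gene_id`, `class`, `rule`), `line`, `mcd`, `pairs` (with `gated` and
#'   `outlier` columns).
#' @export
classify_gene_sets <- function(de_sof, de_ctrl, de_sof_vs_wt,
                               alpha = 0.05, mcd_q = 0.975, mcd_seed = 1,
                               strict_dexind = FALSE,
                               wt_dex_response = NULL) {
  pairs <- foldchange_pairs(de_sof, de_ctrl)
  gated <- gate_pairs(pairs, alpha)
  line <- regression_fit(pairs, alpha)
  mcd <- mcd_outliers(
    pairs[gated, c("log2FC_SoF", "log2FC_Ctrl")],
    q = mcd_q, seed = mcd_seed
  )
  outlier <- rep(FALSE, nrow(pairs))
  outlier[gated] <- mcd$outlier
  dexdep <- select_sof_dexdep(pairs, line, outlier, alpha)
  rep3h <- setdiff(select_sof_3h_rep(pairs, line, outlier, alpha), dexdep)
  const <- select_constitutive_sets(
    de_sof_vs_wt,
    alpha = alpha, exclude = c(dexdep, rep3h),
    strict_dexind = strict_dexind, wt_dex_response = wt_dex_response
  )
  labels <- tibble(gene_id = pairs$gene_id, class = "background", rule = NA_character_) |>
    mutate(
      class = case_when(
        .data$gene_id %in% dexdep ~ "sof_dexdep",
        .data$gene_id %in% rep3h ~ "sof_3h_rep",
        .data$gene_id %in% const$sof_dexind ~ "sof_dexind",
        .data$gene_id %in% const$sof_const_rep ~ "sof_const_rep",
        TRUE ~ "background"
      ),
      rule = case_when(
        .data$class == "sof_dexdep" ~ "mcd_outlier_below_line",
        .data$class == "sof_3h_rep" ~ "mcd_outlier_above_line",
        .data$class == "sof_dexind" ~ "sof_vs_wt_up",
        .data$class == "sof_const_rep" ~ "sof_vs_wt_down",
        TRUE ~ NA_character_
      )
    )
  pairs$gated <- gated
  pairs$outlier <- outlier
  structure(list(labels = labels, line = line, mcd = mcd, pairs = pairs),
    class = "sofdex_classification")
}

#' @export
print.sofdex_classification <- function(x, ...) {
  cat("<sofdex_classification>\n")
  print(table(x$labels$class))
  invisible(x)
}

#' Per-gene z-scores of normalized abundance over the time course
#'
#' Standardizes each gene's size-factor-normalized abundance to mean 0 and
#' sample standard deviation 1 (denominator n-1) across the samples of
#' each genotype, the representation used to summarize a gene set's
#' trajectory over treatment time. Genes with zero variance get z = 0.
#'
#' @param counts tibble: `gene_id` plus one column per sample.
#' @param design design tibble covering the samples.
#' @param gene_set character vector of gene ids (non-empty).
#' @param size_factors optional [median_of_ratios()] tibble.
#' @return tibble `gene_id`, `sample_id`, `genotype`, `treatment`, `time`,
#'   `replicate`, `zscore`.
#' @export
zscore_abundance <- function(counts, design, gene_set, size_factors = NULL) {
  if (length(gene_set) == 0L) abort("gene_set is empty.")
  mat <- counts_to_matrix(counts)
  check_design(design, colnames(mat))
  missing <- setdiff(gene_set, rownames(mat))
  if (length(missing) > 0L) {
    abort(sprintf("gene_set has unknown gene(s): %s",
      paste(head(missing, 5L), collapse = ", ")))
  }
  if (is.null(size_factors)) size_factors <- median_of_ratios(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(mat)]
  norm <- sweep(mat[gene_set, , drop = FALSE], 2, sf, "/")
  long <- as_tibble(norm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "abundance") |>
    left_join(design, by = "sample_id") |>
    group_by(.data$gene_id, .data$genotype) |>
    mutate(
      zscore = {
        s <- sd(.data$abundance)
        if (is.na(s) || s == 0) {
          rep(0, length(.data$abundance))
        } else {
          (.data$abundance - mean(.data$abundance)) / s
        }
      }
    ) |>
    ungroup()
  long |> select(
    "gene_id", "sample_id", "genotype", "treatment", "time", "replicate",
    "zscore"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact p-value via the null U
#' distribution when both groups have at most 20 observations and no ties
#' are present, otherwise the tie-corrected normal approximation with
#' continuity correction. U counts pairs where an `x` observation exceeds
#' a `y` observation (ties count one half).
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`;
#'   `"greater"` means `x` tends to exceed `y`.
#' @return tibble `U`, `p.value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- arg_match(alternative)
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 20 && n2 <= 20) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(
        pwilcox(U, n1, n2),
        1 - pwilcox(U - 1, n1, n2)
      )),
      greater = 1 - pwilcox(U - 1, n1, n2),
      less = pwilcox(U, n1, n2)
    )
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      cc <- 0.5
      p <- switch(alternative,
        two.sided = {
          z <- (abs(U - mu) - cc) / sigma
          min(1, 2 * pnorm(-max(z, 0)))
        },
        greater = pnorm((U - mu - cc) / sigma, lower.tail = FALSE),
        less = pnorm((U - mu + cc) / sigma)
      )
    }
    method <- "normal_approx"
  }
  tibble(U = U, p.value = p, method = method)
}
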