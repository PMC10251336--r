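#' Minimum covariance determinant bivariate outlier detection
#'
#' Robust location/scatter by the FastMCD algorithm: from many elemental
#' (d+1)-point starts, iterate concentration steps (C-steps) to find the
#' h-point subset whose sample covariance has minimal determinant. The raw
#' estimate is rescaled by a consistency correction, then refined by a
#' one-step reweighting (points within the chi-square `q` quantile of the
#' raw robust distance re-enter a classical estimate, itself corrected for
#' the trimming). Outliers are points whose squared robust Mahalanobis
#' distance against the reweighted estimate exceeds the chi-square
#' quantile `q` with `d` degrees of freedom.
#'
#' Two consistency corrections are available. `"median"` (default)
#' rescales the raw scatter so that the median robust distance over the
#' data matches the chi-square median — the data-driven correction used
#' by common robust-covariance implementations, and robust to inlier
#' clouds that are not elliptically normal (e.g. fold-change clouds
#' stretched along a regression direction). `"asymptotic"` applies the
#' normal-model factor `(h/n) / P(chisq_{d+2} <= q_{h/n})`, exact under
#' multivariate normality.
#'
#' The subset search operates on point indices only, so the estimate is
#' affine equivariant for a fixed seed: an affine map of the data maps
#' location and scatter accordingly and leaves the outlier mask unchanged.
#'
#' @param points a data frame or matrix with two numeric columns (e.g. the
#'   SoF and Ctrl log2 fold changes of each gene), all finite.
#' @param h size of the subset; default `floor((n + d + 1) / 2)`.
#' @param q chi-square quantile used both for reweighting and for the
#'   outlier cutoff (default 0.975).
#' @param n_starts number of elemental starts; if all `choose(n, d+1)`
#'   elemental subsets number fewer than this, every one is used.
#' @param max_csteps C-step iteration cap per start.
#' @param correction raw-scatter consistency correction, `"median"`
#'   (default) or `"asymptotic"`; see Details.
#' @param seed integer seed controlling the random starts.
#'
#' @return object of class `sofdex_mcd`: list with `outlier` (logical
#'   mask), `distance2` (squared robust distances), `center`, `cov`
#'   (reweighted), `raw_center`, `raw_cov` (consistency-corrected raw),
#'   `raw_det` (determinant of the uncorrected best h-subset covariance),
#'   `best_subset` (indices), `h`, `n`, `cutoff`.
#' @export
mcd_outliers <- function(points, h = NULL, q = 0.975, n_starts = 500,
                         max_csteps = 100,
                         correction = c("median", "asymptotic"), seed = 1) {
  correction <- arg_match(correction)
  x <- as.matrix(as.data.frame(points))
  if (ncol(x) != 2L) abort("points must have exactly 2 columns.")
  if (!all(is.finite(x))) abort("points must be finite.")
  d <- 2L
  n <- nrow(x)
  if (n < 2L * (d + 1L)) {
    abort(sprintf("MCD needs at least %d points (got %d).", 2 * (d + 1), n))
  }
  if (is.null(h)) h <- floor((n + d + 1) / 2)
  if (h < d + 1L || h > n) abort("h must lie in [d+1, n].")

  cstep_det <- function(subset) {
    # concentration steps from a subset until the determinant stabilizes
    budget <- max_csteps
    repeat {
      ctr <- colMeans(x[subset, , drop = FALSE])
      cv <- cov(x[subset, , drop = FALSE])
      dt <- det(cv)
      if (!is.finite(dt) || dt < .Machine$double.xmin) {
        return(list(subset = subset, det = 0, center = ctr, cov = cv))
      }
      d2 <- mahalanobis(x, ctr, cv)
      new_subset <- sort(order(d2)[seq_len(h)])
      budget <- budget - 1L
      if (identical(new_subset, subset) || budget <= 0L) {
        return(list(subset = subset, det = dt, center = ctr, cov = cv))
      }
      subset <- new_subset
    }
  }

  run <- function() {
    n_elemental <- choose(n, d + 1L)
    starts <- if (n_elemental <= n_starts) {
      asplit(combn(n, d + 1L), 2L)
    } else {
      replicate(n_starts, sample.int(n, d + 1L), simplify = FALSE)
    }
    best <- NULL
    for (s in starts) {
      s <- as.integer(s)
      # grow elemental start to h points via one distance ranking; skip
      # degenerate (collinear) elemental subsets
      cv0 <- cov(x[s, , drop = FALSE])
      ctr0 <- colMeans(x[s, , drop = FALSE])
      if (!is.finite(det(cv0)) || det(cv0) < .Machine$double.xmin) next
      d2 <- mahalanobis(x, ctr0, cv0)
      subset <- sort(order(d2)[seq_len(h)])
      res <- cstep_det(subset)
      if (is.null(best) || res$det < best$det) best <- res
    }
    best
  }
  best <- with_seed_if(seed, run())
  if (is.null(best) || best$det <= 0) {
    abort(paste(
      "degenerate scatter: every candidate h-subset has a singular",
      "covariance (points may be collinear or identical)."
    ))
  }

  # consistency correction of the raw h-subset scatter
  consistency <- function(alpha) alpha / pchisq(qchisq(alpha, d), d + 2)
  raw_center <- best$center
  scale_factor <- if (correction == "median") {
    median(mahalanobis(x, best$center, best$cov)) / qchisq(0.5, d)
  } else {
    consistency(h / n)
  }
  raw_cov <- best$cov * scale_factor

  # one-step reweighting at the chi-square q quantile
  cutoff <- qchisq(q, d)
  d2_raw <- mahalanobis(x, raw_center, raw_cov)
  keep <- d2_raw <= cutoff
  if (sum(keep) > d) {
    center <- colMeans(x[keep, , drop = FALSE])
    cv <- cov(x[keep, , drop = FALSE]) * consistency(q)
    if (is.finite(det(cv)) && det(cv) > .Machine$double.xmin) {
      rew_center <- center
      rew_cov <- cv
    } else {
      rew_center <- raw_center
      rew_cov <- raw_cov
    }
  } else {
    rew_center <- raw_center
    rew_cov <- raw_cov
  }
  distance2 <- mahalanobis(x, rew_center, rew_cov)
  structure(list(
    outlier = distance2 > cutoff,
    distance2 = distance2,
    center = rew_center,
    cov = rew_cov,
    raw_center = raw_center,
    raw_cov = raw_cov,
    raw_det = best$det,
    best_subset = best$subset,
    h = h, n = n, q = q, cutoff = cutoff
  ), class = "sofdex_mcd")
}

#' @export
print.sofdex_mcd <- function(x, ...) {
  cat(sprintf(
    "<sofdex_mcd> n = %d, h = %d, %d outlier(s) at chi-square(%g) cutoff\n",
    x$n, x$h, sum(x$outlier), x$q
  ))
  invisible(x)
}

#' @export
tidy.sofdex_mcd <- function(x, ...) {
  tibble(
    point = seq_len(x$n),
    distance2 = x$distance2,
    outlier = x$outlier
  )
}

#' @export
glance.sofdex_mcd <- function(x, ...) {
  tibble(
    n = x$n, h = x$h, raw_det = x$raw_det,
    n_outliers = sum(x$outlier), cutoff = x$cutoff
  )
}
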