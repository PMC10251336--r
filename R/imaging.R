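#' Otsu threshold of a grayscale image
#'
#' Builds a 256-bin histogram over the image's intensity range and returns
#' the threshold (a bin boundary) maximizing the between-class variance of
#' the below/above split; ties break toward the lower threshold. The 256
#' bins are used regardless of bit depth.
#'
#' @param image numeric matrix with finite, non-negative intensities and
#'   at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return scalar threshold; pixels `> threshold` form the foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  if (any(!is.finite(v))) abort("image intensities must be finite.")
  lo <- min(v); hi <- max(v)
  if (lo == hi) abort("constant image: Otsu threshold is undefined.")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(
    pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  )
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- counts / sum(counts)
  # cumulative class probability and mean below each candidate boundary
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  # candidate thresholds are the boundaries after bins 1..n_bins-1
  o <- omega[-n_bins]
  m <- mu[-n_bins]
  sigma_b <- ifelse(o > 0 & o < 1, (mu_t * o - m)^2 / (o * (1 - o)), -Inf)
  best <- which.max(sigma_b) # which.max takes the first (lowest) maximizer
  breaks[best + 1]
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Binarizes at the Otsu threshold and labels 4-connected foreground
#' components; components smaller than `min_area` pixels are dropped.
#' Touching nuclei merge into one label (no watershed splitting).
#'
#' @param mask_channel numeric matrix (nuclear stain, e.g. Hoechst).
#' @param min_area minimum component size in pixels (default 20).
#' @param threshold optional fixed threshold; Otsu when `NULL`.
#' @return integer matrix of labels (0 = background), labels renumbered
#'   1..n in raster order; attribute `threshold` records the cut used.
#'   Empty result (all zero) with a warning when nothing passes.
#' @export
segment_nuclei <- function(mask_channel, min_area = 20, threshold = NULL) {
  if (is.null(threshold)) threshold <- otsu_threshold(mask_channel)
  fg <- mask_channel > threshold
  labels <- label_components_4(fg)
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes < min_area)
  if (length(drop) > 0L) labels[labels %in% drop] <- 0L
  # renumber surviving labels 1..n
  surv <- sort(unique(labels[labels > 0]))
  if (length(surv) == 0L) {
    warn("no nuclear components found after size filtering.")
  } else {
    labels[] <- match(labels, surv, nomatch = 0L)
    labels[is.na(labels)] <- 0L
  }
  storage.mode(labels) <- "integer"
  attr(labels, "threshold") <- threshold
  labels
}

# 4-connected component labeling by iterative minimum-label propagation
label_components_4 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  if (sum(fg) == 0L) return(lab)
  big <- .Machine$integer.max
  repeat {
    m <- matrix(big, nr, nc)
    m[fg] <- lab[fg]
    up <- rbind(rep(big, nc), m[-nr, , drop = FALSE])
    down <- rbind(m[-1, , drop = FALSE], rep(big, nc))
    left <- cbind(rep(big, nr), m[, -nc, drop = FALSE])
    right <- cbind(m[, -1, drop = FALSE], rep(big, nr))
    newm <- pmin(m, up, down, left, right)
    changed <- fg & newm < lab
    if (!any(changed)) break
    lab[changed] <- newm[changed]
  }
  # compress label ids to consecutive integers
  ids <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

#' Cytoplasmic ring masks around labeled nuclei
#'
#' Dilates each nucleus by a disk of radius `width` pixels (Euclidean;
#' set `shape = "square"` for a Chebyshev square) and subtracts all
#' nuclei, yielding a per-cell cytoplasmic ring. Pixels reached by the
#' rings of two or more cells are contested and assigned to neither.
#'
#' @param nuclear_mask integer label matrix from [segment_nuclei()].
#' @param width ring width in pixels (default 4).
#' @param shape `"disk"` (default) or `"square"` structuring element.
#' @return integer matrix: ring label per pixel (0 = none).
#' @export
cytoplasm_ring <- function(nuclear_mask, width = 4, shape = c("disk", "square")) {
  shape <- arg_match(shape)
  if (width < 1) abort("width must be >= 1.")
  nr <- nrow(nuclear_mask); nc <- ncol(nuclear_mask)
  labs <- sort(unique(nuclear_mask[nuclear_mask > 0]))
  ring <- matrix(0L, nr, nc)
  claimed <- matrix(0L, nr, nc) # number of cells whose dilation reaches px
  owner <- matrix(0L, nr, nc)
  offs <- expand.grid(di = -width:width, dj = -width:width)
  if (shape == "disk") {
    offs <- offs[offs$di^2 + offs$dj^2 <= width^2, ]
  }
  for (lb in labs) {
    px <- which(nuclear_mask == lb, arr.ind = TRUE)
    dil <- matrix(FALSE, nr, nc)
    for (o in seq_len(nrow(offs))) {
      i <- px[, 1] + offs$di[o]
      j <- px[, 2] + offs$dj[o]
      ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
      dil[cbind(i[ok], j[ok])] <- TRUE
    }
    reach <- dil & nuclear_mask == 0L
    claimed[reach] <- claimed[reach] + 1L
    owner[reach] <- lb
  }
  sole <- claimed == 1L
  ring[sole] <- owner[sole]
  ring
}

#' Per-cell nuclear and cytoplasmic signal measurements
#'
#' Mean signal-channel intensity over each cell's nuclear mask and
#' cytoplasmic ring, and the nuclear fraction
#' `nuclear / (nuclear + cytoplasmic)`. Cells with an empty ring get an
#' `NA` cytoplasmic mean and fraction and are flagged, not dropped. The
#' fraction is invariant to rescaling the signal channel by any positive
#' constant.
#'
#' @param signal_channel numeric matrix of the signal to quantify.
#' @param nuclear_mask label matrix from [segment_nuclei()].
#' @param rings ring label matrix from [cytoplasm_ring()].
#' @return tibble `cell`, `nuclear_mean`, `cyto_mean`, `nuclear_fraction`,
#'   `empty_ring`.
#' @export
measure_cells <- function(signal_channel, nuclear_mask, rings) {
  if (!all(dim(signal_channel) == dim(nuclear_mask)) ||
    !all(dim(signal_channel) == dim(rings))) {
    abort("channel and mask dimensions differ.")
  }
  labs <- sort(unique(nuclear_mask[nuclear_mask > 0]))
  res <- map(labs, function(lb) {
    nuc <- signal_channel[nuclear_mask == lb]
    cyt <- signal_channel[rings == lb]
    empty <- length(cyt) == 0L
    nm <- mean(nuc)
    cm <- if (empty) NA_real_ else mean(cyt)
    tibble(
      cell = lb,
      nuclear_mean = nm,
      cyto_mean = cm,
      nuclear_fraction = if (empty) NA_real_ else nm / (nm + cm),
      empty_ring = empty
    )
  }) |> list_rbind()
  if (length(labs) == 0L) {
    res <- tibble(
      cell = integer(), nuclear_mean = numeric(), cyto_mean = numeric(),
      nuclear_fraction = numeric(), empty_ring = logical()
    )
  }
  res
}

#' Quantify nuclear translocation from a two-channel image
#'
#' Convenience wrapper chaining [segment_nuclei()], [cytoplasm_ring()] and
#' [measure_cells()].
#'
#' @param nuclear_channel nuclear-stain matrix (segmentation channel).
#' @param signal_channel signal matrix to quantify.
#' @param ring_width cytoplasmic ring width in pixels.
#' @param min_area minimum nucleus area in pixels.
#' @return a [measure_cells()] tibble.
#' @export
quantify_translocation <- function(nuclear_channel, signal_channel,
                                   ring_width = 4, min_area = 20) {
  labels <- segment_nuclei(nuclear_channel, min_area = min_area)
  rings <- cytoplasm_ring(labels, width = ring_width)
  measure_cells(signal_channel, labels, rings)
}
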