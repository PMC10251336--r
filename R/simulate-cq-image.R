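#' Simulate a qPCR Cq table with known fold changes
#'
#' Generates quantification-cycle values as
#' `Cq = base - log2(expression) + Gaussian noise`, for a set of genes over
#' two conditions, with a designated control gene whose expression is
#' constant. The true per-gene fold change (test vs reference condition)
#' is recorded so the delta-delta-Cq round trip can be checked exactly at
#' zero noise.
#'
#' @param fold_changes named numeric: true expression fold change of each
#'   target gene in `test_condition` relative to `ref_condition`.
#' @param control_gene name of the control (housekeeping) gene.
#' @param conditions character vector `c(ref, test)` naming the two
#'   conditions; the first is the reference.
#' @param n_replicates technical replicates per gene x condition.
#' @param base_cq Cq of a unit-expression transcript.
#' @param base_expression baseline expression of every gene in the
#'   reference condition (and of the control gene everywhere).
#' @param noise_sd Gaussian noise standard deviation on the Cq scale.
#' @param seed integer seed.
#'
#' @return a list with `cq` (tibble `sample_id`, `condition`, `gene`, `cq`)
#'   and `truth` (tibble `gene`, `fold_change`).
#' @export
simulate_cq_table <- function(fold_changes = c(GENE1 = 4, GENE2 = 0.5),
                              control_gene = "RPLP0",
                              conditions = c("t0", "dex3h"),
                              n_replicates = 3,
                              base_cq = 30,
                              base_expression = 1,
                              noise_sd = 0,
                              seed = NULL) {
  stopifnot(length(conditions) == 2L, !is.null(names(fold_changes)))
  if (control_gene %in% names(fold_changes)) {
    abort("control_gene must not appear in fold_changes.")
  }
  with_seed_if(seed, {
    genes <- c(names(fold_changes), control_gene)
    grid <- tidyr::expand_grid(
      condition = conditions,
      replicate = seq_len(n_replicates),
      gene = genes
    ) |>
      mutate(
        sample_id = sprintf("%s_r%d", .data$condition, .data$replicate),
        fc = if_else(
          .data$gene == control_gene | .data$condition == conditions[1],
          1,
          unname(fold_changes[.data$gene])
        ),
        expression = base_expression * .data$fc,
        cq = base_cq - log2(.data$expression) +
          rnorm(dplyr::n(), 0, noise_sd)
      )
    list(
      cq = grid |> select("sample_id", "condition", "gene", "cq"),
      truth = tibble(gene = names(fold_changes), fold_change = unname(fold_changes))
    )
  })
}

#' Simulate a two-channel cell image with known nuclear fractions
#'
#' Builds a nuclear-stain channel (bright elliptical nuclei on a dim
#' background) and a signal channel in which each cell has a known nuclear
#' and cytoplasmic mean intensity, so that segmentation and per-cell
#' measurement can be validated against recorded truth. Cytoplasm occupies
#' an elliptical shell around each nucleus.
#'
#' @param n_cells number of cells; placed on a jittered grid so nuclei do
#'   not touch.
#' @param dim image dimensions (rows, cols) in pixels.
#' @param nucleus_radii semi-axes (pixels) of the elliptical nuclei.
#' @param cyto_extent extra radius (pixels) of the cytoplasm shell.
#' @param nuclear_intensity,cyto_intensity per-cell signal-channel means;
#'   recycled to `n_cells`.
#' @param stain_intensity nuclear-channel intensity inside nuclei.
#' @param background signal- and stain-channel background level.
#' @param noise_sd Gaussian pixel noise (applied to both channels).
#' @param seed integer seed.
#'
#' @return a list with matrices `nuclear_channel`, `signal_channel`,
#'   integer matrix `true_labels` (0 = background), and a `truth` tibble
#'   (`cell`, `nuclear_intensity`, `cyto_intensity`, `nuclear_fraction`).
#' @export
simulate_cell_image <- function(n_cells = 6,
                                dim = c(192, 192),
                                nucleus_radii = c(9, 7),
                                cyto_extent = 8,
                                nuclear_intensity = 120,
                                cyto_intensity = 60,
                                stain_intensity = 200,
                                background = 10,
                                noise_sd = 2,
                                seed = NULL) {
  with_seed_if(seed, {
    nr <- dim[1]; nc <- dim[2]
    nuc_int <- rep_len(nuclear_intensity, n_cells)
    cyt_int <- rep_len(cyto_intensity, n_cells)
    # jittered grid of centers, spaced to keep cytoplasm shells apart
    spacing <- 2 * (max(nucleus_radii) + cyto_extent) + 6
    gx <- seq(spacing, nr - spacing, by = spacing)
    gy <- seq(spacing, nc - spacing, by = spacing)
    centers <- tidyr::expand_grid(x = gx, y = gy)
    if (nrow(centers) < n_cells) {
      abort("image too small for n_cells at this spacing.")
    }
    centers <- centers[sample.int(nrow(centers), n_cells), ]
    centers$x <- centers$x + runif(n_cells, -2, 2)
    centers$y <- centers$y + runif(n_cells, -2, 2)

    row_idx <- matrix(seq_len(nr), nr, nc)
    col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    labels <- matrix(0L, nr, nc)
    cyto_labels <- matrix(0L, nr, nc)
    for (k in seq_len(n_cells)) {
      en <- ((row_idx - centers$x[k]) / nucleus_radii[1])^2 +
        ((col_idx - centers$y[k]) / nucleus_radii[2])^2
      ec <- ((row_idx - centers$x[k]) / (nucleus_radii[1] + cyto_extent))^2 +
        ((col_idx - centers$y[k]) / (nucleus_radii[2] + cyto_extent))^2
      labels[en <= 1] <- k
      cyto_labels[ec <= 1 & en > 1] <- k
    }
    nuclear_channel <- matrix(background, nr, nc)
    nuclear_channel[labels > 0] <- stain_intensity
    signal_channel <- matrix(background, nr, nc)
    for (k in seq_len(n_cells)) {
      signal_channel[labels == k] <- nuc_int[k]
      signal_channel[cyto_labels == k] <- cyt_int[k]
    }
    if (noise_sd > 0) {
      nuclear_channel <- pmax(nuclear_channel + rnorm(nr * nc, 0, noise_sd), 0)
      signal_channel <- pmax(signal_channel + rnorm(nr * nc, 0, noise_sd), 0)
    }
    truth <- tibble(
      cell = seq_len(n_cells),
      nuclear_intensity = nuc_int,
      cyto_intensity = cyt_int,
      nuclear_fraction = nuc_int / (nuc_int + cyt_int)
    )
    list(
      nuclear_channel = nuclear_channel,
      signal_channel = signal_channel,
      true_labels = labels,
      true_cyto_labels = cyto_labels,
      truth = truth
    )
  })
}
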