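#' Control-gene-normalized Cq values
#'
#' Computes per-sample, per-gene delta Cq = Cq_gene - Cq_control against a
#' designated control (housekeeping) gene measured in every sample. The
#' control gene's own delta Cq is 0 by construction. Adding a constant to
#' every Cq of a sample (e.g. an input-amount shift) leaves delta Cq
#' unchanged.
#'
#' @param cq tibble with `sample_id`, `condition`, `gene`, `cq`.
#' @param control_gene name of the control gene (default `"RPLP0"`).
#' @return tibble `sample_id`, `condition`, `gene`, `cq`, `delta_cq`.
#' @export
delta_cq <- function(cq, control_gene = "RPLP0") {
  assert_cols(cq, c("sample_id", "condition", "gene", "cq"), arg = "cq")
  if (any(!is.finite(cq$cq))) abort("Cq values must be finite.")
  ctrl <- cq |>
    filter(.data$gene == control_gene) |>
    select("sample_id", cq_control = "cq")
  missing <- setdiff(unique(cq$sample_id), ctrl$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf(
      "control gene '%s' missing in sample(s): %s",
      control_gene, paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(ctrl$sample_id)) {
    ctrl <- ctrl |>
      group_by(.data$sample_id) |>
      summarise(cq_control = mean(.data$cq_control), .groups = "drop")
  }
  cq |>
    left_join(ctrl, by = "sample_id") |>
    mutate(delta_cq = .data$cq - .data$cq_control) |>
    select("sample_id", "condition", "gene", "cq", "delta_cq")
}

#' Delta-delta Cq and relative expression between conditions
#'
#' Averages replicate delta Cq values on the Cq scale within each gene x
#' condition (geometric-mean-equivalent on the expression scale; set
#' `average = "expression"` to average 2^-deltaCq instead), then takes
#' delta delta Cq = mean delta Cq(test) - mean delta Cq(reference) and
#' relative expression 2^-deltadeltaCq, strictly positive and equal to 1
#' iff delta delta Cq is 0.
#'
#' @param dcq a [delta_cq()] result.
#' @param test_condition,ref_condition condition labels to compare.
#' @param average `"cq"` (default) or `"expression"` replicate averaging.
#' @return tibble `gene`, `delta_delta_cq`, `rel_expression`.
#' @export
delta_delta_cq <- function(dcq, test_condition, ref_condition,
                           average = c("cq", "expression")) {
  average <- arg_match(average)
  assert_cols(dcq, c("condition", "gene", "delta_cq"), arg = "dcq")
  sub <- dcq |> filter(.data$condition %in% c(test_condition, ref_condition))
  agg <- sub |>
    group_by(.data$gene, .data$condition) |>
    summarise(
      mean_dcq = if (average == "cq") {
        mean(.data$delta_cq)
      } else {
        -log2(mean(2^-.data$delta_cq))
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_dcq")
  for (cond in c(test_condition, ref_condition)) {
    if (!cond %in% names(agg) || any(is.na(agg[[cond]]))) {
      bad <- if (!cond %in% names(agg)) {
        unique(agg$gene)
      } else {
        agg$gene[is.na(agg[[cond]])]
      }
      abort(sprintf(
        "condition '%s' missing for gene(s): %s",
        cond, paste(head(bad, 5L), collapse = ", ")
      ))
    }
  }
  agg |>
    mutate(
      delta_delta_cq = .data[[test_condition]] - .data[[ref_condition]],
      rel_expression = rel_expression(.data$delta_delta_cq)
    ) |>
    select("gene", "delta_delta_cq", "rel_expression")
}

#' Relative expression from delta-delta Cq
#'
#' @param ddcq numeric delta-delta Cq value(s).
#' @return `2^-ddcq`.
#' @export
rel_expression <- function(ddcq) 2^(-ddcq)
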