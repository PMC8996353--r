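# Summary / presentation-layer computations: temporal signal-to-noise,
# qualitative ICC bins, whole-map correlations, and the
# activation-by-reliability conjunction classification.

#' Temporal signal-to-noise ratio
#'
#' `mean(signal) / sd(residuals)`, with the sample (n - 1) SD. The signal
#' is a voxel/region time series; the residuals are the corresponding
#' first-level model residuals.
#'
#' @param signal,residuals Equal-length numeric vectors (length >= 2).
#' @return A single number.
#' @export
compute_tsnr <- function(signal, residuals) {
  if (length(signal) != length(residuals) || length(signal) < 2) {
    abort("signal and residuals must have equal length >= 2.",
          class = "retest_input_error")
  }
  s <- sd(residuals)
  if (s == 0) {
    abort("Residual SD is zero; tSNR undefined.",
          class = "retest_degenerate_error")
  }
  mean(signal) / s
}

#' Qualitative reliability bin of an ICC
#'
#' Bins ICC values into the conventional display categories:
#' poor `[0, 0.4)`, fair `[0.4, 0.6)`, good `[0.6, 0.75]`, excellent
#' `(0.75, 1]`. Intervals are lower-closed, with 0.75 assigned to "good"
#' (the excellent bin is strictly above 0.75). Vectorized; values outside
#' `[0, 1]` raise a domain error.
#'
#' @param icc Numeric vector in `[0, 1]`.
#' @return Character vector of bins.
#' @export
bin_icc <- function(icc) {
  if (any(!is.finite(icc)) || any(icc < 0 | icc > 1)) {
    abort("ICC values must lie in [0, 1].", class = "retest_domain_error")
  }
  dplyr::case_when(
    icc < 0.4 ~ "poor",
    icc < 0.6 ~ "fair",
    icc <= 0.75 ~ "good",
    TRUE ~ "excellent"
  )
}

icc_bin_levels <- c("poor", "fair", "good", "excellent")

align_maps <- function(a, b) {
  only_a <- setdiff(a$unit_id, b$unit_id)
  only_b <- setdiff(b$unit_id, a$unit_id)
  if (length(only_a) || length(only_b)) {
    abort(paste0("Unit sets differ; only in first: [",
                 paste(only_a, collapse = ", "), "], only in second: [",
                 paste(only_b, collapse = ", "), "]"),
          class = "retest_alignment_error")
  }
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), "unit_id", value_a = 2),
    dplyr::select(tibble::as_tibble(b), "unit_id", value_b = 2),
    by = "unit_id")
}

#' Correlation between two unit maps
#'
#' Pearson correlation over units between two maps (tibbles with
#' `unit_id` and a value column, e.g. an ICC map and a mean-activation or
#' tSNR map) — one number summarizing how strongly the two spatial
#' patterns agree.
#'
#' @param a,b Unit-map tibbles over identical unit sets (>= 3 units),
#'   value in the second column.
#' @return Pearson r.
#' @export
map_correlation <- function(a, b) {
  m <- align_maps(a, b)
  if (nrow(m) < 3) {
    abort("Need >= 3 shared units.", class = "retest_input_error")
  }
  if (sd(m$value_a) == 0 || sd(m$value_b) == 0) {
    abort("A map has zero variance; correlation undefined.",
          class = "retest_degenerate_error")
  }
  stats::cor(m$value_a, m$value_b)
}

#' Activation-by-reliability conjunction labels
#'
#' Cross-classifies each unit by whether it is in the activation mask
#' (e.g. significantly activated at the first session) and whether its ICC
#' exceeds the threshold (strictly; a unit at exactly the threshold is not
#' "reliable").
#'
#' @param activation Tibble with `unit_id` and logical `active`.
#' @param icc Unit map of ICC values (`unit_id` + value column, e.g.
#'   `icc_mean`).
#' @param icc_threshold Reliability threshold (default 0.4, the lower edge
#'   of the "fair" bin).
#' @return Tibble `unit_id`, `class` (factor: `active_and_reliable`,
#'   `active_only`, `reliable_only`, `neither`); class counts are in
#'   attribute `"summary"` and via [conjunction_summary()].
#' @export
conjunction_labels <- function(activation, icc, icc_threshold = 0.4) {
  if (!"active" %in% names(activation)) {
    abort("activation must have a logical 'active' column.",
          class = "retest_schema_error")
  }
  icc_col <- setdiff(names(icc), "unit_id")[1]
  m <- align_maps(dplyr::select(activation, "unit_id", "active"),
                  dplyr::select(icc, "unit_id",
                                dplyr::all_of(icc_col)))
  names(m) <- c("unit_id", "active", "icc")
  out <- m |>
    dplyr::mutate(
      reliable = .data$icc > icc_threshold,
      class = factor(dplyr::case_when(
        .data$active & .data$reliable ~ "active_and_reliable",
        .data$active ~ "active_only",
        .data$reliable ~ "reliable_only",
        TRUE ~ "neither"
      ), levels = c("active_and_reliable", "active_only",
                    "reliable_only", "neither"))
    ) |>
    dplyr::select("unit_id", "class")
  attr(out, "summary") <- dplyr::count(out, .data$class, .drop = FALSE)
  attr(out, "icc_threshold") <- icc_threshold
  out
}

#' @rdname conjunction_labels
#' @param labels A result of [conjunction_labels()].
#' @export
conjunction_summary <- function(labels) {
  attr(labels, "summary") %||% dplyr::count(labels, .data$class,
                                            .drop = FALSE)
}
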