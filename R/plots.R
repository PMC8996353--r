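# ggplot2 display methods for result objects.

#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_line
#'   geom_abline geom_hline labs scale_color_manual theme_minimal
NULL

bin_colors <- c(poor = "#d73027", fair = "#fdae61", good = "#a6d96a",
                excellent = "#1a9850")

#' Plot a per-unit ICC table
#'
#' Units ordered by ICC with quantile intervals (where available) and the
#' conventional reliability bins as colors.
#'
#' @param object An `icc_tbl` (from [icc_by_unit()] or [bml_icc()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icc_tbl
#' @export
autoplot.icc_tbl <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$icc_mean)) |>
    dplyr::arrange(.data$icc_mean) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  bin = factor(.data$bin, levels = names(bin_colors)))
  p <- ggplot(d, aes(x = .data$rank, y = .data$icc_mean,
                     color = .data$bin))
  if (any(!is.na(d$icc_q025))) {
    p <- p + geom_errorbar(aes(ymin = .data$icc_q025,
                               ymax = .data$icc_q975),
                           width = 0, alpha = 0.4)
  }
  p + geom_point(size = 1) +
    geom_hline(yintercept = c(0.4, 0.6, 0.75), linetype = "dotted",
               color = "grey50") +
    scale_color_manual(values = bin_colors, drop = FALSE) +
    labs(x = "unit (ranked)", y = "ICC", color = "reliability") +
    theme_minimal()
}

#' Plot a fitted four-parameter logistic choice curve
#'
#' Observed per-morph "angry" proportions with the fitted curve.
#'
#' @param object A `psycho_fit` from [fit_4pl()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psycho_fit
#' @export
autoplot.psycho_fit <- function(object, ...) {
  obs <- object$proportions
  p <- ggplot(obs, aes(x = .data$morph, y = .data$p_angry)) +
    geom_point() +
    labs(x = "morph (1 = angry, 15 = happy)", y = "P(respond angry)") +
    theme_minimal()
  if (isTRUE(object$converged)) {
    grid <- tibble(morph = seq(1, 15, by = 0.1))
    grid$fit <- four_pl(grid$morph, object$lower, object$upper,
                        object$slope, object$inflection)
    p <- p + geom_line(data = grid, aes(y = .data$fit), color = "#2166ac")
  }
  p
}

#' Plot a pooled-vs-independent ICC comparison
#'
#' Scatter of BML (pooled) against per-unit LME ICCs with the identity
#' line; vertical compression toward the identity's center is the
#' partial-pooling shrinkage.
#'
#' @param object A `shrinkage_comparison` from [compare_shrinkage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shrinkage_comparison
#' @export
autoplot.shrinkage_comparison <- function(object, ...) {
  ggplot(object$by_unit, aes(x = .data$icc_lme, y = .data$icc_bml)) +
    geom_abline(slope = 1, intercept = 0, color = "grey60") +
    geom_point(alpha = 0.7) +
    labs(x = "independent per-unit ICC", y = "pooled (BML) ICC") +
    theme_minimal()
}
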