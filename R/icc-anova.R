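# Classical Shrout-Fleiss ICC from two-way ANOVA mean squares. Exact
# closed form on balanced data; serves as the frequentist oracle against
# which the Bayesian-regularized estimator is checked.

#' Classical ANOVA intraclass correlation
#'
#' Computes the Shrout-Fleiss single-measure ICC from two-way
#' (subject x session) mean squares:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \tfrac{k}{n}(MS_C - MS_E)}}
#' \deqn{ICC(3,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E}}
#' with \eqn{n} subjects (rows) and \eqn{k} sessions (columns). The
#' absolute-agreement form ICC(2,1) charges systematic session/scanner
#' shifts against reliability; the consistency form ICC(3,1) measures
#' stability of subject rankings only. The classical estimator can be
#' negative on noise; that is expected behaviour, not an error.
#'
#' @param data A one-unit reliability slice with columns `subject_id`,
#'   `session`, `value`. Must be balanced and complete (every subject seen
#'   in every session exactly once); for unbalanced data use the
#'   mixed-model estimator [fit_icc()].
#' @param formulation `"consistency_31"` or `"absolute_21"`.
#' @return A single numeric ICC (possibly negative).
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject_id = letters[1:4], session = 1:3)
#' d$value <- c(1, 2, 3, 2, 3, 4, 3, 4, 5, 4, 5, 6)
#' icc_anova(d, "consistency_31")
icc_anova <- function(data,
                      formulation = c("consistency_31", "absolute_21")) {
  formulation <- match.arg(formulation)
  if ("unit_id" %in% names(data) &&
      length(unique(data$unit_id)) > 1L) {
    abort("icc_anova expects a single-unit slice.",
          class = "retest_input_error")
  }
  tab <- table(data$subject_id, data$session)
  if (any(tab != 1L)) {
    abort(paste("Unbalanced or incomplete subject x session design;",
                "the ANOVA oracle requires balance. Use fit_icc()."),
          class = "retest_unbalanced_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "subject_id", "session", "value"),
    names_from = "session", values_from = "value")
  y <- as.matrix(wide[, -1])
  n <- nrow(y)
  k <- ncol(y)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(y)
  rm_ <- rowMeans(y)
  cm <- colMeans(y)
  ms_r <- k * sum((rm_ - grand)^2) / (n - 1)
  ms_c <- n * sum((cm - grand)^2) / (k - 1)
  resid <- sweep(sweep(y, 1, rm_), 2, cm) + grand
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  if (formulation == "consistency_31") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  } else {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
  }
}
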