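# Behavioral metric extraction for the two face-emotion tasks: QC
# exclusion rules, four-parameter logistic (4PL) choice-curve fits,
# reaction-time morph slopes, and visual-search RT metrics. Each metric is
# a per-subject, per-session scalar whose test-retest reliability is then
# assessed with the unit-wise ICC machinery (each metric playing the role
# of a "unit").

#' Session-level quality-control filter
#'
#' Applies the exclusion rules for one subject-session of trials:
#' accuracy below 70% and/or more than 15% nonresponses excludes the
#' session (strict inequalities: exactly 70% accuracy or exactly 15%
#' nonresponse is retained). For the labeling task, accuracy is computed
#' only at the overt endpoints of the morph continuum (morphs 1 and 15,
#' the prototypically angry and happy expressions), since no correct
#' answer exists for ambiguous morphs. Accuracy is the proportion correct
#' among responded trials; the nonresponse rate is over all (non-fixation)
#' trials.
#'
#' @param trials Trial tibble for a single subject-session.
#' @param task `"search"` or `"labeling"`.
#' @return A list: `included` (logical), `reasons` (character, which rules
#'   fired), `accuracy`, `nonresponse_rate`.
#' @export
qc_filter <- function(trials, task = c("search", "labeling")) {
  task <- match.arg(task)
  trials <- dplyr::filter(trials, .data$condition != "fixation")
  if (nrow(trials) == 0) {
    abort("QC undefined for an empty trial table.",
          class = "retest_qc_error")
  }
  key <- dplyr::distinct(trials, .data$subject_id, .data$session)
  if (nrow(key) > 1L) {
    abort("qc_filter expects trials from a single subject-session.",
          class = "retest_input_error")
  }
  responded <- !is.na(trials$response)
  nonresp <- mean(!responded)
  acc_trials <- if (task == "labeling") {
    trials[responded & trials$morph %in% c(1L, 15L), ]
  } else {
    trials[responded, ]
  }
  accuracy <- if (nrow(acc_trials)) mean(acc_trials$correct) else NA_real_
  reasons <- character()
  if (!is.na(accuracy) && accuracy < 0.70) reasons <- c(reasons, "accuracy")
  if (nonresp > 0.15) reasons <- c(reasons, "nonresponse")
  list(included = length(reasons) == 0L, reasons = reasons,
       accuracy = accuracy, nonresponse_rate = nonresp)
}

#' Fit a four-parameter logistic choice curve
#'
#' Fits \eqn{P(\mathrm{angry} \mid m) = l + (u - l)/(1 + \exp(s (m -
#' x_0)))} to the per-morph proportion of "angry" responses by
#' multi-start bounded least squares (default) or trial-level binomial
#' maximum likelihood. The free asymptotes \eqn{l, u} adjust the
#' inflection for the maximum probability of either judgment; the
#' inflection \eqn{x_0} is the morph where judgments switch from
#' predominantly happy to predominantly angry — 8 (the continuum midpoint)
#' indicates no bias, lower values a hostile interpretation bias.
#'
#' @param trials Trial tibble with `morph` and `response` columns
#'   (responses `"angry"`/`"happy"`; nonresponses ignored).
#' @param objective `"proportions"` (least squares on per-morph response
#'   proportions) or `"binomial"` (trial-level likelihood).
#' @return A `psycho_fit` object: `lower`, `upper`, `slope`, `inflection`,
#'   `converged`, `boundary` (any parameter at its box bound), `sse`,
#'   `status`, and the per-morph proportions used.
#' @export
fit_4pl <- function(trials, objective = c("proportions", "binomial")) {
  objective <- match.arg(objective)
  obs <- trials |>
    dplyr::filter(!is.na(.data$morph), !is.na(.data$response)) |>
    dplyr::group_by(morph = .data$morph) |>
    dplyr::summarise(n = dplyr::n(),
                     p_angry = mean(.data$response == "angry"),
                     .groups = "drop")
  if (nrow(obs) < 2L) {
    abort("Need responses at >= 2 distinct morph levels.",
          class = "retest_input_error")
  }
  if (all(obs$p_angry == 1) || all(obs$p_angry == 0)) {
    return(new_psycho_fit(NA, NA, NA, NA, FALSE, FALSE, NA,
                          "degenerate", obs, objective))
  }
  lo <- c(lower = 0, upper = 0, slope = 1e-3, inflection = 1)
  hi <- c(lower = 1, upper = 1, slope = 20, inflection = 15)
  starts <- tidyr::expand_grid(slope = c(0.3, 1, 3),
                               inflection = c(4, 8, 12))
  p0 <- c(lower = max(0, min(obs$p_angry)),
          upper = min(1, max(obs$p_angry)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    start <- c(p0, slope = starts$slope[i],
               inflection = starts$inflection[i])
    fit <- if (objective == "proportions") {
      tryCatch(
        minpack.lm::nlsLM(
          p_angry ~ lower + (upper - lower) /
            (1 + exp(slope * (morph - inflection))),
          data = obs, start = as.list(start), weights = obs$n,
          lower = lo, upper = hi,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    } else {
      nll <- function(par) {
        p <- four_pl(obs$morph, par[1], par[2], par[3], par[4])
        p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
        -sum(obs$n * (obs$p_angry * log(p) +
                        (1 - obs$p_angry) * log(1 - p)))
      }
      tryCatch(optim(start, nll, method = "L-BFGS-B",
                     lower = lo, upper = hi),
               error = function(e) NULL)
    }
    if (is.null(fit)) next
    val <- if (objective == "proportions") {
      sum(obs$n * (obs$p_angry - stats::predict(fit))^2)
    } else {
      fit$value
    }
    if (is.null(best) || val < best$val) best <- list(fit = fit, val = val)
  }
  if (is.null(best)) {
    return(new_psycho_fit(NA, NA, NA, NA, FALSE, FALSE, NA,
                          "no_converge", obs, objective))
  }
  par <- if (objective == "proportions") coef(best$fit) else best$fit$par
  sse <- sum((obs$p_angry - four_pl(obs$morph, par["lower"], par["upper"],
                                    par["slope"],
                                    par["inflection"]))^2 * obs$n)
  boundary <- any(abs(par - lo) < 1e-6) || any(abs(par - hi) < 1e-6)
  new_psycho_fit(par[["lower"]], par[["upper"]], par[["slope"]],
                 par[["inflection"]],
                 converged = is.finite(sse) &&
                   par[["lower"]] < par[["upper"]],
                 boundary = boundary, sse = sse, status = "ok", obs,
                 objective)
}

new_psycho_fit <- function(lower, upper, slope, inflection, converged,
                           boundary, sse, status, proportions, objective) {
  structure(list(lower = lower, upper = upper, slope = slope,
                 inflection = inflection, converged = converged,
                 boundary = boundary, sse = sse, status = status,
                 proportions = proportions, objective = objective),
            class = "psycho_fit")
}

#' @export
print.psycho_fit <- function(x, ...) {
  cat("4PL choice-curve fit (", x$objective, "): status ", x$status,
      "\n", sep = "")
  cat(sprintf("  lower %.3f  upper %.3f  slope %.3f  inflection %.3f\n",
              x$lower, x$upper, x$slope, x$inflection))
  cat("  SSE:", format(x$sse, digits = 4),
      if (x$boundary) " (boundary hit)" else "", "\n")
  invisible(x)
}

#' @method tidy psycho_fit
#' @export
tidy.psycho_fit <- function(x, ...) {
  tibble(term = c("lower", "upper", "slope", "inflection"),
         estimate = c(x$lower, x$upper, x$slope, x$inflection))
}

#' @method glance psycho_fit
#' @export
glance.psycho_fit <- function(x, ...) {
  tibble(converged = x$converged, boundary = x$boundary, sse = x$sse,
         status = x$status, n_morphs = nrow(x$proportions))
}

#' Linear and quadratic reaction-time slopes over the morph continuum
#'
#' Jointly regresses mean RT per morph on the centered morph index
#' \eqn{(m - 8)} and its square \eqn{(m - 8)^2} (raw, not orthogonal,
#' polynomials) by ordinary least squares. The linear coefficient codes
#' emotion intensity (angry to happy); the quadratic codes ambiguity — a
#' negative quadratic means slower responses to ambiguous mid-continuum
#' morphs than to overt endpoints.
#'
#' @param trials Trial tibble with `morph` and `rt` (responded trials
#'   only are used).
#' @return A one-row tibble: `linear`, `quadratic`.
#' @export
rt_morph_slopes <- function(trials) {
  d <- trials |>
    dplyr::filter(!is.na(.data$morph), !is.na(.data$rt)) |>
    dplyr::group_by(morph = .data$morph) |>
    dplyr::summarise(mrt = mean(.data$rt), .groups = "drop")
  if (nrow(d) < 3L) {
    abort("Need RTs at >= 3 distinct morph levels.",
          class = "retest_input_error")
  }
  ctr <- d$morph - 8
  fit <- lm(d$mrt ~ ctr + I(ctr^2))
  tibble(linear = unname(coef(fit)[2]),
         quadratic = unname(coef(fit)[3]))
}

#' Visual-search reaction-time metrics
#'
#' Computes, from correct trials only: the faces-vs-scramble difference
#' (mean RT after face cues, angry and happy pooled, minus mean RT after
#' scrambled controls) and, per cue condition, the slope of mean RT on the
#' natural log of set size over {1, 5, 30}, plus the average of the
#' condition log-slopes. A condition absent from the data yields `NA` for
#' its metrics rather than an error.
#'
#' @param trials Trial tibble with `condition`, `set_size`, `correct`,
#'   `rt`.
#' @return A long tibble: `metric_name`
#'   (`faces_minus_scramble_rt`, `logslope_angry`, `logslope_happy`,
#'   `logslope_scramble`, `logslope_mean`), `value`.
#' @export
search_rt_metrics <- function(trials) {
  d <- dplyr::filter(trials, !is.na(.data$rt), !is.na(.data$correct),
                     .data$correct)
  face_rt <- mean(d$rt[d$condition %in% c("angry", "happy")])
  scr_rt <- mean(d$rt[d$condition == "scrambled"])
  fms <- face_rt - scr_rt
  logslope <- function(cond) {
    dd <- d |>
      dplyr::filter(.data$condition == cond, !is.na(.data$set_size)) |>
      dplyr::group_by(set_size = .data$set_size) |>
      dplyr::summarise(mrt = mean(.data$rt), .groups = "drop")
    if (nrow(dd) < 2L) return(NA_real_)
    unname(coef(lm(dd$mrt ~ log(dd$set_size)))[2])
  }
  sl <- c(angry = logslope("angry"), happy = logslope("happy"),
          scramble = logslope("scrambled"))
  tibble(
    metric_name = c("faces_minus_scramble_rt", "logslope_angry",
                    "logslope_happy", "logslope_scramble",
                    "logslope_mean"),
    value = c(fms, unname(sl), mean(sl))
  )
}

#' Per-session behavioral metrics
#'
#' Applies QC and computes each task's session-level metrics for every
#' subject-session in a trial table: for the labeling task the 4PL
#' inflection and slope plus the linear/quadratic RT morph slopes; for the
#' search task the faces-vs-scramble RT difference and log set-size
#' slopes. Excluded sessions are reported with their QC reasons and no
#' metric rows.
#'
#' @param trials Trial tibble covering one or more subject-sessions.
#' @param task `"search"` or `"labeling"`.
#' @return A list with `metrics` (tibble `subject_id`, `session`,
#'   `metric_name`, `value`) and `qc` (tibble with per-session inclusion
#'   and reasons).
#' @export
session_metrics <- function(trials, task = c("search", "labeling")) {
  task <- match.arg(task)
  keys <- trials |>
    dplyr::filter(.data$condition != "fixation") |>
    dplyr::distinct(.data$subject_id, .data$session)
  res <- purrr::pmap(keys, function(subject_id, session) {
    tt <- dplyr::filter(trials, .data$subject_id == !!subject_id,
                        .data$session == !!session)
    qc <- qc_filter(tt, task)
    qc_row <- tibble(subject_id = subject_id, session = session,
                     included = qc$included,
                     reasons = paste(qc$reasons, collapse = ";"),
                     accuracy = qc$accuracy,
                     nonresponse_rate = qc$nonresponse_rate)
    if (!qc$included) {
      return(list(qc = qc_row, metrics = NULL))
    }
    m <- if (task == "labeling") {
      pf <- fit_4pl(tt)
      slopes <- rt_morph_slopes(tt)
      tibble(metric_name = c("inflection", "psycho_slope", "rt_linear",
                             "rt_quadratic"),
             value = c(pf$inflection, pf$slope, slopes$linear,
                       slopes$quadratic))
    } else {
      search_rt_metrics(tt)
    }
    list(qc = qc_row,
         metrics = dplyr::bind_cols(
           tibble(subject_id = subject_id, session = session), m))
  })
  list(metrics = dplyr::bind_rows(purrr::map(res, "metrics")),
       qc = dplyr::bind_rows(purrr::map(res, "qc")))
}

#' Test-retest reliability of behavioral metrics
#'
#' Treats each session-level metric as a "unit" and delegates to the
#' unit-wise Bayesian-regularized mixed model (consistency formulation,
#' Gamma(2, 0.5) prior by default): a participant random effect with
#' scanner, visit and task-order fixed effects.
#'
#' @param metrics Metric tibble from [session_metrics()] (`subject_id`,
#'   `session`, `metric_name`, `value`).
#' @param design Session-level covariates to merge: tibble with
#'   `subject_id`, `session`, `scanner`, `task_order` (e.g. from
#'   [simulate_design()]).
#' @param spec An [icc_model_spec()].
#' @param seed Integer seed.
#' @return An `icc_tbl` with one row per metric.
#' @export
behavioral_reliability <- function(metrics, design,
                                   spec = icc_model_spec(), seed = NULL) {
  d <- metrics |>
    dplyr::inner_join(design, by = c("subject_id", "session")) |>
    dplyr::rename(unit_id = "metric_name") |>
    dplyr::filter(is.finite(.data$value))
  icc_by_unit(d, spec, seed = seed)
}
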