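# Bayesian-regularized linear mixed-effects ICC for a single unit (voxel,
# region, or behavioral metric). The model is a Gaussian LMM whose
# random-effect standard deviations carry a Gamma prior; the default
# estimator maximizes the REML-type marginal posterior (fixed effects
# integrated out), the MCMC estimator draws from the full posterior with a
# Gibbs sampler. The regularization keeps variance components nonnegative
# and the resulting ICC inside [0, 1], unlike the classical ANOVA
# estimator which can go negative on noise.

#' Specification of the unit-wise ICC model
#'
#' @param formulation `"consistency_31"` (random participant intercept;
#'   scanner, visit and task order as fixed effects — stability of subject
#'   rankings) or `"absolute_21"` (random participant and scanner
#'   intercepts; visit and task order fixed — systematic scanner
#'   differences count against reliability).
#' @param prior_shape,prior_rate Gamma prior on each random-effect SD
#'   (default shape 2, rate 0.5: mode at SD = 2, weakly regularizing away
#'   from zero). Set `prior_shape = NA` for a flat prior (no
#'   regularization), in which case the MAP estimate is the REML estimate.
#' @param estimator `"map"` (posterior mode; fast, point estimate) or
#'   `"mcmc"` (Gibbs sampling; posterior mean, SE and quantile interval).
#' @param chains,warmup,draws MCMC controls (ignored for `"map"`).
#' @return An `icc_model_spec` list.
#' @export
icc_model_spec <- function(formulation = c("consistency_31",
                                           "absolute_21"),
                           prior_shape = 2, prior_rate = 0.5,
                           estimator = c("map", "mcmc"),
                           chains = 2, warmup = 400, draws = 800) {
  formulation <- match.arg(formulation)
  estimator <- match.arg(estimator)
  if (!is.na(prior_shape)) {
    stopifnot(prior_shape > 0, prior_rate > 0)
  }
  structure(list(formulation = formulation, prior_shape = prior_shape,
                 prior_rate = prior_rate, estimator = estimator,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws)),
            class = "icc_model_spec")
}

# Fixed-effect design for one unit slice. Factors with a single observed
# level are dropped (no empty-level aliasing); a genuinely rank-deficient
# design raises an identifiability error naming the aliased columns.
unit_design <- function(data, formulation) {
  terms <- if (formulation == "consistency_31") {
    c("scanner", "visit", "task_order")
  } else {
    c("visit", "task_order")
  }
  df <- tibble(
    scanner = factor(if ("scanner" %in% names(data)) data$scanner
                     else "A"),
    visit = factor(data$session),
    task_order = factor(if ("task_order" %in% names(data))
                        data$task_order else "first")
  )
  keep <- terms[vapply(df[terms], function(x) nlevels(droplevels(x)) > 1L,
                       logical(1))]
  X <- if (length(keep)) {
    stats::model.matrix(stats::reformulate(keep), data = df)
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(paste0("Fixed-effect design is rank deficient; aliased terms: ",
                 paste(aliased, collapse = ", ")),
          class = "retest_identifiability_error")
  }
  X
}

unit_random <- function(data, formulation) {
  fams <- list(participant = list(index = factor(data$subject_id), z = 1))
  if (formulation == "absolute_21") {
    fams$scanner <- list(index = factor(data$scanner), z = 1)
  }
  fams
}

# Negative log of the REML marginal posterior as a function of log-SDs
# (random-effect SDs first, residual SD last). The Gamma prior applies to
# random-effect SDs only; the residual SD carries a flat prior.
neg_log_post <- function(log_sd, y, X, Zs, prior) {
  sds <- exp(log_sd)
  n <- length(y)
  q <- length(Zs)
  sigma_e <- sds[q + 1L]
  V <- diag(sigma_e^2, n)
  for (f in seq_len(q)) {
    V <- V + sds[f]^2 * tcrossprod(Zs[[f]])
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet_v <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(1e10)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  reml <- 0.5 * (logdet_v + 2 * sum(log(diag(ch2))) + sum(r * Vi_r))
  lp <- if (is.na(prior$shape)) 0 else
    sum(dgamma(sds[seq_len(q)], shape = prior$shape, rate = prior$rate,
               log = TRUE))
  out <- reml - lp
  if (!is.finite(out)) 1e10 else out
}

map_beta <- function(sds, y, X, Zs) {
  n <- length(y)
  V <- diag(sds[length(Zs) + 1L]^2, n)
  for (f in seq_along(Zs)) V <- V + sds[f]^2 * tcrossprod(Zs[[f]])
  ch <- chol(V)
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  drop(solve(crossprod(X, Vi_X), crossprod(X, Vi_y)))
}

#' Fit the Bayesian-regularized mixed model for one unit
#'
#' Decomposes one unit's measurements into participant (and, for the
#' absolute-agreement formulation, scanner) variance plus residual
#' variance, with scanner/visit/task-order fixed effects per the chosen
#' formulation, under a Gamma prior on the random-effect SDs. Handles
#' unbalanced and missing-session data; requires at least two subjects
#' with at least two sessions overall.
#'
#' @param data A single-unit reliability slice with columns `subject_id`,
#'   `session`, `value` and (optionally) `scanner`, `task_order`.
#' @param spec An [icc_model_spec()].
#' @param seed Integer seed (used by the MCMC estimator).
#' @return An object of class `icc_fit` with elements `components` (named
#'   variances), `fixed_effects`, `icc` (tibble with `icc_mean`, `icc_se`,
#'   `icc_q025`, `icc_q975`), `status` (`"ok"`, `"degenerate"`, ...),
#'   `spec`, and for MCMC fits the ICC posterior `draws`.
#' @export
fit_icc <- function(data, spec = icc_model_spec(), seed = NULL) {
  stopifnot(inherits(spec, "icc_model_spec"))
  data <- dplyr::filter(data, is.finite(.data$value))
  if (dplyr::n_distinct(data$subject_id) < 2L ||
      dplyr::n_distinct(data$session) < 2L) {
    abort("Need >= 2 subjects and >= 2 sessions to fit the ICC model.",
          class = "retest_input_error")
  }
  y <- data$value
  if (sd(y) == 0) {
    return(new_icc_fit(
      components = c(sigma2_participant = 0, sigma2_residual = 0),
      fixed_effects = c(`(Intercept)` = y[1]),
      icc = icc_row(0, NA_real_, NA_real_, NA_real_),
      status = "degenerate", spec = spec, n_obs = length(y)))
  }
  X <- unit_design(data, spec$formulation)
  fams <- unit_random(data, spec$formulation)
  prior <- list(shape = spec$prior_shape, rate = spec$prior_rate)
  if (spec$estimator == "map") {
    fit_icc_map(y, X, fams, prior, spec, length(y))
  } else {
    fit_icc_mcmc(y, X, fams, prior, spec, seed)
  }
}

fit_icc_map <- function(y, X, fams, prior, spec, n_obs) {
  Zs <- lapply(fams, function(f) {
    Z <- stats::model.matrix(~ 0 + f$index)
    Z * f$z
  })
  sy <- sd(y)
  starts <- list(log(c(rep(sy / 2, length(Zs)), sy / 2)),
                 log(c(rep(sy, length(Zs)), sy / 4)))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, neg_log_post, y = y, X = X, Zs = Zs, prior = prior,
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    abort("MAP optimization failed for all starts.",
          class = "retest_convergence_error")
  }
  sds <- exp(best$par)
  vc <- setNames(sds[seq_along(Zs)]^2,
                 paste0("sigma2_", names(fams)))
  vc["sigma2_residual"] <- sds[length(Zs) + 1L]^2
  beta <- map_beta(sds, y, X, Zs)
  names(beta) <- colnames(X)
  icc <- icc_from_components(vc, spec$formulation)
  new_icc_fit(components = vc, fixed_effects = beta,
              icc = icc_row(icc, NA_real_, NA_real_, NA_real_),
              status = if (best$convergence == 0) "ok" else "no_converge",
              spec = spec, n_obs = n_obs,
              objective = best$value)
}

fit_icc_mcmc <- function(y, X, fams, prior, spec, seed) {
  pr <- if (is.na(prior$shape)) list(kind = "flat") else
    list(kind = "gamma", shape = prior$shape, rate = prior$rate)
  families <- lapply(fams, function(f)
    list(index = f$index, z = f$z, prior = pr))
  sweeps <- lapply(names(families), function(nm)
    list(type = "fixed", family = nm, col = "(Intercept)"))
  gb <- gibbs_lmm(y, X, families, chains = spec$chains,
                  warmup = spec$warmup, draws = spec$draws, seed = seed,
                  sweeps = sweeps)
  sc2 <- gb$scales^2
  icc_draws <- if (spec$formulation == "consistency_31") {
    sc2[, "participant"] / (sc2[, "participant"] + sc2[, "sigma_e"])
  } else {
    sc2[, "participant"] /
      (sc2[, "participant"] + sc2[, "scanner"] + sc2[, "sigma_e"])
  }
  vc <- setNames(colMeans(sc2[, names(fams), drop = FALSE]),
                 paste0("sigma2_", names(fams)))
  vc["sigma2_residual"] <- mean(sc2[, "sigma_e"])
  beta <- colMeans(gb$beta)
  names(beta) <- colnames(X)
  q <- unname(quantile(icc_draws, c(0.025, 0.975)))
  new_icc_fit(components = vc, fixed_effects = beta,
              icc = icc_row(mean(icc_draws), sd(icc_draws), q[1], q[2]),
              status = "ok", spec = spec, n_obs = length(y),
              draws = icc_draws, scales = gb$scales, chain = gb$chain)
}

icc_row <- function(mean, se, q025, q975) {
  tibble(icc_mean = mean, icc_se = se, icc_q025 = q025, icc_q975 = q975)
}

new_icc_fit <- function(components, fixed_effects, icc, status, spec,
                        n_obs, ...) {
  structure(list(components = components, fixed_effects = fixed_effects,
                 icc = icc, status = status, spec = spec, n_obs = n_obs,
                 ...),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat("Bayesian-regularized ICC fit (", x$spec$formulation, ", ",
      x$spec$estimator, ")\n", sep = "")
  cat("  ICC:", format(x$icc$icc_mean, digits = 3))
  if (!is.na(x$icc$icc_se)) {
    cat(" [", format(x$icc$icc_q025, digits = 3), ", ",
        format(x$icc$icc_q975, digits = 3), "]", sep = "")
  }
  cat("  status:", x$status, "\n")
  cat("  variance components:\n")
  print(round(x$components, 5))
  invisible(x)
}

#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = names(x$components), estimate = unname(x$components),
           type = "variance"),
    tibble(term = names(x$fixed_effects),
           estimate = unname(x$fixed_effects), type = "fixed")
  )
}

#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(formulation = x$spec$formulation,
           estimator = x$spec$estimator, status = x$status,
           n_obs = x$n_obs),
    x$icc
  )
}

#' Intraclass correlation from variance components
#'
#' The participant-attributable share of measurement variance:
#' `consistency_31` uses
#' \eqn{\sigma^2_p / (\sigma^2_p + \sigma^2_e)};
#' `absolute_21` adds the scanner variance to the denominator,
#' \eqn{\sigma^2_p / (\sigma^2_p + \sigma^2_s + \sigma^2_e)}.
#'
#' @param vc Named numeric vector/list with `sigma2_participant`,
#'   `sigma2_residual` and (for absolute agreement) `sigma2_scanner`.
#' @param formulation `"consistency_31"` or `"absolute_21"`.
#' @return ICC in `[0, 1]`.
#' @export
icc_from_components <- function(vc,
                                formulation = c("consistency_31",
                                                "absolute_21")) {
  formulation <- match.arg(formulation)
  vc <- unlist(vc)
  p <- vc[["sigma2_participant"]]
  e <- vc[["sigma2_residual"]]
  s <- if (formulation == "absolute_21") {
    if (!"sigma2_scanner" %in% names(vc)) {
      abort("absolute_21 requires a sigma2_scanner component.",
            class = "retest_input_error")
    }
    vc[["sigma2_scanner"]]
  } else 0
  stopifnot(p >= 0, e >= 0, s >= 0)
  tot <- p + s + e
  if (tot == 0) {
    abort("All variance components are zero; ICC undefined.",
          class = "retest_degenerate_error")
  }
  p / tot
}

#' Per-unit ICC estimates for a whole dataset
#'
#' Applies [fit_icc()] independently to every unit of a reliability table.
#' Units whose fit fails or is degenerate are reported with a status
#' rather than dropped. Per-unit seeds are derived deterministically from
#' `seed`, so results are reproducible and independent of unit order.
#'
#' @param data A reliability tibble covering one or more units.
#' @param spec An [icc_model_spec()].
#' @param seed Integer seed.
#' @return A tibble of class `icc_tbl` with one row per unit: `unit_id`,
#'   `formulation`, `icc_mean`, `icc_se`, `icc_q025`, `icc_q975`, `bin`,
#'   `status`.
#' @export
icc_by_unit <- function(data, spec = icc_model_spec(), seed = NULL) {
  units <- sort(unique(data$unit_id))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  rows <- purrr::imap(setNames(units, units), function(u, nm) {
    slice <- dplyr::filter(data, .data$unit_id == u)
    s <- if (is.null(base_seed)) NULL else
      (base_seed + match(u, units) * 7919L) %% .Machine$integer.max
    fit <- tryCatch(fit_icc(slice, spec, seed = s),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(unit_id = u, formulation = spec$formulation,
             icc_mean = NA_real_, icc_se = NA_real_,
             icc_q025 = NA_real_, icc_q975 = NA_real_,
             bin = NA_character_, status = conditionMessage(fit))
    } else {
      tibble(unit_id = u, formulation = spec$formulation,
             fit$icc,
             bin = if (is.na(fit$icc$icc_mean)) NA_character_ else
               bin_icc(fit$icc$icc_mean),
             status = fit$status)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("icc_tbl", class(out))
  out
}
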