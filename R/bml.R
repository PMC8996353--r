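# Integrative Bayesian multilevel model: all regions enter one MCMC fit,
# so per-region ICC posteriors borrow strength across the brain (partial
# pooling / "global calibration"). The model decomposes each measurement
# into population effects (intercept, scanner, task order), session-,
# subject- and region-level intercepts, session-level and region-level
# covariate slopes, the pairwise interactions subject x session,
# session x region and subject x region, and a residual:
#
#   y_ijk = a0 + a1 scanner + a2 order
#         + xi0_i + xi1_i scanner + xi2_i order      (session family)
#         + eta_j + gamma_ij                          (subject families)
#         + zeta0_k + zeta1_k scanner + zeta2_k order (region families)
#         + mu0_ik + nu0_jk + eps_ijk                 (interactions)
#
# with i sessions, j subjects, k regions, every family iid Gaussian.

#' Specification of the Bayesian multilevel (all-regions) model
#'
#' @param chains Number of MCMC chains (>= 2).
#' @param warmup Warmup iterations per chain.
#' @param draws Post-warmup draws per chain (>= 500 for reported
#'   intervals).
#' @param icc_formula Default ICC reading for [bml_icc()]:
#'   `"subject_attributable"` (subject-linked variance over total) or
#'   `"as_printed"` (the literal published expression, which also places
#'   the region-intercept variance in the numerator and the
#'   subject-by-region variance twice in the denominator).
#' @param scale_prior_df,scale_prior_mult Half-Student-t prior on every SD
#'   (df and the multiple of `sd(y)` used as its scale).
#' @param seed Integer seed.
#' @return A `bml_spec` list.
#' @export
bml_spec <- function(chains = 4, warmup = 500, draws = 1000,
                     icc_formula = c("subject_attributable", "as_printed"),
                     scale_prior_df = 3, scale_prior_mult = 2.5,
                     seed = NULL) {
  icc_formula <- match.arg(icc_formula)
  stopifnot(chains >= 2, draws >= 500, warmup >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), icc_formula = icc_formula,
                 scale_prior_df = scale_prior_df,
                 scale_prior_mult = scale_prior_mult, seed = seed),
            class = "bml_spec")
}

bml_scale_names <- c("xi0", "xi1", "xi2", "eta", "gamma",
                     "zeta0", "zeta1", "zeta2", "mu0", "nu0")

#' Fit the integrative Bayesian multilevel model
#'
#' Fits the all-regions hierarchical decomposition (see the package
#' vignette) by Gibbs sampling, with scanner and task order coded as
#' centered (+/- 1/2) covariates so the population intercept is the grand
#' mean. Unbalanced designs (missing sessions) are handled naturally.
#'
#' @param data A reliability tibble with >= 2 subjects, sessions and
#'   units.
#' @param spec A [bml_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @return An object of class `bml_fit` holding scale/population draws,
#'   realized session-by-region and subject-by-region effect draws (needed
#'   for region-specific ICC), convergence diagnostics, and the spec. A
#'   convergence warning is attached (and signalled) if any scale
#'   parameter has split-Rhat > 1.05.
#' @export
fit_bml <- function(data, spec = bml_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "bml_spec"))
  if (dplyr::n_distinct(data$unit_id) < 2L ||
      dplyr::n_distinct(data$subject_id) < 2L ||
      dplyr::n_distinct(data$session) < 2L) {
    abort("fit_bml needs >= 2 units, >= 2 subjects and >= 2 sessions.",
          class = "retest_input_error")
  }
  y <- data$value
  scanner <- ifelse(data$scanner == "B", 0.5, -0.5)
  task_order <- if ("task_order" %in% names(data)) data$task_order
    else "first"
  task <- ifelse(task_order == "second", 0.5, -0.5)
  X <- cbind(a0 = 1, a1 = scanner, a2 = task)
  sess <- factor(data$session)
  subj <- factor(data$subject_id)
  unit <- factor(data$unit_id)
  ht <- list(kind = "half_t", df = spec$scale_prior_df,
             scale = spec$scale_prior_mult * max(sd(y), 1e-3))
  fam <- function(index, z = 1) list(index = index, z = z, prior = ht)
  families <- list(
    xi0 = fam(sess), xi1 = fam(sess, scanner), xi2 = fam(sess, task),
    eta = fam(subj),
    gamma = fam(interaction(subj, sess, drop = TRUE, sep = "|")),
    zeta0 = fam(unit), zeta1 = fam(unit, scanner),
    zeta2 = fam(unit, task),
    mu0 = fam(interaction(sess, unit, drop = TRUE, sep = "|")),
    nu0 = fam(interaction(subj, unit, drop = TRUE, sep = "|"))
  )
  # interweaving sweeps along the non-identified locations of the crossed
  # design: family means <-> population effects, and interaction-family
  # means <-> their parent main-effect families
  lev_of <- function(f) levels(factor(families[[f]]$index))
  map_to <- function(child, parent, which = c("pre", "post")) {
    which <- match.arg(which)
    lab <- if (which == "pre") sub("\\|.*$", "", lev_of(child)) else
      sub("^[^|]*\\|", "", lev_of(child))
    match(lab, lev_of(parent))
  }
  sweeps <- list(
    list(type = "fixed", family = "xi0", col = "a0"),
    list(type = "fixed", family = "xi1", col = "a1"),
    list(type = "fixed", family = "xi2", col = "a2"),
    list(type = "fixed", family = "eta", col = "a0"),
    list(type = "fixed", family = "gamma", col = "a0"),
    list(type = "fixed", family = "zeta0", col = "a0"),
    list(type = "fixed", family = "zeta1", col = "a1"),
    list(type = "fixed", family = "zeta2", col = "a2"),
    list(type = "fixed", family = "mu0", col = "a0"),
    list(type = "fixed", family = "nu0", col = "a0"),
    list(type = "family", child = "mu0", parent = "xi0",
         map = map_to("mu0", "xi0", "pre")),
    list(type = "family", child = "mu0", parent = "zeta0",
         map = map_to("mu0", "zeta0", "post")),
    list(type = "family", child = "nu0", parent = "eta",
         map = map_to("nu0", "eta", "pre")),
    list(type = "family", child = "nu0", parent = "zeta0",
         map = map_to("nu0", "zeta0", "post")),
    list(type = "family", child = "gamma", parent = "eta",
         map = map_to("gamma", "eta", "pre"))
  )
  gb <- gibbs_lmm(y, X, families, resid_prior = ht,
                  chains = spec$chains, warmup = spec$warmup,
                  draws = spec$draws, seed = seed,
                  keep_effects = c("mu0", "nu0"), sweeps = sweeps)
  pars <- cbind(gb$beta, gb$scales)
  diag_tbl <- mcmc_diagnostics(pars, gb$chain)
  diag_tbl$pass <- !is.na(diag_tbl$rhat) & diag_tbl$rhat <= 1.05
  fit <- structure(list(
    scales = gb$scales, beta = gb$beta, chain = gb$chain,
    effects = gb$effects,
    units = levels(unit), subjects = levels(subj),
    sessions = levels(sess),
    diagnostics = diag_tbl, spec = spec, n_obs = length(y),
    seed = seed
  ), class = "bml_fit")
  bad <- diag_tbl$parameter[!diag_tbl$pass]
  if (length(bad)) {
    fit$convergence_warning <- paste0(
      "split-Rhat > 1.05 for: ", paste(bad, collapse = ", "))
    warn(fit$convergence_warning)
  }
  fit
}

#' @export
print.bml_fit <- function(x, ...) {
  cat("Bayesian multilevel reliability fit:", length(x$units), "units,",
      length(x$subjects), "subjects,", length(x$sessions), "sessions\n")
  cat("  chains:", x$spec$chains, " draws/chain:", x$spec$draws,
      " max split-Rhat:",
      format(max(x$diagnostics$rhat, na.rm = TRUE), digits = 4), "\n")
  if (!is.null(x$convergence_warning)) {
    cat("  WARNING:", x$convergence_warning, "\n")
  }
  invisible(x)
}

#' @method tidy bml_fit
#' @export
tidy.bml_fit <- function(x, ...) {
  pars <- cbind(x$beta, x$scales)
  purrr::map_dfr(colnames(pars), function(p) {
    v <- pars[, p]
    tibble(term = p, estimate = mean(v), std.error = sd(v),
           conf.low = unname(quantile(v, 0.025)),
           conf.high = unname(quantile(v, 0.975)))
  })
}

#' @method glance bml_fit
#' @export
glance.bml_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_units = length(x$units),
         n_subjects = length(x$subjects),
         chains = x$spec$chains, draws = x$spec$draws,
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         converged = is.null(x$convergence_warning))
}

# Per-draw empirical variance of realized effects at each region:
# draws x levels matrix, columns labeled "session|unit" or
# "subject|unit"; returns draws x units matrix of variances across the
# first index (sample variance, denominator n - 1).
realized_var_by_unit <- function(eff, units) {
  lab <- sub("^[^|]*\\|", "", colnames(eff))
  out <- matrix(NA_real_, nrow(eff), length(units),
                dimnames = list(NULL, units))
  for (u in units) {
    cols <- which(lab == u)
    m <- length(cols)
    if (m < 2) {
      out[, u] <- 0
      next
    }
    sub_ <- eff[, cols, drop = FALSE]
    rs <- rowSums(sub_)
    out[, u] <- (rowSums(sub_^2) - rs^2 / m) / (m - 1)
  }
  out
}

#' Posterior region-level ICC from a BML fit
#'
#' For each posterior draw, combines the global scale draws (subject,
#' session, subject-by-session, residual) with region-specific variance
#' contributions — the per-draw empirical variances of the realized
#' session-by-region and subject-by-region effects at region k — into an
#' ICC, then summarizes the draws by mean, SE and 2.5/97.5% quantiles.
#'
#' Two readings of the region ICC are provided. The default
#' `"subject_attributable"` counts subject-linked variance only:
#' \deqn{ICC_k = \frac{\sigma^2_\eta + \sigma^2_{\nu_0 k}}
#'  {\sigma^2_\eta + \sigma^2_{\nu_0 k} + \sigma^2_{\xi_0} +
#'   \sigma^2_\gamma + \sigma^2_{\mu_0 k} + \sigma^2_\varepsilon}.}
#' `"as_printed"` follows the published expression literally, adding the
#' region-intercept variance \eqn{\sigma^2_{\zeta_0}} to numerator and
#' denominator and counting \eqn{\sigma^2_{\nu_0 k}} twice in the
#' denominator.
#'
#' @param fit A [fit_bml()] result.
#' @param units Units to summarize (default all).
#' @param formula ICC reading; defaults to the spec's.
#' @return An `icc_tbl` tibble: `unit_id`, `formulation`, `icc_mean`,
#'   `icc_se`, `icc_q025`, `icc_q975`, `bin`.
#' @export
bml_icc <- function(fit, units = NULL,
                    formula = fit$spec$icc_formula) {
  stopifnot(inherits(fit, "bml_fit"))
  formula <- match.arg(formula, c("subject_attributable", "as_printed"))
  units <- units %||% fit$units
  unknown <- setdiff(units, fit$units)
  if (length(unknown)) {
    abort(paste0("Unknown unit_id(s): ", paste(unknown, collapse = ", ")),
          class = "retest_lookup_error")
  }
  s2 <- fit$scales^2
  v_mu <- realized_var_by_unit(fit$effects$mu0, units)
  v_nu <- realized_var_by_unit(fit$effects$nu0, units)
  base_num <- s2[, "eta"]
  base_den <- s2[, "xi0"] + s2[, "gamma"] + s2[, "sigma_e"]
  rows <- purrr::map_dfr(units, function(u) {
    if (formula == "subject_attributable") {
      num <- base_num + v_nu[, u]
      den <- num + base_den + v_mu[, u]
    } else {
      num <- base_num + s2[, "zeta0"] + v_nu[, u]
      den <- num + base_den + v_mu[, u] + v_nu[, u]
    }
    d <- num / den
    tibble(unit_id = u, formulation = paste0("bml_", formula),
           icc_mean = mean(d), icc_se = sd(d),
           icc_q025 = unname(quantile(d, 0.025)),
           icc_q975 = unname(quantile(d, 0.975)),
           bin = bin_icc(mean(d)))
  })
  class(rows) <- c("icc_tbl", class(rows))
  rows
}

#' Convergence diagnostics of a BML fit
#'
#' @param fit A [fit_bml()] result.
#' @return Tibble with one row per population effect and scale parameter:
#'   split-Rhat, bulk and tail effective sample sizes, and a `pass` flag
#'   (Rhat <= 1.05). Attribute `overall_pass` summarizes the fit.
#' @export
bml_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "bml_fit"))
  out <- fit$diagnostics
  attr(out, "overall_pass") <- all(out$pass)
  out
}

#' Compare pooled (BML) and independent per-unit ICC estimates
#'
#' Quantifies the partial-pooling behaviour of the multilevel model
#' relative to independently fitted per-unit mixed models: per-unit
#' differences, the ratio of across-unit SDs (pooled / independent; < 1
#' indicates shrinkage toward the center), the mean shift, and the
#' Spearman correlation of unit rankings.
#'
#' @param bml,lme `icc_tbl` tibbles over the same unit set (e.g. from
#'   [bml_icc()] and [icc_by_unit()]).
#' @return A `shrinkage_comparison` list with `by_unit` (unit, both ICCs,
#'   difference) and `summary` (sd_ratio, mean_shift, rank_correlation).
#' @export
compare_shrinkage <- function(bml, lme) {
  only_b <- setdiff(bml$unit_id, lme$unit_id)
  only_l <- setdiff(lme$unit_id, bml$unit_id)
  if (length(only_b) || length(only_l)) {
    abort(paste0("Unit sets differ; only in first: [",
                 paste(only_b, collapse = ", "), "], only in second: [",
                 paste(only_l, collapse = ", "), "]"),
          class = "retest_alignment_error")
  }
  by_unit <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(bml), "unit_id", icc_bml = "icc_mean"),
    dplyr::select(tibble::as_tibble(lme), "unit_id", icc_lme = "icc_mean"),
    by = "unit_id"
  ) |>
    dplyr::mutate(difference = .data$icc_bml - .data$icc_lme)
  summary <- tibble(
    sd_ratio = sd(by_unit$icc_bml) / sd(by_unit$icc_lme),
    mean_shift = mean(by_unit$difference),
    rank_correlation = stats::cor(by_unit$icc_bml, by_unit$icc_lme,
                                  method = "spearman")
  )
  structure(list(by_unit = by_unit, summary = summary),
            class = "shrinkage_comparison")
}

#' @export
print.shrinkage_comparison <- function(x, ...) {
  cat("Shrinkage comparison over", nrow(x$by_unit), "units\n")
  cat("  SD ratio (pooled/independent):",
      format(x$summary$sd_ratio, digits = 3), "\n")
  cat("  mean shift:", format(x$summary$mean_shift, digits = 3),
      "  rank correlation:",
      format(x$summary$rank_correlation, digits = 3), "\n")
  invisible(x)
}

#' @method tidy shrinkage_comparison
#' @export
tidy.shrinkage_comparison <- function(x, ...) x$by_unit

#' @method glance shrinkage_comparison
#' @export
glance.shrinkage_comparison <- function(x, ...) x$summary
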