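# A hand-built posterior with known, constant draws: 2 units, 3 sessions,
# 4 subjects. Family scales are held fixed across draws so the region ICC
# is an exact arithmetic function of them.
fake_bml_fit <- function(eta = 1, xi0 = 0, gamma = 0, zeta0 = 0,
                         sigma_e = 1, n_draws = 10) {
  units <- c("u1", "u2")
  sess <- as.character(1:3)
  subj <- sprintf("s%d", 1:4)
  scales <- matrix(
    rep(c(xi0 = xi0, xi1 = 0, xi2 = 0, eta = eta, gamma = gamma,
          zeta0 = zeta0, zeta1 = 0, zeta2 = 0, mu0 = 0.1, nu0 = 0.1,
          sigma_e = sigma_e), each = n_draws),
    nrow = n_draws,
    dimnames = list(NULL, c("xi0", "xi1", "xi2", "eta", "gamma", "zeta0",
                            "zeta1", "zeta2", "mu0", "nu0", "sigma_e")))
  mu0_cols <- as.vector(outer(sess, units, paste, sep = "|"))
  nu0_cols <- as.vector(outer(subj, units, paste, sep = "|"))
  # realized interaction effects all zero: per-draw empirical variance at
  # each region is exactly 0
  effects <- list(
    mu0 = matrix(0, n_draws, length(mu0_cols),
                 dimnames = list(NULL, mu0_cols)),
    nu0 = matrix(0, n_draws, length(nu0_cols),
                 dimnames = list(NULL, nu0_cols)))
  structure(list(scales = scales, effects = effects, units = units,
                 spec = bml_spec()),
            class = "bml_fit")
}

test_that("region ICC is exact arithmetic on held-fixed posterior draws", {
  fit <- fake_bml_fit(eta = 1, sigma_e = 1)
  icc <- bml_icc(fit, formula = "subject_attributable")
  expect_equal(icc$icc_mean, c(0.5, 0.5))
  expect_equal(icc$icc_se, c(0, 0))
  expect_equal(icc$icc_q025, icc$icc_q975)

  # literal published reading: zeta0^2 joins the numerator, nu0k counted
  # twice in the denominator (here nu0k = 0, zeta0 = 0.5)
  fitp <- fake_bml_fit(eta = 1, zeta0 = 0.5, sigma_e = 1)
  iccp <- bml_icc(fitp, formula = "as_printed")
  expect_equal(iccp$icc_mean, rep(1.25 / 2.25, 2))

  # no subject-linked variance anywhere -> ICC 0
  fit0 <- fake_bml_fit(eta = 0, xi0 = 0.5, sigma_e = 1)
  expect_equal(bml_icc(fit0, formula = "subject_attributable")$icc_mean,
               c(0, 0))

  expect_error(bml_icc(fit, units = "nope"),
               class = "retest_lookup_error")
})

test_that("posterior ICC summaries are coherent probabilities", {
  des <- simulate_design(design_spec(n_subjects = 10, n_units = 8),
                         seed = 1)
  d <- simulate_unit_data(des, n_units = 8, seed = 2)
  fit <- suppressWarnings(
    fit_bml(d, bml_spec(chains = 2, warmup = 200, draws = 500), seed = 3))
  icc <- bml_icc(fit)
  expect_true(all(icc$icc_mean >= 0 & icc$icc_mean <= 1))
  expect_true(all(icc$icc_q025 <= icc$icc_mean))
  expect_true(all(icc$icc_mean <= icc$icc_q975))
  expect_true(all(icc$bin %in% c("poor", "fair", "good", "excellent")))

  # same seed refits identically
  fit2 <- suppressWarnings(
    fit_bml(d, bml_spec(chains = 2, warmup = 200, draws = 500), seed = 3))
  expect_identical(fit$scales, fit2$scales)
  expect_identical(fit$effects$nu0, fit2$effects$nu0)
})

test_that("constant data concentrates all scales near zero", {
  des <- simulate_design(design_spec(n_subjects = 6, n_units = 4),
                         seed = 4)
  d <- simulate_unit_data(des, n_units = 4, seed = 5)
  d$value <- 3.5
  fit <- suppressWarnings(
    fit_bml(d, bml_spec(chains = 2, warmup = 200, draws = 500), seed = 6))
  expect_lt(max(colMeans(fit$scales)), 0.05)
  expect_equal(mean(fit$beta[, "a0"]), 3.5, tolerance = 0.01)
})

test_that("diagnostics table covers every parameter and flags starvation", {
  des <- simulate_design(design_spec(n_subjects = 10, n_units = 6),
                         seed = 7)
  d <- simulate_unit_data(des, n_units = 6, seed = 8)
  fit <- suppressWarnings(
    fit_bml(d, bml_spec(chains = 2, warmup = 300, draws = 600), seed = 9))
  dg <- bml_diagnostics(fit)
  expect_setequal(dg$parameter,
                  c("a0", "a1", "a2", "xi0", "xi1", "xi2", "eta", "gamma",
                    "zeta0", "zeta1", "zeta2", "mu0", "nu0", "sigma_e"))
  expect_true(all(is.finite(dg$ess_bulk)))

  # a starved run has unusable effective sample sizes
  y <- d$value[1:60]
  X <- matrix(1, 60, 1, dimnames = list(NULL, "(Intercept)"))
  g <- rep(1:10, each = 6)
  gb <- gibbs_lmm(y, X, list(u = list(index = g, z = 1,
                                      prior = list(kind = "half_t",
                                                   df = 3, scale = 1))),
                  chains = 2, warmup = 5, draws = 10, seed = 10)
  dg2 <- retest:::mcmc_diagnostics(cbind(gb$beta, gb$scales), gb$chain)
  expect_true(any(dg2$ess_bulk < 50))
})

test_that("shrinkage comparison is exact on identical tables and strict on
           mismatches", {
  tab <- tibble::tibble(unit_id = c("a", "b", "c"),
                        icc_mean = c(0.2, 0.5, 0.8))
  cmp <- compare_shrinkage(tab, tab)
  expect_equal(cmp$by_unit$difference, rep(0, 3))
  expect_equal(cmp$summary$sd_ratio, 1)
  expect_equal(cmp$summary$rank_correlation, 1)
  expect_error(compare_shrinkage(tab, tab[-1, ]), "a",
               class = "retest_alignment_error")
})
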