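test_that("icc_from_components follows the variance-ratio definitions", {
  expect_equal(icc_from_components(
    c(sigma2_participant = 1, sigma2_scanner = 0, sigma2_residual = 1),
    "absolute_21"), 0.5)
  expect_equal(icc_from_components(
    c(sigma2_participant = 1, sigma2_residual = 1), "consistency_31"),
    0.5)
  expect_equal(icc_from_components(
    c(sigma2_participant = 1, sigma2_scanner = 2, sigma2_residual = 1),
    "absolute_21"), 0.25)
  expect_equal(icc_from_components(
    c(sigma2_participant = 1, sigma2_scanner = 2, sigma2_residual = 1),
    "consistency_31"), 0.5)
  expect_equal(icc_from_components(
    c(sigma2_participant = 0, sigma2_residual = 1), "consistency_31"), 0)
  expect_error(icc_from_components(
    c(sigma2_participant = 0, sigma2_residual = 0), "consistency_31"),
    class = "retest_degenerate_error")
  expect_error(icc_from_components(
    c(sigma2_participant = 1, sigma2_residual = 1), "absolute_21"),
    class = "retest_input_error")
})

test_that("MAP estimator recovers a known consistency ICC at study size", {
  d <- make_icc_data(40, true_icc = 0.75, design_seed = 1, data_seed = 2)
  fit <- fit_icc(d, icc_model_spec())
  expect_equal(fit$icc$icc_mean, 0.75, tolerance = 0.15)
  expect_identical(fit$status, "ok")
  # glance/tidy accessors expose the fit
  expect_identical(glance(fit)$formulation, "consistency_31")
  expect_true(all(tidy(fit)$estimate[tidy(fit)$type == "variance"] >= 0))
})

test_that("visit fixed effect absorbs session shifts in the consistency
           model", {
  d <- make_icc_data(20, true_icc = 0.6, design_seed = 3, data_seed = 4)
  ref <- fit_icc(d, icc_model_spec())
  d2 <- dplyr::mutate(d, value = value + 5 * (session == 2))
  shifted <- fit_icc(d2, icc_model_spec())
  expect_equal(shifted$icc$icc_mean, ref$icc$icc_mean, tolerance = 1e-4)
  expect_equal(shifted$components, ref$components, tolerance = 1e-3)
})

test_that("scanner variance penalizes absolute agreement only", {
  des <- simulate_design(design_spec(n_subjects = 40), seed = 5)
  d <- simulate_unit_data(des, generator_params(
    sd_participant = 0.8, sd_session = 0, sd_unit = 0,
    sd_participant_x_session = 0, sd_session_x_unit = 0,
    sd_participant_x_unit = 0, sd_residual = 0.5, sd_scanner = 0.6,
    scanner_effect = 0), n_units = 1, seed = 6)
  abs_fit <- fit_icc(d, icc_model_spec("absolute_21"))
  con_fit <- fit_icc(d, icc_model_spec("consistency_31"))
  expect_lt(abs_fit$icc$icc_mean, con_fit$icc$icc_mean)
  expect_true("sigma2_scanner" %in% names(abs_fit$components))
})

test_that("an aliased fixed design raises an identifiability error", {
  # all subjects on the ABA pattern: scanner B occurs iff visit 2
  des <- simulate_design(design_spec(n_subjects = 8,
                                     scanner_orders = "ABA"), seed = 7)
  d <- simulate_unit_data(des, n_units = 1, seed = 8)
  expect_error(fit_icc(d, icc_model_spec("consistency_31")),
               "aliased", class = "retest_identifiability_error")
})

test_that("degenerate inputs are flagged, not fatal", {
  d <- tiny_reliability()
  d$value <- 1
  fit <- fit_icc(d, icc_model_spec())
  expect_identical(fit$status, "degenerate")
  expect_identical(fit$icc$icc_mean, 0)
})

test_that("regularized ICC stays in [0,1] where ANOVA goes negative", {
  des <- simulate_design(design_spec(n_subjects = 20), seed = 9)
  d <- simulate_unit_data(des, generator_params(
    sd_participant = 0, sd_session = 0, sd_unit = 0,
    sd_participant_x_session = 0, sd_session_x_unit = 0,
    sd_participant_x_unit = 0, sd_residual = 1, scanner_effect = 0,
    order_effect = 0), n_units = 200, seed = 10)
  bayes <- icc_by_unit(d, icc_model_spec(), seed = 11)
  anova_icc <- vapply(split(d, d$unit_id),
                      icc_anova, numeric(1))
  expect_true(all(bayes$icc_mean >= 0 & bayes$icc_mean <= 1))
  expect_lt(min(anova_icc), 0)
})

test_that("estimated ICC is monotone in the participant SD", {
  set.seed(12)
  n_subj <- 30
  subj <- rep(sprintf("s%02d", 1:n_subj), each = 3)
  sess <- rep(1:3, n_subj)
  # alternate ABA/BAB patterns so scanner is not aliased with visit
  scanner <- as.vector(vapply(seq_len(n_subj), function(j)
    if (j %% 2) c("A", "B", "A") else c("B", "A", "B"), character(3)))
  u <- rnorm(n_subj)
  e <- rnorm(length(subj))
  iccs <- vapply(c(0.3, 0.6, 1, 1.6), function(a) {
    d <- tibble::tibble(subject_id = subj, session = sess,
                        scanner = scanner, task_order = "first",
                        unit_id = "u", value = a * u[as.integer(
                          factor(subj))] + e)
    fit_icc(d, icc_model_spec())$icc$icc_mean
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))
})

test_that("MCMC estimator agrees with an independent JAGS fit", {
  d <- make_icc_data(30, true_icc = 0.6, design_seed = 13, data_seed = 14)
  fit <- fit_icc(d, icc_model_spec(estimator = "mcmc", chains = 2,
                                   warmup = 500, draws = 1500),
                 seed = 15)
  # same model in JAGS: participant random intercept with the same
  # Gamma(2, 0.5) prior on its SD, fixed scanner/visit/order effects
  X <- stats::model.matrix(~ scanner + factor(session) + task_order,
                           data = d)
  model <- "model {
    for (i in 1:N) {
      mu[i] <- inprod(X[i, ], b) + u[g[i]]
      y[i] ~ dnorm(mu[i], pow(sige, -2))
    }
    for (j in 1:J) { u[j] ~ dnorm(0, pow(sigp, -2)) }
    for (p in 1:P) { b[p] ~ dnorm(0, 1e-6) }
    sigp ~ dgamma(2, 0.5)
    sige ~ dunif(0, 100)
  }"
  g <- as.integer(factor(d$subject_id))
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = d$value, X = X, g = g,
                                      N = nrow(d), J = max(g),
                                      P = ncol(X)),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 16))
  stats::update(jm, 1000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("sigp", "sige"), 4000,
                            progress.bar = "none")
  post <- summary(sm)$statistics
  icc_jags <- post["sigp", "Mean"]^2 /
    (post["sigp", "Mean"]^2 + post["sige", "Mean"]^2)
  expect_equal(sqrt(fit$components[["sigma2_participant"]]),
               post["sigp", "Mean"], tolerance = 0.05)
  expect_equal(sqrt(fit$components[["sigma2_residual"]]),
               post["sige", "Mean"], tolerance = 0.05)
  expect_equal(fit$icc$icc_mean, icc_jags, tolerance = 0.05)
})

test_that("per-unit table is deterministic and isolates failures", {
  d <- make_icc_data(12, true_icc = 0.5, n_units = 3, design_seed = 17,
                     data_seed = 18)
  # unit 2 degenerate: all values identical
  d$value[d$unit_id == "R002"] <- 7
  tab1 <- icc_by_unit(d, icc_model_spec(), seed = 19)
  tab2 <- icc_by_unit(d, icc_model_spec(), seed = 19)
  expect_equal(tab1, tab2)
  expect_identical(tab1$status[tab1$unit_id == "R002"], "degenerate")
  expect_true(all(tab1$status[tab1$unit_id != "R002"] == "ok"))

  # a single-unit table equals the direct fit
  one <- dplyr::filter(d, unit_id == "R001")
  direct <- fit_icc(one, icc_model_spec())
  expect_equal(tab1$icc_mean[tab1$unit_id == "R001"],
               direct$icc$icc_mean)
})

test_that("units with participant signal outrank pure-noise units", {
  des <- simulate_design(design_spec(n_subjects = 25), seed = 20)
  signal <- simulate_unit_data(des, generator_params(
    sd_participant = 1, sd_session = 0, sd_unit = 0,
    sd_participant_x_session = 0, sd_session_x_unit = 0,
    sd_participant_x_unit = 0, sd_residual = 0.5), n_units = 5,
    seed = 21)
  noise <- simulate_unit_data(des, generator_params(
    sd_participant = 0, sd_session = 0, sd_unit = 0,
    sd_participant_x_session = 0, sd_session_x_unit = 0,
    sd_participant_x_unit = 0, sd_residual = 1), n_units = 5, seed = 22)
  noise$unit_id <- sub("^R", "N", noise$unit_id)
  tab <- icc_by_unit(dplyr::bind_rows(signal, noise), icc_model_spec(),
                     seed = 23)
  expect_gt(min(tab$icc_mean[grepl("^R", tab$unit_id)]),
            max(tab$icc_mean[grepl("^N", tab$unit_id)]))
})
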